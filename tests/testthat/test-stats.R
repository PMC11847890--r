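test_that("fold enrichment matches exact tail enumeration on small universes", {
  u <- sprintf("U%02d", 1:100)
  res <- fold_enrichment(u[1:10], u[6:15], u)
  expect_equal(res$overlap, 5)
  expect_equal(res$fold, (5 / 10) / (10 / 100))
  expect_equal(res$p, hyper_tail_enum(k = 10, ks = 5, s0 = 10, N = 100),
    tolerance = 1e-12
  )

  withr::with_seed(13, {
    for (i in 1:50) {
      n <- sample(20:60, 1)
      uni <- sprintf("U%02d", seq_len(n))
      mod <- sample(uni, sample(2:(n / 2), 1))
      set <- sample(uni, sample(2:(n / 2), 1))
      got <- fold_enrichment(mod, set, uni)
      ov <- length(intersect(mod, set))
      expect_equal(got$p,
        hyper_tail_enum(
          k = length(mod), ks = ov,
          s0 = length(set), N = n
        ),
        tolerance = 1e-10
      )
      expect_equal(
        got$fold,
        (ov / length(mod)) / (length(set) / n)
      )
    }
  })
})

test_that("degenerate and saturated enrichment cases are flagged", {
  u <- sprintf("U%02d", 1:20)
  sat <- fold_enrichment(u, u, u)
  expect_equal(sat$fold, 1)
  expect_equal(sat$p, 1)

  none <- fold_enrichment(u[1:5], u[6:10], u)
  expect_equal(none$overlap, 0)
  expect_equal(none$p, 1, tolerance = 1e-12)

  empty <- fold_enrichment(character(0), u[1:5], u)
  expect_true(empty$degenerate)
  expect_equal(empty$fold, 0)
  expect_equal(empty$p, 1)
  expect_error(fold_enrichment(u[1:5], u[1:5], character(0)), "universe")
})

test_that("collection enrichment adjusts and orders by p", {
  u <- sprintf("U%03d", 1:200)
  mod <- u[1:30]
  coll <- gene_set_collection(
    list(hit = u[1:25], miss = u[101:130]),
    universe = u
  )
  res <- enrich_many(mod, coll)
  expect_equal(res$set[1], "hit")
  expect_true(all(res$q >= res$p))
  one <- enrich_many(mod, gene_set_collection(list(only = u[1:25]), universe = u))
  expect_equal(one$q, one$p)
  expect_error(
    gene_set_collection(list(a = u[1:2], a = u[3:4]), universe = u),
    "duplicate"
  )
})

test_that("synthetic enriched sets outrank decoys across generator seeds", {
  wins <- vapply(1:100, function(s) {
    sc <- synthetic_scenario(
      network_size = 1000, attachment_parameter = 2,
      planted_modules = list(list(size = 30, density = 0.5)),
      pathogenic_gene_count = 10, n_pathogenic_variants = 10,
      recurrence_profile = rep(1L, 10), rng_seed = 1000 + s
    )
    net <- generate_network(sc)
    sets <- generate_genesets(sc, net)
    seeds <- sample(planted_modules(net)$M1, 10)
    mod <- diamond_expand(net, seeds, n_iter = 20)
    res <- enrich_many(mod, sets)
    enriched <- res[res$set == "enriched_M1", ]
    res$set[1] == "enriched_M1" && enriched$fold > 1 && enriched$p < 0.05
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("module-pathway intersection partitions the union", {
  net <- toy_graph("A", "B", "B", "C", "C", "D", "D", "E")
  out <- module_pathway_intersection(c("A", "B", "C"), c("C", "D", "E"), net)
  expect_equal(out$module_only, c("A", "B"))
  expect_equal(out$shared, "C")
  expect_equal(out$pathway_only, c("D", "E"))
  expect_equal(nrow(out$edges), 4)
  expect_equal(unname(out$membership["C"]), "shared")

  disjoint <- module_pathway_intersection(c("A", "B"), c("D", "E"), net)
  expect_equal(disjoint$shared, character(0))
  nested <- module_pathway_intersection(c("A", "B", "C"), c("B", "C"), net)
  expect_equal(nested$pathway_only, character(0))
})

test_that("edge Jaccard handles identity, disjointness and shared-node cases", {
  tri <- toy_graph("A", "B", "B", "C", "A", "C", "C", "D")
  self <- edge_jaccard(c("A", "B", "C"), c("A", "B", "C"), tri)
  expect_equal(self$edge_jaccard, 1)

  # triangle: modules {A,B} and {B,C} share a node but no induced edge
  m12 <- edge_jaccard(c("A", "B"), c("B", "C"), tri)
  expect_equal(m12$edge_jaccard, 0)
  expect_equal(m12$gene_jaccard, 1 / 3)

  far <- toy_graph("A", "B", "X", "Y")
  expect_equal(edge_jaccard(c("A", "B"), c("X", "Y"), far)$edge_jaccard, 0)

  # both modules induce no edges: undefined, not zero
  und <- edge_jaccard(c("A", "X"), c("B", "Y"), far)
  expect_true(und$undefined)
  expect_true(is.na(und$edge_jaccard))
})

test_that("edge Jaccard is symmetric and invariant under node relabeling", {
  net <- random_small_graph(17)
  nodes <- igraph::V(net)$name
  a <- nodes[1:6]
  b <- nodes[4:9]
  ab <- edge_jaccard(a, b, net)
  ba <- edge_jaccard(b, a, net)
  expect_equal(ab$edge_jaccard, ba$edge_jaccard)
  expect_equal(ab$gene_jaccard, ba$gene_jaccard)
  expect_equal(ab$gene_overlap_a, ba$gene_overlap_b)

  # relabel all nodes through a fixed permutation: similarity is unchanged
  relabel <- setNames(sprintf("Z%02d", rev(seq_along(nodes))), nodes)
  el <- igraph::as_edgelist(net)
  net2 <- igraph::graph_from_data_frame(
    data.frame(from = relabel[el[, 1]], to = relabel[el[, 2]]),
    directed = FALSE
  )
  ab2 <- edge_jaccard(unname(relabel[a]), unname(relabel[b]), net2)
  expect_equal(ab2$edge_jaccard, ab$edge_jaccard)
  expect_equal(ab2$gene_jaccard, ab$gene_jaccard)
})

test_that("similarity ranking orders by edge Jaccard with deterministic ties", {
  net <- random_small_graph(19)
  nodes <- igraph::V(net)$name
  query <- nodes[1:6]
  others <- list(
    self_copy = query,
    near = nodes[2:7],
    far = nodes[8:12]
  )
  ranked <- rank_similar(query, others, net,
    category = c(self_copy = "x", near = "x", far = "y")
  )
  expect_equal(ranked$module_b[1], "self_copy")
  expect_equal(ranked$edge_jaccard[1], 1)
  expect_equal(ranked$rank, 1:3)

  single <- rank_similar(query, list(only = nodes[3:8]), net)
  expect_equal(single$rank, 1L)

  share <- category_share(ranked, top_k = 2)
  expect_equal(share$category[1], "x")
  expect_equal(share$share[1], 1)
})

test_that("modules sharing a planted region dominate the similarity ranking", {
  sc <- synthetic_scenario(
    network_size = 500, attachment_parameter = 2,
    planted_modules = list(list(size = 40, density = 0.5)),
    pathogenic_gene_count = 5, n_pathogenic_variants = 5,
    recurrence_profile = rep(1L, 5), rng_seed = 77
  )
  net <- generate_network(sc)
  planted <- planted_modules(net)$M1
  outside <- setdiff(igraph::V(net)$name, planted)
  others <- withr::with_seed(78, {
    mods <- list()
    for (i in 1:3) mods[[paste0("planted_", i)]] <- sample(planted, 20)
    for (i in 1:3) mods[[paste0("random_", i)]] <- sample(outside, 20)
    mods
  })
  query <- withr::with_seed(79, sample(planted, 20))
  cat_lab <- setNames(rep(c("planted", "random"), each = 3), names(others))
  ranked <- rank_similar(query, others, net, category = cat_lab)
  share <- category_share(ranked, top_k = 3)
  expect_equal(share$category[1], "planted")
  expect_equal(share$share[1], 1)
})

test_that("random-seed null p-values hit their analytic edge cases", {
  net <- random_small_graph(23)
  seeds <- igraph::V(net)$name[1:3]
  ref <- diamond_expand(net, seeds, n_iter = 4)
  # reference against itself: observed overlap is maximal
  res <- random_seed_null(net, ref, ref,
    seed_size = 3, n_iter = 4,
    n_perm = 19, rng_seed = 1
  )
  expect_equal(res$observed, 1)
  expect_equal(res$p, 1 / 20)
  expect_length(res$null, 19)
  expect_true(all(res$null >= 0 & res$null <= 1))
  expect_gte(res$p, 1 / (res$n_perm + 1))

  # reproducibility under a fixed seed
  res2 <- random_seed_null(net, ref, ref,
    seed_size = 3, n_iter = 4,
    n_perm = 19, rng_seed = 1
  )
  expect_identical(res$null, res2$null)

  # an observed statistic of zero can never beat a non-negative null
  zero <- random_seed_null(net, ref, character(0),
    seed_size = 3, n_iter = 4,
    n_perm = 19, rng_seed = 2
  )
  expect_equal(zero$p, 1)
  expect_error(
    random_seed_null(net, ref, ref, seed_size = 1000, n_perm = 5),
    "seed_size"
  )
})

test_that("modules grown inside one planted region beat the random-seed null", {
  hits <- vapply(1:50, function(s) {
    sc <- synthetic_scenario(
      network_size = 1000, attachment_parameter = 2,
      planted_modules = list(list(size = 30, density = 0.5)),
      pathogenic_gene_count = 5, n_pathogenic_variants = 5,
      recurrence_profile = rep(1L, 5), rng_seed = 2000 + s
    )
    net <- generate_network(sc)
    planted <- planted_modules(net)$M1
    two_seed_sets <- withr::with_seed(3000 + s, {
      list(a = sample(planted, 5), b = sample(planted, 5))
    })
    mods <- expand_all(net, two_seed_sets, n_iter = 10)
    res <- random_seed_null(net, mods$a, mods$b,
      seed_size = 5, n_iter = 10,
      n_perm = 99, rng_seed = 4000 + s
    )
    res$p <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("shared enrichment reporting keeps sets supported by all modules", {
  u <- sprintf("U%03d", 1:300)
  coll <- gene_set_collection(
    list(both = u[1:40], only_a = u[101:140], neither = u[201:240]),
    universe = u
  )
  mod_a <- c(u[1:30], u[101:130])
  mod_b <- u[1:30]
  shared <- shared_enriched_sets(list(a = mod_a, b = mod_b), coll, q_max = 0.05)
  expect_setequal(unique(shared$set), "both")
  expect_setequal(unique(shared$module), c("a", "b"))
})
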