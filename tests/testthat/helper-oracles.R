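# Independent oracles and tiny fixtures shared across the suite.

# Hypergeometric upper tail by direct enumeration of the mass function,
# independent of stats::phyper.
hyper_tail_enum <- function(k, ks, s0, N) {
  if (ks == 0) {
    return(1)
  }
  i <- ks:k
  sum(choose(s0, i) * choose(N - s0, k - i)) / choose(N, k)
}

# Brute-force module expansion: rescans every node and recomputes every
# candidate p-value from scratch with the enumeration oracle at each step.
# Same tie rule (smaller p, then smaller degree, then gene symbol).
brute_expand <- function(net, seeds, n_iter) {
  nodes <- igraph::V(net)$name
  N <- length(nodes)
  nb_of <- lapply(
    igraph::as_adj_list(net, mode = "all"),
    function(v) nodes[as.integer(v)]
  )
  names(nb_of) <- nodes
  module <- intersect(seeds, nodes)
  added <- character(0)
  for (step in seq_len(n_iter)) {
    best <- NULL
    for (v in sort(setdiff(nodes, module))) {
      nb <- nb_of[[v]]
      ks <- length(intersect(nb, module))
      if (ks == 0) next
      k <- length(nb)
      p <- hyper_tail_enum(k, ks, length(module), N)
      if (is.null(best) ||
        p < best$p ||
        (p == best$p && (k < best$k || (k == best$k && v < best$v)))) {
        best <- list(p = p, k = k, v = v)
      }
    }
    if (is.null(best)) break
    module <- c(module, best$v)
    added <- c(added, best$v)
  }
  added
}

# A clean single-row variant record; override any field via ...
make_record <- function(..., id = "v1", gene = "GENE1",
                        patients = sprintf("P%02d", 1:4),
                        carriers = "P01", genotype = "het",
                        freqs = c(dbA = NA_real_)) {
  rec <- tibble::tibble(
    variant_id = id, chromosome = "1", position = 100L,
    ref_allele = "A", alt_allele = "G", gene_symbol = gene,
    pathogenicity_class = "pathogenic",
    forward_support = 10L, reverse_support = 10L,
    in_repeat_region = FALSE, near_miscall = FALSE,
    conflicting_at_site = FALSE
  )
  for (p in patients) {
    rec[[paste0("gt_", p)]] <- if (p %in% carriers) genotype else "hom_ref"
  }
  for (db in names(freqs)) {
    rec[[paste0("af_", db)]] <- freqs[[db]]
  }
  overrides <- list(...)
  for (nm in names(overrides)) {
    rec[[nm]] <- overrides[[nm]]
  }
  rec
}

# Small undirected test graph from an even-length vertex sequence.
toy_graph <- function(...) {
  igraph::make_graph(c(...), directed = FALSE)
}

# Random connected graph on <= 30 named nodes for oracle-equivalence runs.
random_small_graph <- function(seed, n_min = 8, n_max = 30) {
  withr::with_seed(seed, {
    n <- sample(n_min:n_max, 1)
    g <- igraph::sample_gnp(n, p = min(1, 2.5 / n))
    g <- igraph::simplify(g)
    comp <- igraph::components(g)
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
    igraph::V(g)$name <- sprintf("N%02d", seq_len(igraph::vcount(g)))
    g
  })
}

# Random seed set matched to the degree sequence of a given seed set,
# drawn from outside the excluded genes (nearest available degree).
degree_matched_seeds <- function(net, seeds, exclude, rng_seed) {
  withr::with_seed(rng_seed, {
    deg <- igraph::degree(net)
    pool <- setdiff(igraph::V(net)$name, exclude)
    chosen <- character(0)
    for (s in seeds) {
      gap <- abs(deg[pool] - deg[[s]])
      best <- pool[gap == min(gap)]
      pick <- sample(best, 1)
      chosen <- c(chosen, pick)
      pool <- setdiff(pool, pick)
    }
    chosen
  })
}

# Connected uniform random graph used by permutation-null calibration.
random_gnm_graph <- function(n, m, seed) {
  withr::with_seed(seed, {
    g <- igraph::simplify(igraph::sample_gnm(n, m))
    comp <- igraph::components(g)
    g <- igraph::induced_subgraph(g, comp$membership == which.max(comp$csize))
    igraph::V(g)$name <- sprintf("G%04d", seq_len(igraph::vcount(g)))
    g
  })
}

# Small full scenario used by pipeline-level tests (fast to generate).
small_scenario <- function(rng_seed = 1) {
  synthetic_scenario(
    network_size = 300,
    attachment_parameter = 2,
    planted_modules = list(list(size = 30, density = 0.5)),
    cohort_size = 20,
    pathogenic_gene_count = 12,
    n_pathogenic_variants = 15,
    recurrence_profile = c(rep(2L, 3), rep(1L, 9)),
    n_common_decoys = 2,
    n_filter_decoys = c(
      strand = 1, conflicting = 1, repeat_region = 1,
      near_miscall = 1, no_hom_ref = 1
    ),
    n_benign = 5,
    rng_seed = rng_seed
  )
}
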