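module_gene_vector <- function(module) {
  if (inherits(module, "disease_module")) module$module_genes else unique(module)
}

#' Fold enrichment of a gene set in a disease module
#'
#' Fold enrichment is `(overlap / module_size) / (set_size / universe_size)`
#' — how over-represented the annotation set is among module genes relative
#' to its share of the universe — paired with the cumulative hypergeometric
#' tail `P(X >= overlap)` for `X ~ Hypergeometric(universe_size, set_size,
#' module_size)`. Module genes include the seeds: the disease module is the
#' whole object, seeds plus expansion.
#'
#' Both the module and the set are intersected with the universe first. An
#' empty module or set is degenerate: fold 0, p 1, flagged.
#'
#' @param module A `disease_module` or character vector of genes.
#' @param geneset Character vector of genes.
#' @param universe Character vector, the gene universe (non-empty).
#' @param set_name Label carried into the result.
#' @return One-row tibble: `set`, `overlap`, `module_size`, `set_size`,
#'   `universe_size`, `fold`, `p`, `degenerate`.
#' @export
#' @examples
#' u <- sprintf("G%03d", 1:100)
#' fold_enrichment(u[1:10], u[6:15], u) # overlap 5, fold 5
fold_enrichment <- function(module, geneset, universe, set_name = "set") {
  universe <- unique(universe)
  if (length(universe) == 0) {
    abort("`universe` must be non-empty")
  }
  mod <- intersect(module_gene_vector(module), universe)
  set <- intersect(unique(geneset), universe)
  m <- length(mod)
  s <- length(set)
  u <- length(universe)
  ov <- length(intersect(mod, set))
  degenerate <- m == 0 || s == 0
  if (degenerate) {
    fold <- 0
    p <- 1
  } else {
    fold <- (ov / m) / (s / u)
    p <- phyper(ov - 1, s, u - s, m, lower.tail = FALSE)
  }
  tibble::tibble(
    set = set_name, overlap = ov, module_size = m, set_size = s,
    universe_size = u, fold = fold, p = p, degenerate = degenerate
  )
}

#' Enrichment of a module against every set of a collection
#'
#' One [fold_enrichment()] row per set, with multiple-testing adjustment
#' across the collection (Benjamini-Hochberg by default), sorted by p-value.
#' The universe is the collection's universe; intersect the collection with
#' the network first (see [intersect_with_network()]) when the module comes
#' from network expansion.
#'
#' @param module A `disease_module` or character vector.
#' @param collection A [gene_set_collection()].
#' @param adjust Method for [stats::p.adjust()] (default `"BH"`).
#' @return Tibble of enrichment rows with a `q` column, ordered by `p`.
#' @export
enrich_many <- function(module, collection, adjust = "BH") {
  stopifnot(inherits(collection, "gene_set_collection"))
  res <- purrr::imap(
    collection$sets,
    function(s, nm) fold_enrichment(module, s, collection$universe, set_name = nm)
  )
  res <- dplyr::bind_rows(res)
  res$q <- p.adjust(res$p, method = adjust)
  dplyr::arrange(res, .data$p, .data$set)
}

#' Sets significantly enriched in every one of several modules
#'
#' Cross-cohort support report: runs [enrich_many()] per module and keeps
#' the annotation sets whose adjusted p-value clears `q_max` in all of them
#' — the analogue of graying out terms not supported by every cohort's
#' module in a multi-module enrichment figure.
#'
#' @param modules Named list of `disease_module`s (or gene vectors).
#' @param collection A [gene_set_collection()].
#' @param q_max Adjusted-p threshold (default 0.05).
#' @param adjust Adjustment method (default `"BH"`).
#' @return Tibble of per-module enrichment rows for the supported sets, with
#'   a `module` column; zero rows when no set is supported by all modules.
#' @export
shared_enriched_sets <- function(modules, collection, q_max = 0.05, adjust = "BH") {
  stopifnot(length(modules) > 0, !is.null(names(modules)))
  per_module <- purrr::imap(modules, function(m, nm) {
    dplyr::mutate(enrich_many(m, collection, adjust = adjust), module = nm, .before = 1)
  })
  all_rows <- dplyr::bind_rows(per_module)
  sig <- dplyr::filter(all_rows, .data$q <= q_max)
  supported <- Reduce(
    intersect,
    lapply(split(sig$set, sig$module)[names(modules)], unique)
  )
  dplyr::filter(all_rows, .data$set %in% supported)
}

#' Partition a module and a pathway into intersection classes
#'
#' Splits the union of a disease module and a pathway gene set into
#' module-only, shared, and pathway-only genes, with the network edges
#' induced by the union — the data behind an intersection figure where the
#' shared core is highlighted between the module side and the pathway side.
#'
#' @param module A `disease_module` or character vector.
#' @param pathway Character vector of pathway genes.
#' @param net An igraph network with named vertices.
#' @return List: `module_only`, `shared`, `pathway_only` (sorted character
#'   vectors), `edges` (induced edges tibble on the union), and `membership`
#'   (named vector gene -> class, ready for [write_graphml()]).
#' @export
module_pathway_intersection <- function(module, pathway, net) {
  mod <- unique(module_gene_vector(module))
  pw <- unique(pathway)
  parts <- list(
    module_only = sort(setdiff(mod, pw)),
    shared = sort(intersect(mod, pw)),
    pathway_only = sort(setdiff(pw, mod))
  )
  membership <- setNames(
    rep(names(parts), lengths(parts)),
    unlist(parts, use.names = FALSE)
  )
  c(parts, list(
    edges = induced_edges(net, union(mod, pw)),
    membership = membership
  ))
}

edge_key <- function(edges) paste(edges$from, edges$to, sep = "\r")

#' Edge-Jaccard similarity between two disease modules
#'
#' Similarity of two modules as the Jaccard index of their protein
#' interactions: `J = |E_A intersect E_B| / |E_A union E_B|`, where `E_X`
#' is the edge set of the subgraph induced by module X's genes. Gene-level
#' Jaccard and directional gene overlaps (`|A intersect B| / |A|`, and the
#' reverse) are reported alongside, since the two views can disagree.
#'
#' When both induced edge sets are empty the edge similarity is undefined
#' (`NA` with `undefined = TRUE`), not zero.
#'
#' @param module_a,module_b `disease_module`s or character vectors.
#' @param net An igraph network with named vertices.
#' @param name_a,name_b Labels (default: module labels or `"A"`/`"B"`).
#' @return One-row tibble: `module_a`, `module_b`, `edge_jaccard`,
#'   `gene_jaccard`, `gene_overlap_a`, `gene_overlap_b`, `n_edges_a`,
#'   `n_edges_b`, `undefined`.
#' @export
edge_jaccard <- function(module_a, module_b, net, name_a = NULL, name_b = NULL) {
  label_of <- function(m, fallback) {
    if (inherits(m, "disease_module")) m$label else fallback
  }
  name_a <- name_a %||% label_of(module_a, "A")
  name_b <- name_b %||% label_of(module_b, "B")
  genes_a <- unique(module_gene_vector(module_a))
  genes_b <- unique(module_gene_vector(module_b))
  ea <- edge_key(induced_edges(net, genes_a))
  eb <- edge_key(induced_edges(net, genes_b))
  n_union <- length(union(ea, eb))
  undefined <- n_union == 0
  ej <- if (undefined) NA_real_ else length(intersect(ea, eb)) / n_union
  gu <- length(union(genes_a, genes_b))
  gi <- length(intersect(genes_a, genes_b))
  tibble::tibble(
    module_a = name_a, module_b = name_b,
    edge_jaccard = ej,
    gene_jaccard = if (gu == 0) NA_real_ else gi / gu,
    gene_overlap_a = if (length(genes_a) == 0) NA_real_ else gi / length(genes_a),
    gene_overlap_b = if (length(genes_b) == 0) NA_real_ else gi / length(genes_b),
    n_edges_a = length(ea), n_edges_b = length(eb),
    undefined = undefined
  )
}

#' Rank reference modules by similarity to a query module
#'
#' Sorts a bank of labelled modules (e.g. disease modules expanded from
#' published seed files) by descending edge-Jaccard similarity to the query
#' module; ties break by gene-level Jaccard, then label. Optional category
#' labels (disease groups) are carried through for top-k composition
#' summaries via [category_share()].
#'
#' @param module Query `disease_module` or character vector.
#' @param others Named list of `disease_module`s or gene vectors.
#' @param net An igraph network with named vertices.
#' @param category Optional named character vector of category labels.
#' @return Tibble of [edge_jaccard()] rows with `rank` and (if given)
#'   `category` columns, most similar first.
#' @export
rank_similar <- function(module, others, net, category = NULL) {
  stopifnot(length(others) > 0, !is.null(names(others)))
  rows <- purrr::imap(
    others,
    function(m, nm) edge_jaccard(module, m, net, name_b = nm)
  )
  res <- dplyr::bind_rows(rows)
  res <- dplyr::arrange(
    res,
    dplyr::desc(!is.na(.data$edge_jaccard)),
    dplyr::desc(.data$edge_jaccard),
    dplyr::desc(.data$gene_jaccard),
    .data$module_b
  )
  res <- dplyr::mutate(res, rank = dplyr::row_number(), .before = 1)
  if (!is.null(category)) {
    res$category <- unname(category[res$module_b])
  }
  res
}

#' Category composition of the top of a similarity ranking
#'
#' @param ranked Output of [rank_similar()] with a `category` column.
#' @param top_k How many top modules to summarise (default 20).
#' @return Tibble: `category`, `n`, `share`, descending.
#' @export
category_share <- function(ranked, top_k = 20) {
  stopifnot("category" %in% names(ranked))
  top <- head(ranked, top_k)
  out <- dplyr::count(top, .data$category, name = "n")
  out <- dplyr::mutate(out, share = .data$n / nrow(top))
  dplyr::arrange(out, dplyr::desc(.data$n), .data$category)
}

overlap_statistic <- function(query_genes, ref_genes, statistic, net = NULL) {
  gi <- length(intersect(query_genes, ref_genes))
  switch(statistic,
    directional = if (length(query_genes) == 0) 0 else gi / length(query_genes),
    gene_jaccard = {
      gu <- length(union(query_genes, ref_genes))
      if (gu == 0) 0 else gi / gu
    },
    edge_jaccard = {
      ea <- edge_key(induced_edges(net, query_genes))
      eb <- edge_key(induced_edges(net, ref_genes))
      nu <- length(union(ea, eb))
      if (nu == 0) 0 else length(intersect(ea, eb)) / nu
    }
  )
}

#' Permutation null for module overlap from random seed sets
#'
#' How large is the observed overlap between a query module and a reference
#' module, compared to modules grown from random seeds? Draws `n_perm`
#' uniform seed sets of size `seed_size` from the network nodes, expands
#' each with the same configuration as the query, computes the chosen
#' overlap statistic against the reference, and reports the empirical
#' p-value `(1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' The default statistic is the directional gene overlap
#' `|Q intersect R| / |Q|` (Q the query/null module); gene-level and
#' edge-level Jaccard are available since "overlap" is ambiguous between
#' them — report whichever the analysis states, or both.
#'
#' @param net Connected igraph network with named vertices.
#' @param reference A `disease_module` or gene vector, the fixed reference.
#' @param observed The query `disease_module` (or gene vector) whose overlap
#'   with the reference is being tested.
#' @param seed_size Number of random seeds per null draw (typically the
#'   query's seed count).
#' @param n_iter,alpha Expansion configuration, as in [diamond_expand()].
#' @param n_perm Number of null draws (`>= 1`, default 99).
#' @param rng_seed Integer seed for the null draws.
#' @param statistic `"directional"` (default), `"gene_jaccard"` or
#'   `"edge_jaccard"`.
#' @return A `permutation_null` list: `p`, `observed`, `null` (numeric
#'   vector of length `n_perm`), `statistic`, `seed_size`, `n_perm`.
#' @export
random_seed_null <- function(net, reference, observed, seed_size,
                             n_iter = 200, alpha = 1, n_perm = 99,
                             rng_seed = 1,
                             statistic = c("directional", "gene_jaccard", "edge_jaccard")) {
  statistic <- match.arg(statistic)
  stopifnot(n_perm >= 1)
  nodes <- igraph::V(net)$name
  if (seed_size > length(nodes)) {
    abort("`seed_size` exceeds the number of network nodes")
  }
  ref_genes <- unique(module_gene_vector(reference))
  obs_genes <- unique(module_gene_vector(observed))
  obs_stat <- overlap_statistic(obs_genes, ref_genes, statistic, net)
  compiled <- compile_adjacency(net)
  null_stats <- local_seed(rng_seed, {
    vapply(seq_len(n_perm), function(i) {
      seeds <- sample(nodes, seed_size)
      m <- diamond_expand(compiled, seeds,
        n_iter = n_iter, alpha = alpha,
        label = sprintf("null_%d", i)
      )
      overlap_statistic(m$module_genes, ref_genes, statistic, net)
    }, numeric(1))
  })
  structure(
    list(
      p = (1 + sum(null_stats >= obs_stat)) / (n_perm + 1),
      observed = obs_stat,
      null = null_stats,
      statistic = statistic,
      seed_size = seed_size,
      n_perm = n_perm
    ),
    class = "permutation_null"
  )
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "<permutation_null>  statistic '%s': observed %.4f, null mean %.4f (n_perm = %d), p = %.4g\n",
    x$statistic, x$observed, mean(x$null), x$n_perm, x$p
  ))
  invisible(x)
}

#' @method tidy permutation_null
#' @export
tidy.permutation_null <- function(x, ...) {
  tibble::tibble(draw = seq_along(x$null), statistic = x$null)
}

#' @method glance permutation_null
#' @export
glance.permutation_null <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, observed = x$observed, p = x$p,
    null_mean = mean(x$null), null_max = max(x$null),
    n_perm = x$n_perm, seed_size = x$seed_size
  )
}
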