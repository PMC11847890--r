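#' Connectivity significance of a candidate node
#'
#' The probability that a node of degree `k` has at least `ks` links into a
#' module of size `s0`, in a network of `N` nodes, under random wiring — the
#' upper tail of the hypergeometric distribution:
#' \deqn{p = \sum_{i=ks}^{k} \frac{\binom{s0}{i}\binom{N-s0}{k-i}}{\binom{N}{k}}.}
#'
#' This is the per-step score of the DIAMOnD expansion: at every iteration the
#' candidate with the smallest connectivity p-value is the most surprisingly
#' connected to the current module and is added next. Computed via
#' [stats::phyper()], which works in log-space internally; set `log.p = TRUE`
#' to obtain log tail probabilities directly (used for comparisons, so values
#' below the double underflow threshold still order correctly).
#'
#' @param k Candidate degree (vectorised).
#' @param ks Links from the candidate into the current module (vectorised).
#' @param s0 Current module size.
#' @param N Network size (node count).
#' @param log.p Return the natural log of the tail probability.
#' @return Tail probability in `(0, 1]`; `1` when `ks = 0`.
#' @export
#' @examples
#' connectivity_pvalue(k = 2, ks = 2, s0 = 3, N = 10) # 3/45
connectivity_pvalue <- function(k, ks, s0, N, log.p = FALSE) {
  if (any(ks < 0) || any(ks > pmin(k, s0))) {
    abort("`ks` must satisfy 0 <= ks <= min(k, s0)")
  }
  if (any(k > N - 1)) {
    abort("`k` must be at most N - 1")
  }
  if (s0 < 0 || s0 > N) {
    abort("`s0` must satisfy 0 <= s0 <= N")
  }
  phyper(ks - 1, s0, N - s0, k, lower.tail = FALSE, log.p = log.p)
}

#' Grow a disease module by iterative connectivity significance (DIAMOnD)
#'
#' Starting from the seed genes, repeatedly scores every node adjacent to the
#' current module with [connectivity_pvalue()] and absorbs the node with the
#' smallest p-value, for `n_iter` iterations. The result is the disease
#' module: the seeds plus the ordered expansion, with the per-step p-value of
#' each added gene.
#'
#' Seeds absent from the network are dropped with a message before expansion
#' (the algorithm is defined on the network universe); if no seed remains an
#' error names the dropped genes. Ties in p-value are broken by smaller
#' degree (the more surprising connectivity), then lexicographic gene symbol,
#' so the expansion is a deterministic function of the inputs. p-values are
#' compared on the log scale so that scores far below double underflow still
#' order correctly; exact ties — several `(k, ks)` pairs can yield the same
#' rational tail, e.g. `p = s0/N` — are detected within a `1e-10` relative
#' tolerance before the tie rule applies, since floating evaluation breaks
#' them by last-bit noise otherwise. Only nodes with at least one link to the module are
#' scored: an unlinked node has `ks = 0`, p-value 1, and cannot be selected
#' ahead of any linked node.
#'
#' `alpha > 1` turns on seed weighting as defined for the algorithm: each
#' link to a seed counts `alpha` times, and `s0` and `N` are inflated by
#' `(alpha - 1)` per in-module seed. The default `alpha = 1` is plain
#' unweighted expansion.
#'
#' @param net Connected igraph network with named vertices (apply
#'   [largest_connected_component()] first if needed).
#' @param seeds Character vector of seed gene symbols.
#' @param n_iter Number of genes to add (default 200). Expansion stops early
#'   only if no candidate with a link to the module remains.
#' @param alpha Integer seed weight, `>= 1` (default 1).
#' @param label Provenance label for the module (e.g. the cohort name).
#' @return A `disease_module` object: list with `seeds` (sorted, after
#'   network intersection), `dropped_seeds`, `added` (tibble: `rank`, `gene`,
#'   `degree`, `links_to_module`, `p`, `log_p`), `module_genes`, `label`,
#'   `alpha`, `network_size`.
#' @seealso [tidy.disease_module()], [glance.disease_module()],
#'   [autoplot.disease_module()]
#' @export
diamond_expand <- function(net, seeds, n_iter = 200, alpha = 1, label = "module") {
  stopifnot(n_iter >= 0, alpha >= 1)
  compiled <- if (inherits(net, "igraph")) compile_adjacency(net) else net
  nodes <- compiled$nodes
  if (is.null(nodes)) {
    abort("network vertices must be named with gene symbols")
  }
  seeds <- unique(seeds)
  eff_seeds <- sort(intersect(seeds, nodes))
  dropped <- sort(setdiff(seeds, nodes))
  if (length(eff_seeds) == 0L) {
    abort(c(
      "no seed gene is present in the network",
      "x" = paste("dropped seeds:", paste(dropped, collapse = ", "))
    ))
  }
  if (length(dropped) > 0L) {
    inform(sprintf(
      "%d seed gene(s) not in the network were dropped: %s",
      length(dropped), paste(dropped, collapse = ", ")
    ))
  }

  N <- compiled$N
  idx <- seq_len(N)
  names(idx) <- nodes
  adj <- compiled$adj
  deg <- compiled$deg

  in_module <- logical(N)
  is_seed <- logical(N)
  seed_idx <- idx[eff_seeds]
  in_module[seed_idx] <- TRUE
  is_seed[seed_idx] <- TRUE

  # ks: links into the current module; ks_seed: links to in-module seeds
  ks <- integer(N)
  ks_seed <- integer(N)
  for (si in seed_idx) {
    nb <- adj[[si]]
    ks[nb] <- ks[nb] + 1L
    ks_seed[nb] <- ks_seed[nb] + 1L
  }

  n_seeds <- length(seed_idx)
  w <- alpha - 1
  added_gene <- character(0)
  added_deg <- integer(0)
  added_ks <- integer(0)
  added_logp <- numeric(0)

  s0 <- n_seeds
  for (step in seq_len(n_iter)) {
    cand <- which(!in_module & ks > 0L)
    if (length(cand) == 0L) {
      break
    }
    k_eff <- deg[cand] + w * ks_seed[cand]
    ks_eff <- ks[cand] + w * ks_seed[cand]
    s0_eff <- s0 + w * n_seeds
    N_eff <- N + w * n_seeds
    log_p <- phyper(ks_eff - 1, s0_eff, N_eff - s0_eff, k_eff,
      lower.tail = FALSE, log.p = TRUE
    )
    # exact ties (e.g. p = s0/N arising from several (k, ks) pairs) come out
    # of phyper with last-bit noise; detect them within a relative tolerance
    # on the log scale before applying the degree/symbol tie rule
    min_lp <- min(log_p)
    tied <- which(log_p <= min_lp + 1e-10 * max(1, abs(min_lp)))
    best <- tied[order(deg[cand[tied]], nodes[cand[tied]])[1]]
    pick <- cand[best]
    pick_logp <- log_p[best]

    in_module[pick] <- TRUE
    s0 <- s0 + 1L
    nb <- adj[[pick]]
    ks[nb] <- ks[nb] + 1L
    added_gene <- c(added_gene, nodes[pick])
    added_deg <- c(added_deg, deg[pick])
    added_ks <- c(added_ks, ks[pick])
    added_logp <- c(added_logp, pick_logp)
  }

  added <- tibble::tibble(
    rank = seq_along(added_gene),
    gene = added_gene,
    degree = added_deg,
    links_to_module = added_ks,
    p = exp(added_logp),
    log_p = added_logp
  )
  structure(
    list(
      label = label,
      seeds = eff_seeds,
      dropped_seeds = dropped,
      added = added,
      module_genes = c(eff_seeds, added_gene),
      n_iter = n_iter,
      alpha = alpha,
      network_size = N
    ),
    class = "disease_module"
  )
}

# Flat integer adjacency representation of a named igraph, so repeated
# expansions over one network skip the igraph conversion cost.
compile_adjacency <- function(net) {
  nodes <- igraph::V(net)$name
  adj <- lapply(igraph::as_adj_list(net, mode = "all"), as.integer)
  list(nodes = nodes, adj = adj, deg = lengths(adj), N = length(nodes))
}

#' Expand several labelled seed sets with one configuration
#'
#' Runs [diamond_expand()] once per seed set (e.g. the cohorts of a
#' cross-cohort comparison, or a bank of disease seed files), with identical
#' expansion settings, so the resulting modules are directly comparable.
#'
#' @param net Connected igraph network with named vertices.
#' @param seed_sets Named list of character vectors.
#' @inheritParams diamond_expand
#' @return Named list of `disease_module` objects.
#' @export
expand_all <- function(net, seed_sets, n_iter = 200, alpha = 1) {
  if (length(seed_sets) == 0L) {
    return(setNames(list(), character(0)))
  }
  if (is.null(names(seed_sets)) || anyDuplicated(names(seed_sets))) {
    abort("`seed_sets` must be a uniquely named list")
  }
  compiled <- compile_adjacency(net)
  purrr::imap(
    seed_sets,
    function(s, nm) diamond_expand(compiled, s, n_iter = n_iter, alpha = alpha, label = nm)
  )
}

#' @export
print.disease_module <- function(x, ...) {
  cat(sprintf(
    "<disease_module '%s'>  %d seeds + %d added = %d genes (network N = %d, alpha = %g)\n",
    x$label, length(x$seeds), nrow(x$added), length(x$module_genes),
    x$network_size, x$alpha
  ))
  if (nrow(x$added) > 0) {
    print(head(x$added, 5))
    if (nrow(x$added) > 5) cat(sprintf("# ... with %d more added genes\n", nrow(x$added) - 5))
  }
  invisible(x)
}

#' Tidy a disease module into a per-gene tibble
#'
#' One row per module gene: seeds first (rank `NA`, role `"seed"`), then the
#' expansion in order of addition with each step's connectivity p-value.
#'
#' @param x A `disease_module`.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `role`, `rank`, `degree`,
#'   `links_to_module`, `p`.
#' @method tidy disease_module
#' @export
tidy.disease_module <- function(x, ...) {
  seeds <- tibble::tibble(
    gene = x$seeds,
    role = "seed",
    rank = NA_integer_,
    degree = NA_integer_,
    links_to_module = NA_integer_,
    p = NA_real_
  )
  added <- dplyr::mutate(
    dplyr::select(x$added, "gene", "rank", "degree", "links_to_module", "p"),
    role = "added", .after = "gene"
  )
  dplyr::bind_rows(seeds, added)
}

#' One-row summary of a disease module
#'
#' @param x A `disease_module`.
#' @param ... Unused.
#' @return A tibble with module label, seed/added/total gene counts, the
#'   smallest per-step p-value, and the network size.
#' @method glance disease_module
#' @export
glance.disease_module <- function(x, ...) {
  tibble::tibble(
    label = x$label,
    n_seeds = length(x$seeds),
    n_added = nrow(x$added),
    n_module = length(x$module_genes),
    min_p = if (nrow(x$added) > 0) min(x$added$p) else NA_real_,
    alpha = x$alpha,
    network_size = x$network_size
  )
}

#' Write a disease module as a ranked TSV
#'
#' One row per added gene (`rank`, `gene`, `degree`, `links_to_module`, `p`),
#' mirroring the usual output shape of module-detection runs; seeds are
#' written with rank 0.
#'
#' @param module A `disease_module`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_module_tsv <- function(module, path) {
  seeds <- tibble::tibble(
    rank = 0L, gene = module$seeds,
    degree = NA_integer_, links_to_module = NA_integer_, p = NA_real_
  )
  out <- dplyr::bind_rows(
    seeds,
    dplyr::select(module$added, "rank", "gene", "degree", "links_to_module", "p")
  )
  readr::write_tsv(out, path)
  invisible(path)
}
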