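#' Configure a pipeline run
#'
#' Bundles inputs and stage parameters for [run_pipeline()]. Inputs may be
#' in-memory objects (a variant tibble, an igraph network, a
#' [gene_set_collection()]) or file paths (variant TSV, edge-list TSV, GMT),
#' which are loaded at run time. Defaults are the pipeline's reference
#' settings: odds-ratio threshold 5, recurrence at 2 patients, 200
#' expansion iterations with unweighted seeds.
#'
#' @param variants Variant table tibble or TSV path.
#' @param network igraph network or edge-list path.
#' @param genesets Optional [gene_set_collection()] or GMT path.
#' @param output_dir Optional directory; when given, every stage output is
#'   written there and listed in the manifest.
#' @param threshold Odds-ratio threshold (default 5).
#' @param or_mode `"allele"` or `"carrier"` (see [odds_ratio_filter()]).
#' @param min_patients Recurrence cutoff (default 2).
#' @param n_iter Expansion iterations (default 200).
#' @param alpha Seed weight (default 1).
#' @param n_perm Random-seed permutations for the overlap null; 0 (default)
#'   skips the permutation stage.
#' @param q_max Adjusted-p cutoff used in reporting (default 0.05).
#' @param rng_seed Seed for every stochastic stage (default 1).
#' @param label Module provenance label (default `"cohort"`).
#' @return A validated `run_config` list.
#' @export
run_config <- function(variants, network, genesets = NULL, output_dir = NULL,
                       threshold = 5, or_mode = "allele", min_patients = 2,
                       n_iter = 200, alpha = 1, n_perm = 0, q_max = 0.05,
                       rng_seed = 1, label = "cohort") {
  stopifnot(
    threshold > 0, min_patients >= 1, n_iter >= 0, alpha >= 1,
    n_perm >= 0, q_max > 0, q_max <= 1
  )
  for (input in list(variants, network, genesets)) {
    if (is.character(input) && length(input) == 1 && !file.exists(input)) {
      abort(sprintf("input path does not exist: %s", input))
    }
  }
  structure(
    list(
      variants = variants, network = network, genesets = genesets,
      output_dir = output_dir, threshold = threshold, or_mode = or_mode,
      min_patients = min_patients, n_iter = n_iter, alpha = alpha,
      n_perm = n_perm, q_max = q_max, rng_seed = rng_seed, label = label
    ),
    class = "run_config"
  )
}

config_echo <- function(config) {
  keep <- c(
    "threshold", "or_mode", "min_patients", "n_iter", "alpha",
    "n_perm", "q_max", "rng_seed", "label"
  )
  lapply(unclass(config)[keep], identity)
}

#' Run the full variants-to-module-statistics pipeline
#'
#' Executes the stages in order — high-confidence filtering, restriction to
#' pathogenic/likely-pathogenic records, odds-ratio screening against
#' background frequencies, gene-level aggregation, recurrence counting,
#' seed-set construction, reduction of the network to its largest connected
#' component, DIAMOnD expansion, and (when a collection is supplied)
#' enrichment, plus an optional random-seed overlap null — logging record
#' counts at every boundary. With identical configuration and `rng_seed`
#' the run is bit-reproducible.
#'
#' @param config A [run_config()].
#' @return A `pipeline_run` list: `manifest` (stage counts, config echo,
#'   output paths, package version), `hc` (the [filter_high_confidence()]
#'   result), `or` ([odds_ratio_filter()] result), `gene_hits`,
#'   `recurrent`, `seeds`, `module` (a `disease_module`), `enrichment`
#'   (or `NULL`), `null` (or `NULL`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  records <- if (is.character(config$variants)) {
    read_variant_table(config$variants)
  } else {
    validate_variants(config$variants)
    config$variants
  }
  net <- if (is.character(config$network)) {
    read_edge_list(config$network)
  } else {
    config$network
  }
  collection <- if (is.character(config$genesets)) {
    read_gmt(config$genesets)
  } else {
    config$genesets
  }

  counts <- list(input_variants = nrow(records))
  hc <- filter_high_confidence(records)
  counts$high_confidence <- nrow(hc$retained)
  inform(sprintf(
    "high-confidence filter: %d -> %d", counts$input_variants, counts$high_confidence
  ))

  pathogenic <- pathogenic_subset(hc$retained)
  counts$pathogenic <- nrow(pathogenic)
  or <- odds_ratio_filter(pathogenic, threshold = config$threshold, mode = config$or_mode)
  counts$or_removed <- nrow(or$removed)
  counts$or_retained <- nrow(or$retained)
  inform(sprintf(
    "odds-ratio screen: %d pathogenic -> %d retained (%d removed)",
    counts$pathogenic, counts$or_retained, counts$or_removed
  ))

  gene_hits <- aggregate_to_genes(or$retained)
  counts$genes <- nrow(gene_hits)
  recurrent <- recurrent_genes(gene_hits, min_patients = config$min_patients)
  counts$recurrent_genes <- nrow(recurrent)
  seeds <- build_seed_set(gene_hits)
  counts$seed_genes <- length(seeds)
  inform(sprintf(
    "aggregation: %d genes, %d recurrent (>= %d patients), %d seeds",
    counts$genes, counts$recurrent_genes, config$min_patients, counts$seed_genes
  ))

  lcc <- largest_connected_component(net)
  counts$network_nodes <- igraph::vcount(lcc)
  counts$network_edges <- igraph::ecount(lcc)
  module <- diamond_expand(lcc, seeds,
    n_iter = config$n_iter, alpha = config$alpha, label = config$label
  )
  counts$effective_seeds <- length(module$seeds)
  counts$added_genes <- nrow(module$added)
  counts$module_genes <- length(module$module_genes)
  inform(sprintf(
    "expansion: %d effective seeds + %d added = %d module genes",
    counts$effective_seeds, counts$added_genes, counts$module_genes
  ))

  enrichment <- NULL
  if (!is.null(collection)) {
    enrichment <- enrich_many(module, intersect_with_network(collection, lcc))
    counts$enriched_sets <- sum(enrichment$q <= config$q_max)
  }

  null <- NULL
  if (config$n_perm > 0) {
    null <- random_seed_null(
      lcc,
      reference = module, observed = module,
      seed_size = counts$effective_seeds,
      n_iter = config$n_iter, alpha = config$alpha,
      n_perm = config$n_perm, rng_seed = config$rng_seed
    )
  }

  paths <- list()
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(name) file.path(config$output_dir, name)
    paths$retained_variants <- out("retained_variants.tsv")
    readr::write_tsv(or$retained, paths$retained_variants)
    paths$removed_variants <- out("removed_variants.tsv")
    removed <- dplyr::bind_rows(
      dplyr::mutate(hc$removed, stage = "high_confidence"),
      dplyr::mutate(or$removed, stage = "odds_ratio", filter_reason = "odds_ratio")
    )
    readr::write_tsv(removed, paths$removed_variants)
    paths$filter_report <- out("filter_report.json")
    jsonlite::write_json(
      list(
        input_total = attr(hc$report, "input_total"),
        output_total = attr(hc$report, "output_total"),
        removed = setNames(as.list(hc$report$removed), hc$report$filter)
      ),
      paths$filter_report,
      auto_unbox = TRUE, pretty = TRUE
    )
    paths$gene_hits <- out("gene_hits.tsv")
    readr::write_tsv(
      dplyr::mutate(gene_hits,
        variant_ids = purrr::map_chr(.data$variant_ids, paste, collapse = ","),
        affected_patients = purrr::map_chr(.data$affected_patients, paste, collapse = ",")
      ),
      paths$gene_hits
    )
    paths$module <- out("module.tsv")
    write_module_tsv(module, paths$module)
    if (!is.null(enrichment)) {
      paths$enrichment <- out("enrichment.tsv")
      readr::write_tsv(enrichment, paths$enrichment)
    }
    if (!is.null(null)) {
      paths$null <- out("overlap_null.json")
      jsonlite::write_json(
        glance(null),
        paths$null,
        auto_unbox = TRUE, pretty = TRUE, digits = NA
      )
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("modnet")),
    config = config_echo(config),
    counts = counts,
    outputs = paths
  )
  if (!is.null(config$output_dir)) {
    manifest_path <- file.path(config$output_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
    manifest$outputs$manifest <- manifest_path
  }

  structure(
    list(
      manifest = manifest, hc = hc, or = or, gene_hits = gene_hits,
      recurrent = recurrent, seeds = seeds, module = module,
      enrichment = enrichment, null = null
    ),
    class = "pipeline_run"
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cts <- x$manifest$counts
  cat("<pipeline_run>\n")
  cat(sprintf(
    "  variants: %d in -> %d high-confidence -> %d pathogenic -> %d retained\n",
    cts$input_variants, cts$high_confidence, cts$pathogenic, cts$or_retained
  ))
  cat(sprintf(
    "  genes: %d (%d recurrent), module: %d seeds + %d added\n",
    cts$genes, cts$recurrent_genes, cts$effective_seeds, cts$added_genes
  ))
  invisible(x)
}
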