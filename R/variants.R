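#' @title Cohort variant tables
#' @description
#' A cohort variant table is a tibble with one row per called variant and the
#' columns below. Per-patient genotype calls live in wide columns named
#' `gt_<patient>` with values `hom_ref`, `het`, `hom_alt` or `missing`;
#' per-database background allele frequencies live in columns named
#' `af_<database>` (`NA` = not reported by that database).
#'
#' Required columns: `variant_id`, `chromosome`, `position` (1-based),
#' `ref_allele`, `alt_allele`, `gene_symbol`, `pathogenicity_class`
#' (`pathogenic`, `likely_pathogenic` or `other`), `forward_support`,
#' `reverse_support` (read counts per strand), `in_repeat_region`,
#' `near_miscall`, `conflicting_at_site` (logical flags).
#' @name variant-table
NULL

.variant_required <- c(
  "variant_id", "chromosome", "position", "ref_allele", "alt_allele",
  "gene_symbol", "pathogenicity_class", "forward_support", "reverse_support",
  "in_repeat_region", "near_miscall", "conflicting_at_site"
)
.genotype_levels <- c("hom_ref", "het", "hom_alt", "missing")
.pathogenic_classes <- c("pathogenic", "likely_pathogenic")

genotype_cols <- function(records) grep("^gt_", names(records), value = TRUE)
frequency_cols <- function(records) grep("^af_", names(records), value = TRUE)

#' Validate a cohort variant table
#'
#' Checks the column contract described in [variant-table]: required fields
#' present, positions `>= 1`, background frequencies in `[0, 1]`, genotype
#' values in the four-level code, and at least one `gt_` column.
#'
#' @param records A variant table tibble.
#' @return `records`, invisibly, on success; otherwise an error listing every
#'   offending field.
#' @export
validate_variants <- function(records) {
  problems <- character(0)
  missing_cols <- setdiff(.variant_required, names(records))
  if (length(missing_cols) > 0) {
    problems <- c(problems, paste("missing column(s):", paste(missing_cols, collapse = ", ")))
  }
  gt <- genotype_cols(records)
  if (length(gt) == 0) {
    problems <- c(problems, "no per-patient genotype columns (gt_*)")
  }
  if ("position" %in% names(records) && any(records$position < 1, na.rm = TRUE)) {
    problems <- c(problems, "position must be >= 1 (1-based coordinates)")
  }
  for (fc in frequency_cols(records)) {
    f <- records[[fc]]
    if (any(f < 0 | f > 1, na.rm = TRUE)) {
      problems <- c(problems, sprintf("%s has frequencies outside [0, 1]", fc))
    }
  }
  for (gc in gt) {
    if (!all(records[[gc]] %in% .genotype_levels)) {
      problems <- c(problems, sprintf(
        "%s has genotype values outside {%s}", gc,
        paste(.genotype_levels, collapse = ", ")
      ))
    }
  }
  if (length(problems) > 0) {
    abort(c("invalid variant table", setNames(problems, rep("x", length(problems)))))
  }
  invisible(records)
}

#' Read / write a cohort variant table
#'
#' TSV serialisation of the [variant-table] schema.
#'
#' @param path File path.
#' @return `read_variant_table()` returns a validated tibble;
#'   `write_variant_table()` returns `path` invisibly.
#' @export
read_variant_table <- function(path) {
  records <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  records <- dplyr::mutate(records, dplyr::across(
    dplyr::any_of(c("in_repeat_region", "near_miscall", "conflicting_at_site")),
    as.logical
  ))
  validate_variants(records)
  records
}

#' @rdname read_variant_table
#' @param records A variant table tibble.
#' @export
write_variant_table <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}

#' Flag variants in the proximity of known miscall sites
#'
#' Sets the `near_miscall` flag for variants within `window` base pairs of a
#' recorded miscall position on the same chromosome. The flag is normally an
#' upstream annotation; this reference implementation exists so synthetic and
#' ad-hoc tables can be flagged reproducibly.
#'
#' @param records A variant table.
#' @param miscalls Tibble with columns `chromosome` and `position` (1-based).
#' @param window Distance in bp (default 10).
#' @return `records` with `near_miscall` recomputed.
#' @export
flag_near_miscalls <- function(records, miscalls, window = 10) {
  near <- purrr::map2_lgl(records$chromosome, records$position, function(chr, pos) {
    same <- miscalls$chromosome == chr
    any(abs(miscalls$position[same] - pos) <= window)
  })
  dplyr::mutate(records, near_miscall = near)
}

#' High-confidence variant filtering
#'
#' Applies the five high-confidence filters to a cohort variant table, in
#' order, attributing each removed record to the first filter it fails:
#'
#' 1. `strand` — the call must be supported by reads from both strands
#'    (`forward_support >= 1` and `reverse_support >= 1`);
#' 2. `conflicting` — sites where multiple variant types were called are
#'    excluded (`conflicting_at_site`);
#' 3. `repeat_region` — variants inside repetitive regions are excluded
#'    (`in_repeat_region`, an upstream mask annotation);
#' 4. `near_miscall` — variants in the proximity of miscalls are removed
#'    (`near_miscall`, see [flag_near_miscalls()]);
#' 5. `no_hom_ref` — at least one patient must be homozygous with both
#'    alleles consistent with the reference, guarding against contamination
#'    and systematic artefacts.
#'
#' @param records A variant table (validated on entry).
#' @return A list with class `hc_filter`: `retained` and `removed` variant
#'   tibbles (`removed` carries a `filter_reason` column) and `report`, a
#'   tibble of per-filter removal counts plus input/output totals as
#'   attributes. Counts always balance: `input = output + sum(removed)`.
#' @export
filter_high_confidence <- function(records) {
  validate_variants(records)
  gt <- genotype_cols(records)
  gt_mat <- as.matrix(records[gt])
  has_hom_ref <- if (nrow(records) > 0) {
    rowSums(gt_mat == "hom_ref") > 0
  } else {
    logical(0)
  }

  reason <- rep(NA_character_, nrow(records))
  fails <- list(
    strand = records$forward_support < 1 | records$reverse_support < 1,
    conflicting = records$conflicting_at_site,
    repeat_region = records$in_repeat_region,
    near_miscall = records$near_miscall,
    no_hom_ref = !has_hom_ref
  )
  for (nm in names(fails)) {
    reason[is.na(reason) & fails[[nm]]] <- nm
  }

  retained <- records[is.na(reason), , drop = FALSE]
  removed <- dplyr::mutate(
    records[!is.na(reason), , drop = FALSE],
    filter_reason = reason[!is.na(reason)]
  )
  report <- tibble::tibble(
    filter = names(fails),
    removed = vapply(names(fails), function(nm) sum(reason == nm, na.rm = TRUE), integer(1))
  )
  attr(report, "input_total") <- nrow(records)
  attr(report, "output_total") <- nrow(retained)
  structure(
    list(retained = retained, removed = removed, report = report),
    class = "hc_filter"
  )
}

#' @export
print.hc_filter <- function(x, ...) {
  cat(sprintf(
    "<hc_filter>  %d in, %d retained, %d removed\n",
    attr(x$report, "input_total"), attr(x$report, "output_total"),
    sum(x$report$removed)
  ))
  print(x$report)
  invisible(x)
}

# Cohort alternate-allele count and effective allele number per record.
# Missing genotypes contribute nothing to either count.
cohort_allele_counts <- function(records) {
  gt <- genotype_cols(records)
  gt_mat <- as.matrix(records[gt])
  alt <- rowSums(gt_mat == "het") + 2L * rowSums(gt_mat == "hom_alt")
  total <- 2L * rowSums(gt_mat != "missing")
  carriers <- rowSums(gt_mat == "het" | gt_mat == "hom_alt")
  n_called <- rowSums(gt_mat != "missing")
  tibble::tibble(alt = alt, total = total, carriers = carriers, n_called = n_called)
}

# Odds from a count out of a total, with a Haldane-Anscombe +0.5 continuity
# correction on the implied 2x2 cell pair when either cell is zero.
count_odds <- function(x, total) {
  z <- x == 0 | x == total
  num <- ifelse(z, x + 0.5, x)
  den <- ifelse(z, total - x + 0.5, total - x)
  num / den
}

#' Screen pathogenic variants against background population frequencies
#'
#' Removes variants that are too common relative to background databases: a
#' record is removed iff, for at least one database with a reported
#' frequency, the cohort-versus-background odds ratio falls below
#' `threshold` (default 5, i.e. "odds ratio of less than 5 in any of these
#' comparisons"). Databases with an absent (`NA`) frequency are skipped; a
#' record with no reported frequency anywhere is retained, since no
#' comparison is possible.
#'
#' The odds ratio is `OR = [a / (2n - a)] / [f / (1 - f)]` with `a` the
#' cohort alternate-allele count, `2n` the called allele number and `f` the
#' background allele frequency (`mode = "allele"`, the default). With
#' `mode = "carrier"`, cohort odds use carrier counts (patients with at
#' least one alternate allele out of `n`) against the implied background
#' carrier frequency `1 - (1 - f)^2` under Hardy-Weinberg. Zero cells on the
#' cohort side get the Haldane-Anscombe +0.5 correction; a background
#' frequency of exactly 0 yields an infinite OR (retained) and exactly 1 an
#' OR of 0 (removed), so no division by zero can occur.
#'
#' @param records A variant table, typically restricted to pathogenic /
#'   likely-pathogenic records (see [pathogenic_subset()]).
#' @param threshold Minimum odds ratio to survive (default 5).
#' @param mode `"allele"` (default) or `"carrier"`.
#' @return List with `retained` and `removed` tibbles; `removed` carries
#'   `min_odds_ratio` and `failing_database` columns. Every input row lands
#'   in exactly one of the two.
#' @export
odds_ratio_filter <- function(records, threshold = 5, mode = c("allele", "carrier")) {
  mode <- match.arg(mode)
  validate_variants(records)
  counts <- cohort_allele_counts(records)
  fc <- frequency_cols(records)

  if (mode == "allele") {
    cohort_odds <- count_odds(counts$alt, counts$total)
  } else {
    cohort_odds <- count_odds(counts$carriers, counts$n_called)
  }

  min_or <- rep(Inf, nrow(records))
  failing <- rep(NA_character_, nrow(records))
  for (db in fc) {
    f <- records[[db]]
    if (mode == "carrier") {
      f <- 1 - (1 - f)^2
    }
    bg_odds <- ifelse(f >= 1, Inf, f / (1 - f))
    or <- ifelse(bg_odds == 0, Inf, cohort_odds / bg_odds)
    or[is.na(f)] <- Inf # absent frequency: no comparison for this database
    upd <- !is.na(or) & or < min_or
    min_or[upd] <- or[upd]
    failing[upd & or < threshold & is.na(failing)] <- sub("^af_", "", db)
  }
  fail <- min_or < threshold
  removed <- dplyr::mutate(
    records[fail, , drop = FALSE],
    min_odds_ratio = min_or[fail],
    failing_database = failing[fail]
  )
  list(retained = records[!fail, , drop = FALSE], removed = removed)
}

#' Restrict a variant table to pathogenic and likely-pathogenic records
#'
#' @param records A variant table.
#' @return The subset with `pathogenicity_class` in
#'   `{pathogenic, likely_pathogenic}`.
#' @export
pathogenic_subset <- function(records) {
  dplyr::filter(records, .data$pathogenicity_class %in% .pathogenic_classes)
}

#' Aggregate retained variants to the gene level
#'
#' Collapses a variant table to one row per gene, recording the retained
#' variant ids and the set of affected patients — patients with at least one
#' non-reference genotype (`het` or `hom_alt`) at any retained variant in
#' the gene.
#'
#' @param records A variant table; every record must carry a non-missing
#'   `gene_symbol`.
#' @return A tibble with one row per gene: `gene_symbol`, `n_variants`,
#'   `variant_ids` (list), `affected_patients` (list of patient ids),
#'   `n_patients`.
#' @export
aggregate_to_genes <- function(records) {
  validate_variants(records)
  if (any(is.na(records$gene_symbol) | records$gene_symbol == "")) {
    bad <- records$variant_id[is.na(records$gene_symbol) | records$gene_symbol == ""]
    abort(sprintf(
      "record(s) lacking a gene_symbol: %s", paste(bad, collapse = ", ")
    ))
  }
  gt <- genotype_cols(records)
  patients <- sub("^gt_", "", gt)
  gt_mat <- as.matrix(records[gt])
  carrier_sets <- apply(
    gt_mat == "het" | gt_mat == "hom_alt", 1L,
    function(row) patients[row],
    simplify = FALSE
  )
  tib <- tibble::tibble(
    gene_symbol = records$gene_symbol,
    variant_id = records$variant_id,
    carriers = carrier_sets
  )
  out <- dplyr::summarise(
    dplyr::group_by(tib, .data$gene_symbol),
    n_variants = dplyr::n(),
    variant_ids = list(sort(.data$variant_id)),
    affected_patients = list(sort(unique(unlist(.data$carriers)))),
    .groups = "drop"
  )
  dplyr::arrange(
    dplyr::mutate(out, n_patients = lengths(.data$affected_patients)),
    .data$gene_symbol
  )
}

#' Genes recurrently affected across the cohort
#'
#' Filters gene-level hits to those affecting at least `min_patients`
#' patients (default 2, i.e. 10% of a 20-patient cohort), sorted by
#' descending patient count then gene symbol.
#'
#' @param hits Output of [aggregate_to_genes()].
#' @param min_patients Minimum number of affected patients (`>= 1`).
#' @return The filtered, sorted hits tibble.
#' @export
recurrent_genes <- function(hits, min_patients = 2) {
  stopifnot(min_patients >= 1)
  dplyr::arrange(
    dplyr::filter(hits, .data$n_patients >= min_patients),
    dplyr::desc(.data$n_patients), .data$gene_symbol
  )
}

#' Seed gene set for module expansion
#'
#' All genes housing at least one retained variant — not only the recurrent
#' ones — form the seed input of the network-expansion stage.
#'
#' @param hits Output of [aggregate_to_genes()].
#' @return Sorted character vector of gene symbols.
#' @export
build_seed_set <- function(hits) {
  sort(unique(hits$gene_symbol))
}

#' Map variants to genes through LD-block windows
#'
#' For seed sets built from GWAS-style hits rather than coding variants:
#' a gene is selected when its interval intersects the window
#' `[block_start - window, block_end + window)` around the linkage
#' disequilibrium block of any variant, on the same chromosome. All
#' intervals are 0-based half-open (BED convention); LD blocks are
#' precomputed inputs, not derived here.
#'
#' @param ld_blocks Tibble with columns `chromosome`, `start`, `end`
#'   (one row per variant's LD block).
#' @param gene_intervals Tibble with columns `chromosome`, `start`, `end`,
#'   `gene_symbol`.
#' @param window Radius in bp added on both sides of each block
#'   (default 500000).
#' @return Sorted character vector of gene symbols.
#' @export
map_variants_to_genes <- function(ld_blocks, gene_intervals, window = 500000) {
  stopifnot(window >= 0)
  hit <- purrr::pmap_lgl(
    list(gene_intervals$chromosome, gene_intervals$start, gene_intervals$end),
    function(chr, gs, ge) {
      same <- ld_blocks$chromosome == chr
      any(gs < ld_blocks$end[same] + window & ge > ld_blocks$start[same] - window)
    }
  )
  sort(unique(gene_intervals$gene_symbol[hit]))
}

#' Read a BED file of intervals
#'
#' Minimal three/four-column BED reader (0-based half-open), returning a
#' tibble compatible with [map_variants_to_genes()]; the fourth column, when
#' present, is taken as `gene_symbol`.
#'
#' @param path BED file path.
#' @return Tibble with `chromosome`, `start`, `end` and optionally
#'   `gene_symbol`.
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(
    path,
    col_names = FALSE, comment = "#",
    show_col_types = FALSE, progress = FALSE
  )
  out <- tibble::tibble(
    chromosome = as.character(df[[1]]),
    start = as.numeric(df[[2]]),
    end = as.numeric(df[[3]])
  )
  if (ncol(df) >= 4) {
    out$gene_symbol <- as.character(df[[4]])
  }
  out
}
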