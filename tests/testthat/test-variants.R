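test_that("each high-confidence filter removes its targeted record", {
  records <- dplyr::bind_rows(
    make_record(id = "clean"),
    make_record(id = "one_strand", reverse_support = 0L),
    make_record(id = "conflict", conflicting_at_site = TRUE),
    make_record(id = "repeat", in_repeat_region = TRUE),
    make_record(id = "miscall", near_miscall = TRUE),
    make_record(id = "all_het", carriers = sprintf("P%02d", 1:4))
  )
  res <- filter_high_confidence(records)
  expect_equal(res$retained$variant_id, "clean")
  expect_equal(
    setNames(res$removed$filter_reason, res$removed$variant_id),
    c(
      one_strand = "strand", conflict = "conflicting",
      "repeat" = "repeat_region", miscall = "near_miscall",
      all_het = "no_hom_ref"
    )
  )
})

test_that("removal is attributed to the first failing filter and counts balance", {
  records <- dplyr::bind_rows(
    make_record(id = "multi", reverse_support = 0L, in_repeat_region = TRUE),
    make_record(id = "clean")
  )
  res <- filter_high_confidence(records)
  expect_equal(res$removed$filter_reason, "strand")
  rep <- res$report
  expect_equal(
    attr(rep, "input_total") - sum(rep$removed),
    attr(rep, "output_total")
  )
  expect_equal(nrow(res$retained) + nrow(res$removed), nrow(records))
})

test_that("high-confidence filtering is idempotent and handles empty input", {
  records <- dplyr::bind_rows(
    make_record(id = "a"),
    make_record(id = "b", reverse_support = 0L)
  )
  once <- filter_high_confidence(records)
  twice <- filter_high_confidence(once$retained)
  expect_identical(once$retained, twice$retained)
  expect_equal(sum(twice$report$removed), 0)

  empty <- filter_high_confidence(records[0, ])
  expect_equal(nrow(empty$retained), 0)
  expect_equal(sum(empty$report$removed), 0)
  expect_equal(attr(empty$report, "input_total"), 0)
})

test_that("validation errors name the missing fields", {
  bad <- dplyr::select(make_record(), -forward_support, -gene_symbol)
  expect_error(validate_variants(bad), "forward_support")
  expect_error(validate_variants(bad), "gene_symbol")
  bad_gt <- make_record()
  bad_gt$gt_P01 <- "heterozygous"
  expect_error(validate_variants(bad_gt), "gt_P01")
})

test_that("odds-ratio filter removes records by cohort-vs-background odds", {
  # cohort frequency equal to background: OR = 1 < 5
  equal_f <- make_record(
    id = "eq", patients = sprintf("P%02d", 1:20),
    carriers = sprintf("P%02d", 1:2), freqs = c(dbA = 2 / 40)
  )
  # no database reports a frequency: no comparison possible
  absent <- make_record(
    id = "abs", patients = sprintf("P%02d", 1:20),
    carriers = "P01", freqs = c(dbA = NA_real_)
  )
  # a = 9 of 2n = 40 alleles vs background f = 0.12:
  # OR = (0.225/0.775)/(0.12/0.88) ~= 2.13 < 5
  or_itself <- (9 / 31) / (0.12 / 0.88)
  derived <- make_record(
    id = "der", patients = sprintf("P%02d", 1:20),
    carriers = sprintf("P%02d", 1:9), freqs = c(dbA = 0.12)
  )
  res <- odds_ratio_filter(dplyr::bind_rows(equal_f, absent, derived))
  expect_setequal(res$removed$variant_id, c("eq", "der"))
  expect_equal(res$retained$variant_id, "abs")
  expect_equal(
    res$removed$min_odds_ratio[res$removed$variant_id == "der"],
    or_itself,
    tolerance = 1e-12
  )
  expect_equal(
    res$removed$min_odds_ratio[res$removed$variant_id == "eq"], 1,
    tolerance = 1e-12
  )
})

test_that("odds-ratio filter handles boundary frequencies without dividing by zero", {
  f0 <- make_record(id = "f0", freqs = c(dbA = 0)) # infinitely rare background
  f1 <- make_record(id = "f1", freqs = c(dbA = 1)) # fixed in background
  none <- make_record(id = "none", carriers = character(0), freqs = c(dbA = 0.01))
  res <- odds_ratio_filter(dplyr::bind_rows(f0, f1, none))
  expect_true("f0" %in% res$retained$variant_id)
  expect_true("f1" %in% res$removed$variant_id)
  expect_true(all(is.finite(res$removed$min_odds_ratio)))
})

test_that("odds-ratio filter is monotone in the threshold", {
  withr::with_seed(8, {
    records <- dplyr::bind_rows(lapply(1:30, function(i) {
      make_record(
        id = sprintf("v%02d", i), patients = sprintf("P%02d", 1:20),
        carriers = sample(sprintf("P%02d", 1:20), sample(1:6, 1)),
        freqs = c(dbA = stats::runif(1, 0, 0.2), dbB = stats::runif(1, 0, 0.05))
      )
    }))
  })
  thresholds <- c(1, 2, 5, 10, 50)
  retained_n <- vapply(
    thresholds,
    function(th) nrow(odds_ratio_filter(records, threshold = th)$retained),
    numeric(1)
  )
  expect_true(all(diff(retained_n) <= 0))
  # conservation at every threshold
  for (th in thresholds) {
    res <- odds_ratio_filter(records, threshold = th)
    expect_equal(nrow(res$retained) + nrow(res$removed), nrow(records))
  }
})

test_that("carrier-count mode uses carriers against Hardy-Weinberg background", {
  rec <- make_record(
    id = "c", patients = sprintf("P%02d", 1:20),
    carriers = sprintf("P%02d", 1:9), genotype = "het", freqs = c(dbA = 0.12)
  )
  res <- odds_ratio_filter(rec, mode = "carrier")
  f_carrier <- 1 - (1 - 0.12)^2
  expected <- (9 / 11) / (f_carrier / (1 - f_carrier))
  removed_or <- if (nrow(res$removed) > 0) res$removed$min_odds_ratio else NA
  expect_equal(removed_or, expected, tolerance = 1e-12)
})

test_that("gene aggregation unions affected patients across variants", {
  records <- dplyr::bind_rows(
    make_record(id = "v1", gene = "GENEA", carriers = c("P01", "P02")),
    make_record(id = "v2", gene = "GENEA", carriers = c("P02", "P03")),
    make_record(id = "v3", gene = "GENEB", carriers = "P04", genotype = "hom_alt")
  )
  hits <- aggregate_to_genes(records)
  expect_equal(nrow(hits), 2)
  a <- hits[hits$gene_symbol == "GENEA", ]
  expect_equal(a$affected_patients[[1]], c("P01", "P02", "P03"))
  expect_equal(a$n_variants, 2)
  expect_equal(hits$n_patients[hits$gene_symbol == "GENEB"], 1L)

  expect_equal(nrow(aggregate_to_genes(records[0, ])), 0)
  no_gene <- make_record(id = "vx", gene = NA_character_)
  expect_error(aggregate_to_genes(no_gene), "vx")
})

test_that("recurrent gene selection sorts and thresholds correctly", {
  records <- dplyr::bind_rows(
    make_record(id = "v1", gene = "A", carriers = c("P01", "P02", "P03")),
    make_record(id = "v2", gene = "B", carriers = c("P01", "P02")),
    make_record(id = "v3", gene = "C", carriers = "P01")
  )
  hits <- aggregate_to_genes(records)
  rec2 <- recurrent_genes(hits, min_patients = 2)
  expect_equal(rec2$gene_symbol, c("A", "B"))
  expect_equal(nrow(recurrent_genes(hits, min_patients = 1)), 3)
  expect_equal(build_seed_set(hits), c("A", "B", "C"))
  expect_equal(build_seed_set(hits[0, ]), character(0))
})

test_that("window mapping selects genes by half-open LD-block windows", {
  # block [1.0 Mb, 1.1 Mb) with a 0.5 Mb radius reaches [0.5 Mb, 1.6 Mb)
  blocks <- tibble::tibble(chromosome = "1", start = 1.0e6, end = 1.1e6)
  genes <- tibble::tibble(
    chromosome = c("1", "1", "1", "1", "2"),
    start = c(0.4e6, 0.5e6, 1.55e6, 1.7e6, 1.0e6),
    end = c(0.45e6, 0.55e6, 1.65e6, 1.8e6, 1.1e6),
    gene_symbol = c("TOOFAR_LEFT", "LEFT", "EDGE", "FAR", "OTHERCHR")
  )
  expect_equal(
    map_variants_to_genes(blocks, genes, window = 5e5),
    c("EDGE", "LEFT")
  )
  # gene starting exactly window bp after block end is excluded (half-open)
  boundary <- tibble::tibble(
    chromosome = "1", start = 1.6e6, end = 1.7e6, gene_symbol = "BOUND"
  )
  expect_equal(map_variants_to_genes(blocks, boundary, window = 5e5), character(0))
  # window 0: only genes overlapping the block itself
  overlap <- tibble::tibble(
    chromosome = "1", start = 1.05e6, end = 1.2e6, gene_symbol = "OV"
  )
  expect_equal(map_variants_to_genes(blocks, overlap, window = 0), "OV")
})

test_that("miscall flagging and variant-table IO round-trip", {
  records <- dplyr::bind_rows(
    make_record(id = "near", position = 105L),
    make_record(id = "far", position = 500L)
  )
  miscalls <- tibble::tibble(chromosome = "1", position = 100L)
  flagged <- flag_near_miscalls(records, miscalls, window = 10)
  expect_equal(flagged$near_miscall, c(TRUE, FALSE))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(flagged, path)
  rt <- read_variant_table(path)
  expect_equal(rt$near_miscall, flagged$near_miscall)
  expect_equal(rt$variant_id, flagged$variant_id)
})
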