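#' Describe a synthetic study scenario
#'
#' A scenario bundles every parameter of the synthetic-data generators:
#' an interactome with planted dense modules, a small cohort carrying
#' recurrent rare pathogenic variants over planted genes, background
#' population allele-frequency tables, and annotation collections enriched
#' in the planted modules. Generation is a pure function of `rng_seed` and
#' the parameters, so every downstream recovery test has exact ground truth.
#'
#' The defaults emulate the study design the pipeline targets: a 20-patient
#' severely affected cohort whose pathogenic and likely-pathogenic calls
#' number 103 after high-confidence filtering — 96 genuinely rare records
#' over 93 genes (9 of them affecting at least 2 patients) plus 7
#' common-frequency records that the odds-ratio screen removes — on a
#' scale-free interactome of 2,000 genes with one planted 120-gene module.
#'
#' @param network_size Number of genes in the interactome (>= 10).
#' @param attachment_parameter Edges added per new node during
#'   preferential-attachment growth (default 3).
#' @param planted_modules List of `list(size =, density =)` entries; each
#'   planted module is a node set whose induced subgraph is topped up to at
#'   least `density * choose(size, 2)` edges. `density` in `(0, 1]`.
#' @param cohort_size Number of patients (default 20).
#' @param pathogenic_gene_count Planted-module genes carrying pathogenic
#'   variants (default 93).
#' @param n_pathogenic_variants Total planted pathogenic/likely-pathogenic
#'   records (default 96; the surplus over `pathogenic_gene_count` puts
#'   second variants on the first genes).
#' @param recurrence_profile Integer vector, affected patients per planted
#'   gene (length `pathogenic_gene_count`; default: 9 genes with 2 patients,
#'   the rest with 1).
#' @param n_common_decoys Pathogenic-class records whose background
#'   frequency equals their cohort frequency, so the odds-ratio screen
#'   removes them (default 7).
#' @param n_filter_decoys Named integer vector, decoy records per
#'   high-confidence filter class (`strand`, `conflicting`, `repeat_region`,
#'   `near_miscall`, `no_hom_ref`); each decoy fails exactly its targeted
#'   filter (default 3 each).
#' @param n_benign Clean non-pathogenic background records (default 20).
#' @param background_databases Names of the background frequency tables
#'   (columns `af_<name>`).
#' @param rng_seed Integer seed; all generators derive their streams from it.
#' @return A validated `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(network_size = 2000,
                               attachment_parameter = 3,
                               planted_modules = list(list(size = 120, density = 0.2)),
                               cohort_size = 20,
                               pathogenic_gene_count = 93,
                               n_pathogenic_variants = 96,
                               recurrence_profile = c(rep(2L, 9), rep(1L, 84)),
                               n_common_decoys = 7,
                               n_filter_decoys = c(
                                 strand = 3, conflicting = 3, repeat_region = 3,
                                 near_miscall = 3, no_hom_ref = 3
                               ),
                               n_benign = 20,
                               background_databases = c(
                                 "kaviar", "exac", "g1000", "gnomad", "afc", "pgp"
                               ),
                               rng_seed = 1) {
  stopifnot(
    network_size >= 10, attachment_parameter >= 1, cohort_size >= 1,
    pathogenic_gene_count >= 0, n_pathogenic_variants >= pathogenic_gene_count,
    n_pathogenic_variants <= 2 * pathogenic_gene_count,
    n_common_decoys >= 0, n_benign >= 0,
    length(recurrence_profile) == pathogenic_gene_count,
    length(background_databases) >= 1,
    rng_seed == floor(rng_seed)
  )
  for (pm in planted_modules) {
    if (!all(c("size", "density") %in% names(pm))) {
      abort("each planted module needs `size` and `density`")
    }
    if (pm$size < 2 || pm$size > network_size) {
      abort("planted module size must be in [2, network_size]")
    }
    if (pm$density <= 0 || pm$density > 1) {
      abort("planted module density must be in (0, 1]")
    }
  }
  if (sum(vapply(planted_modules, `[[`, numeric(1), "size")) > network_size) {
    abort("planted modules cannot cover more nodes than the network has")
  }
  if (any(recurrence_profile < 1) || any(recurrence_profile > cohort_size)) {
    abort("recurrence_profile entries must be in [1, cohort_size]")
  }
  filter_classes <- c("strand", "conflicting", "repeat_region", "near_miscall", "no_hom_ref")
  if (!setequal(names(n_filter_decoys), filter_classes)) {
    abort(sprintf(
      "n_filter_decoys must be named with exactly: %s",
      paste(filter_classes, collapse = ", ")
    ))
  }
  structure(
    list(
      network_size = as.integer(network_size),
      attachment_parameter = as.integer(attachment_parameter),
      planted_modules = planted_modules,
      cohort_size = as.integer(cohort_size),
      pathogenic_gene_count = as.integer(pathogenic_gene_count),
      n_pathogenic_variants = as.integer(n_pathogenic_variants),
      recurrence_profile = as.integer(recurrence_profile),
      n_common_decoys = as.integer(n_common_decoys),
      n_filter_decoys = vapply(n_filter_decoys[filter_classes], as.integer, integer(1)),
      n_benign = as.integer(n_benign),
      background_databases = background_databases,
      rng_seed = as.integer(rng_seed)
    ),
    class = "synthetic_scenario"
  )
}

gene_names <- function(n) sprintf("G%0*d", max(4L, nchar(n)), seq_len(n))
patient_ids <- function(n) sprintf("P%02d", seq_len(n))

#' Generate a scale-free interactome with planted dense modules
#'
#' Grows an undirected preferential-attachment backbone (heavy-tailed
#' degrees, connected, simple), then tops up edges inside each planted node
#' set until its induced subgraph reaches the requested internal density.
#' Planted node sets are disjoint, sampled uniformly, and recorded as
#' ground truth: a graph attribute `planted` (named list of gene vectors)
#' and a vertex attribute `planted_module` (module name or `""`).
#'
#' @param scenario A [synthetic_scenario()].
#' @return An igraph network with named vertices (`G0001`, ...).
#' @seealso [planted_modules()]
#' @export
generate_network <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  local_seed(scenario$rng_seed, {
    n <- scenario$network_size
    g <- igraph::sample_pa(n,
      power = 1, m = scenario$attachment_parameter,
      directed = FALSE
    )
    g <- igraph::simplify(g)
    nodes <- gene_names(n)
    igraph::V(g)$name <- nodes

    n_modules <- length(scenario$planted_modules)
    membership <- rep("", n)
    planted <- list()
    if (n_modules > 0) {
      sizes <- vapply(scenario$planted_modules, `[[`, numeric(1), "size")
      pool <- sample.int(n, sum(sizes))
      offset <- 0L
      for (mi in seq_len(n_modules)) {
        pm <- scenario$planted_modules[[mi]]
        members <- sort(pool[(offset + 1):(offset + pm$size)])
        offset <- offset + pm$size
        nm <- sprintf("M%d", mi)
        planted[[nm]] <- nodes[members]
        membership[members] <- nm

        n_pairs <- choose(pm$size, 2)
        target <- ceiling(pm$density * n_pairs)
        if (target > n_pairs) {
          abort(sprintf("planted module %s: density %.3f unachievable", nm, pm$density))
        }
        pairs <- t(utils::combn(members, 2))
        existing <- igraph::get_edge_ids(g, as.vector(t(pairs))) > 0
        deficit <- target - sum(existing)
        if (deficit > 0) {
          free <- which(!existing)
          add <- free[sample.int(length(free), deficit)]
          g <- igraph::add_edges(g, as.vector(t(pairs[add, , drop = FALSE])))
        }
      }
    }
    g <- igraph::set_vertex_attr(g, "planted_module", value = membership)
    g <- igraph::set_graph_attr(g, "planted", planted)
    g
  })
}

#' Ground-truth planted module membership of a synthetic network
#'
#' @param net A network from [generate_network()].
#' @return Named list of gene vectors (empty for networks without planting).
#' @export
planted_modules <- function(net) {
  igraph::graph_attr(net, "planted") %||% list()
}

# A clean variant record template; decoy constructors perturb one field.
blank_records <- function(n, patients, databases, start_id = 1L) {
  rec <- tibble::tibble(
    variant_id = sprintf("v%05d", start_id - 1L + seq_len(n)),
    chromosome = as.character(sample(1:22, n, replace = TRUE)),
    position = sample.int(2.4e8, n, replace = TRUE),
    ref_allele = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt_allele = NA_character_,
    gene_symbol = NA_character_,
    pathogenicity_class = NA_character_,
    forward_support = sample(3:40, n, replace = TRUE),
    reverse_support = sample(3:40, n, replace = TRUE),
    in_repeat_region = FALSE,
    near_miscall = FALSE,
    conflicting_at_site = FALSE
  )
  rec$alt_allele <- vapply(
    rec$ref_allele,
    function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
    character(1)
  )
  for (p in patients) {
    rec[[paste0("gt_", p)]] <- rep("hom_ref", n)
  }
  for (db in databases) {
    rec[[paste0("af_", db)]] <- rep(NA_real_, n)
  }
  rec
}

set_carriers <- function(records, row, carriers, genotype = "het") {
  for (p in carriers) {
    records[[paste0("gt_", p)]][row] <- genotype
  }
  records
}

#' Generate a cohort variant table with attributable decoys
#'
#' Emits the planted pathogenic and likely-pathogenic records on
#' planted-module genes with the scenario's recurrence profile (every
#' variant of a gene is carried, heterozygous, by that gene's assigned
#' patients), at rare background frequencies that survive the odds-ratio
#' screen. Around them it plants decoys designed to fail exactly one stage
#' each, so filter tests are attributable:
#'
#' * one decoy class per high-confidence filter (single-strand support,
#'   conflicting site, repeat region, miscall proximity, no homozygous-
#'   reference patient) — pathogenic-class records that a broken filter
#'   would wrongly pass downstream;
#' * common-frequency decoys whose background allele frequency equals their
#'   cohort frequency (odds ratio 1 < threshold), removed by the
#'   odds-ratio screen;
#' * clean benign background records (class `other`).
#'
#' The `truth_role` column records each row's ground-truth fate
#' (`planted`, `decoy_<filter>`, `decoy_common`, `benign`).
#'
#' @param scenario A [synthetic_scenario()].
#' @param network The matching [generate_network()] output (planted genes
#'   host the pathogenic records; decoys live on other genes).
#' @return A validated [variant-table] tibble with a `truth_role` column.
#' @export
generate_cohort <- function(scenario, network) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  planted_pool <- unlist(planted_modules(network), use.names = FALSE)
  if (scenario$pathogenic_gene_count > length(planted_pool)) {
    abort("pathogenic_gene_count exceeds the number of planted-module genes")
  }
  nodes <- igraph::V(network)$name
  patients <- patient_ids(scenario$cohort_size)
  dbs <- scenario$background_databases
  rare_f <- 5e-4

  local_seed(scenario$rng_seed + 1L, {
    n_genes <- scenario$pathogenic_gene_count
    path_genes <- sample(planted_pool, n_genes)
    # per-gene variant counts: the surplus puts a second variant on the
    # first genes, so variants > genes while recurrence stays per-gene
    extra <- scenario$n_pathogenic_variants - n_genes
    per_gene <- rep(1L, n_genes)
    if (extra > 0) per_gene[seq_len(extra)] <- 2L

    gene_of <- rep(path_genes, per_gene)
    profile_of <- rep(scenario$recurrence_profile, per_gene)
    n_planted <- length(gene_of)

    planted <- blank_records(n_planted, patients, dbs)
    planted$gene_symbol <- gene_of
    planted$pathogenicity_class <- sample(
      c("pathogenic", "likely_pathogenic"), n_planted,
      replace = TRUE
    )
    carriers_by_gene <- setNames(
      lapply(scenario$recurrence_profile, function(r) sample(patients, r)),
      path_genes
    )
    for (i in seq_len(n_planted)) {
      planted <- set_carriers(planted, i, carriers_by_gene[[gene_of[i]]])
    }
    for (db in dbs) {
      planted[[paste0("af_", db)]] <- rep(rare_f, n_planted)
    }
    planted$truth_role <- "planted"

    next_id <- n_planted + 1L
    decoy_genes <- setdiff(nodes, path_genes)

    make_decoys <- function(n, role, class_pool, perturb) {
      if (n == 0) {
        return(NULL)
      }
      d <- blank_records(n, patients, dbs, start_id = next_id)
      next_id <<- next_id + n
      d$gene_symbol <- sample(decoy_genes, n)
      d$pathogenicity_class <- sample(class_pool, n, replace = TRUE)
      for (db in dbs) {
        d[[paste0("af_", db)]] <- rep(rare_f, n)
      }
      for (i in seq_len(n)) {
        d <- set_carriers(d, i, sample(patients, 2))
      }
      d <- perturb(d)
      d$truth_role <- role
      d
    }
    path_pool <- c("pathogenic", "likely_pathogenic")

    common <- make_decoys(
      scenario$n_common_decoys, "decoy_common", path_pool,
      function(d) {
        # background frequency equal to the cohort allele frequency: OR = 1
        f_cohort <- 2 / (2 * scenario$cohort_size)
        for (db in dbs) {
          d[[paste0("af_", db)]] <- rep(f_cohort, nrow(d))
        }
        d
      }
    )
    nf <- scenario$n_filter_decoys
    strand <- make_decoys(
      nf[["strand"]], "decoy_strand", path_pool,
      function(d) dplyr::mutate(d, reverse_support = 0L)
    )
    conflicting <- make_decoys(
      nf[["conflicting"]], "decoy_conflicting", path_pool,
      function(d) dplyr::mutate(d, conflicting_at_site = TRUE)
    )
    repeats <- make_decoys(
      nf[["repeat_region"]], "decoy_repeat_region", path_pool,
      function(d) dplyr::mutate(d, in_repeat_region = TRUE)
    )
    miscall <- make_decoys(
      nf[["near_miscall"]], "decoy_near_miscall", path_pool,
      function(d) dplyr::mutate(d, near_miscall = TRUE)
    )
    no_hom_ref <- make_decoys(
      nf[["no_hom_ref"]], "decoy_no_hom_ref", path_pool,
      function(d) {
        for (i in seq_len(nrow(d))) {
          d <- set_carriers(d, i, patients) # every patient heterozygous
        }
        d
      }
    )
    benign <- make_decoys(
      scenario$n_benign, "benign", "other",
      function(d) {
        for (db in dbs) {
          d[[paste0("af_", db)]] <- stats::runif(nrow(d), 0.01, 0.4)
        }
        d
      }
    )

    records <- dplyr::bind_rows(
      planted, common, strand, conflicting, repeats, miscall, no_hom_ref, benign
    )
    records <- records[sample.int(nrow(records)), , drop = FALSE]
    validate_variants(records)
    records
  })
}

#' Generate annotation gene-set collections with planted enrichment
#'
#' For each planted module the collection gets one enriched set — half of
#' its members sampled from the planted module, half from the rest of the
#' network — plus `decoys_per_module` size-matched sets drawn uniformly
#' from the universe (the network's nodes). By construction the enriched
#' sets overlap their module far above chance while the decoys sit at fold
#' enrichment 1 in expectation.
#'
#' @param scenario A [synthetic_scenario()].
#' @param network The matching [generate_network()] output.
#' @param decoys_per_module Uniform decoy sets per planted module
#'   (default 3).
#' @param enriched_fraction Fraction of an enriched set drawn from its
#'   planted module (default 0.5).
#' @return A [gene_set_collection()]; enriched sets are named
#'   `enriched_M<i>`, decoys `decoy_<j>`.
#' @export
generate_genesets <- function(scenario, network, decoys_per_module = 3,
                              enriched_fraction = 0.5) {
  stopifnot(
    inherits(scenario, "synthetic_scenario"),
    enriched_fraction > 0, enriched_fraction <= 1
  )
  universe <- igraph::V(network)$name
  planted <- planted_modules(network)
  local_seed(scenario$rng_seed + 2L, {
    sets <- list()
    for (nm in names(planted)) {
      members <- planted[[nm]]
      size <- length(members)
      n_in <- round(enriched_fraction * size)
      sets[[paste0("enriched_", nm)]] <- c(
        sample(members, n_in),
        sample(setdiff(universe, members), size - n_in)
      )
      for (j in seq_len(decoys_per_module)) {
        sets[[sprintf("decoy_%s_%d", nm, j)]] <- sample(universe, size)
      }
    }
    gene_set_collection(sets, universe = universe)
  })
}

#' Write every synthetic input of a scenario to disk
#'
#' Materialises the generator outputs in pipeline-readable formats: the
#' edge list (TSV), the cohort variant table (TSV), the annotation
#' collection (GMT) and the ground truth (JSON: planted module membership,
#' per-record truth roles, scenario echo).
#'
#' @param scenario A [synthetic_scenario()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_synthetic_inputs <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  net <- generate_network(scenario)
  cohort <- generate_cohort(scenario, net)
  sets <- generate_genesets(scenario, net)
  paths <- list(
    edge_list = file.path(dir, "edge_list.tsv"),
    variants = file.path(dir, "variants.tsv"),
    genesets = file.path(dir, "genesets.gmt"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  write_edge_list(net, paths$edge_list)
  write_variant_table(cohort, paths$variants)
  write_gmt(sets, paths$genesets)
  truth <- list(
    planted_modules = planted_modules(net),
    truth_roles = setNames(as.list(cohort$truth_role), cohort$variant_id),
    scenario = unclass(scenario)
  )
  jsonlite::write_json(truth, paths$ground_truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
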