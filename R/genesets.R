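#' Construct a gene-set collection
#'
#' A collection holds uniquely named gene sets over a declared universe —
#' the shape of disease-gene association resources and pathway databases.
#' Sets are intersected with the universe at construction, so every
#' downstream statistic is computed on a consistent gene space; an optional
#' category labelling (e.g. disease-ontology groups) supports category
#' summaries of similarity rankings.
#'
#' @param sets Named list of character vectors.
#' @param universe Character vector; defaults to the union of all sets.
#' @param category Optional named character vector, one label per set name.
#' @return A `gene_set_collection`: list with `sets`, `universe`, `category`.
#' @export
gene_set_collection <- function(sets, universe = NULL, category = NULL) {
  if (length(sets) > 0 && (is.null(names(sets)) || any(names(sets) == ""))) {
    abort("every gene set must be named")
  }
  if (anyDuplicated(names(sets))) {
    abort(sprintf(
      "duplicate gene-set name(s): %s",
      paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", ")
    ))
  }
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
  }
  universe <- sort(unique(universe))
  sets <- lapply(sets, function(s) sort(intersect(unique(s), universe)))
  if (!is.null(category)) {
    missing_cat <- setdiff(names(sets), names(category))
    if (length(missing_cat) > 0) {
      abort(sprintf(
        "category labels missing for set(s): %s",
        paste(missing_cat, collapse = ", ")
      ))
    }
    category <- category[names(sets)]
  }
  structure(
    list(sets = sets, universe = universe, category = category),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf(
    "<gene_set_collection>  %d sets over %d universe genes\n",
    length(x$sets), length(x$universe)
  ))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a gene-set collection from a GMT file
#'
#' GMT is the tab-delimited gene-set exchange format: one set per line as
#' `name <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#'
#' @param path GMT file path.
#' @param universe Optional universe (defaults to the union of the sets).
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0) {
    abort(sprintf("GMT line %d has fewer than three fields", short[1]))
  }
  sets <- lapply(fields, function(f) unique(trimws(f[-(1:2)])))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  gene_set_collection(sets, universe = universe)
}

#' Write a gene-set collection as GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @param descriptions Optional named character vector of set descriptions
#'   (defaults to the set name).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  nms <- names(collection$sets)
  desc <- if (is.null(descriptions)) setNames(nms, nms) else descriptions
  lines <- vapply(nms, function(nm) {
    paste(c(nm, desc[[nm]], collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict a collection to a network's gene universe
#'
#' Enrichment against a disease module is defined on the interactome's node
#' set, so annotation collections are intersected with it (genes absent from
#' the network are dropped with a logged count) before any statistic.
#'
#' @param collection A [gene_set_collection()].
#' @param net An igraph network with named vertices.
#' @return A [gene_set_collection()] whose universe is the intersection of
#'   the old universe and the network's nodes.
#' @export
intersect_with_network <- function(collection, net) {
  nodes <- igraph::V(net)$name
  new_universe <- intersect(collection$universe, nodes)
  n_dropped <- length(collection$universe) - length(new_universe)
  if (n_dropped > 0) {
    inform(sprintf("dropped %d universe gene(s) absent from the network", n_dropped))
  }
  gene_set_collection(collection$sets,
    universe = new_universe,
    category = collection$category
  )
}
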