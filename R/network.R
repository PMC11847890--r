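#' Read a protein-protein interaction network from a two-column edge list
#'
#' Parses a tab- or whitespace-separated two-column edge list of gene symbols
#' into an undirected simple graph. Self-loops are dropped and duplicate edges
#' (including reversed duplicates) collapsed, each with an informative message.
#' Symbols are whitespace-trimmed; case is preserved. Lines starting with `#`
#' are ignored, and a first row whose fields look like column labels
#' (`from`/`to`, `source`/`target`, ...) is treated as a header.
#'
#' @param path Path to the edge-list file.
#' @return An [igraph::igraph] object with vertex `name` attributes.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("A\tB", "B\tA", "B\tC"), tf)
#' net <- read_edge_list(tf)
#' igraph::ecount(net) # 2
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    abort("edge list is empty")
  }
  fields <- strsplit(lines, "[\t ]+")
  bad <- which(lengths(fields) < 2L)
  if (length(bad) > 0L) {
    abort(sprintf("edge list line %d does not have two columns", bad[1]))
  }
  from <- trimws(vapply(fields, `[[`, character(1), 1L))
  to <- trimws(vapply(fields, `[[`, character(1), 2L))
  header_tokens <- c(
    "from", "to", "source", "target", "gene1", "gene2",
    "node1", "node2", "protein1", "protein2", "a", "b"
  )
  if (length(from) > 0L &&
      tolower(from[1]) %in% header_tokens && tolower(to[1]) %in% header_tokens) {
    from <- from[-1]
    to <- to[-1]
  }
  edges_to_network(tibble::tibble(from = from, to = to))
}

# Build a simple undirected igraph from a from/to tibble, logging drops.
edges_to_network <- function(edges) {
  loops <- edges$from == edges$to
  if (any(loops)) {
    inform(sprintf("dropped %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to), sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    inform(sprintf("collapsed %d duplicate edge(s)", sum(dup)))
    edges <- edges[!dup, , drop = FALSE]
  }
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

#' Write a network as a two-column edge list
#'
#' @param net An igraph network with named vertices.
#' @param path Output path (TSV, header `from`/`to`).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  df <- tibble::tibble(
    from = pmin(el[, 1], el[, 2]),
    to = pmax(el[, 1], el[, 2])
  )
  df <- dplyr::arrange(df, .data$from, .data$to)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Extract the largest connected component
#'
#' Module expansion and connectivity statistics are defined on a connected
#' interactome, so networks are reduced to their largest connected component
#' first. When several components tie for maximum size, the component
#' containing the lexicographically smallest gene symbol is chosen, making the
#' reduction deterministic.
#'
#' @param net An igraph network with named vertices.
#' @return The induced subgraph on the winning component.
#' @export
largest_connected_component <- function(net) {
  comp <- igraph::components(net)
  if (comp$no == 1L) {
    return(net)
  }
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1L) {
    nodes <- igraph::V(net)$name
    min_member <- vapply(
      cand,
      function(ci) min(nodes[comp$membership == ci]),
      character(1)
    )
    cand <- cand[order(min_member)][1]
  }
  keep <- which(comp$membership == cand[1])
  igraph::induced_subgraph(net, keep)
}

#' Edges of the subgraph induced by a gene set
#'
#' Returns exactly the network edges with both endpoints in `genes` — the
#' interaction set of a disease module, used by the edge-Jaccard similarity.
#'
#' @param net An igraph network with named vertices.
#' @param genes Character vector of gene symbols (symbols absent from the
#'   network are ignored).
#' @return A tibble with columns `from` and `to`, canonically ordered
#'   (`from < to`, rows sorted).
#' @export
induced_edges <- function(net, genes) {
  keep <- intersect(unique(genes), igraph::V(net)$name)
  sub <- igraph::induced_subgraph(net, keep)
  el <- igraph::as_edgelist(sub)
  if (nrow(el) == 0L) {
    return(tibble::tibble(from = character(), to = character()))
  }
  df <- tibble::tibble(from = pmin(el[, 1], el[, 2]), to = pmax(el[, 1], el[, 2]))
  dplyr::arrange(df, .data$from, .data$to)
}

#' Export a network with node and edge attributes as GraphML
#'
#' Supports external rendering of module partitions (for example, the
#' module-only / shared / pathway-only colouring of an intersection figure):
#' any named vectors passed via `node_attrs` are attached as vertex
#' attributes, keyed by gene symbol.
#'
#' @param net An igraph network with named vertices.
#' @param path Output `.graphml` path.
#' @param node_attrs Named list of named character/numeric vectors; each is
#'   attached as a vertex attribute (missing genes get `NA`).
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path, node_attrs = list()) {
  nodes <- igraph::V(net)$name
  for (attr_name in names(node_attrs)) {
    vals <- node_attrs[[attr_name]]
    net <- igraph::set_vertex_attr(net, attr_name, value = unname(vals[nodes]))
  }
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
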