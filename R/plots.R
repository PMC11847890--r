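#' Plot the expansion trajectory of a disease module
#'
#' Connectivity significance of each added gene against its addition step:
#' the signature decay of an expansion, where early additions are tightly
#' wired into the seed subgraph and later ones approach the background.
#'
#' @param object A `disease_module`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot disease_module
#' @export
autoplot.disease_module <- function(object, ...) {
  df <- object$added
  if (nrow(df) == 0) {
    abort("module has no added genes to plot")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = -.data$log_p / log(10))) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "expansion step",
      y = expression(-log[10] ~ "connectivity p-value"),
      title = sprintf("Module expansion: %s", object$label)
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of fold enrichments coloured by p-value
#'
#' The standard enrichment display: one bar per annotation set, bar length
#' the fold enrichment, fill encoding the hypergeometric tail p-value.
#'
#' @param enrichment Output of [enrich_many()] (or rows of
#'   [fold_enrichment()]).
#' @param top_n Show at most this many sets, smallest p first (default 20).
#' @return A ggplot.
#' @export
plot_enrichment <- function(enrichment, top_n = 20) {
  df <- head(dplyr::arrange(enrichment, .data$p), top_n)
  df$set <- factor(df$set, levels = rev(df$set))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$fold, y = .data$set,
    fill = -log10(pmax(.data$p, 1e-300))
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10] ~ p)) +
    ggplot2::labs(x = "fold enrichment", y = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of a permutation null with the observed statistic
#'
#' @param object A `permutation_null` from [random_seed_null()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot permutation_null
#' @export
autoplot.permutation_null <- function(object, ...) {
  df <- tibble::tibble(statistic = object$null)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(
      x = sprintf("overlap statistic (%s)", object$statistic),
      y = "null draws",
      title = sprintf("Random-seed null: p = %.4g", object$p)
    ) +
    ggplot2::theme_minimal()
}
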