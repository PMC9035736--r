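#' Bar chart of per-gene ancestry categories
#'
#' @param gene_summary Per-gene table from [aggregate_gene_ancestry()] or
#'   `tidy(run)`, optionally with a `variant_class` column for faceting.
#' @return A ggplot object.
#' @export
plot_gene_categories <- function(gene_summary) {
  stopifnot(is.data.frame(gene_summary), "category" %in% names(gene_summary))
  p <- ggplot2::ggplot(gene_summary,
                       ggplot2::aes(x = .data$category, fill = .data$category)) +
    ggplot2::geom_bar(show.legend = FALSE) +
    ggplot2::labs(x = "gene ancestry category", y = "genes") +
    ggplot2::theme_minimal()
  if ("variant_class" %in% names(gene_summary)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$variant_class))
  }
  p
}

#' Bar chart of per-site origin assignments
#'
#' @param assignments Site table from [assign_ancestry()] (an `origin`
#'   column; `NA` origins are dropped).
#' @return A ggplot object.
#' @export
plot_origin_counts <- function(assignments) {
  stopifnot(is.data.frame(assignments), "origin" %in% names(assignments))
  d <- assignments[!is.na(assignments$origin), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$origin, fill = .data$origin)) +
    ggplot2::geom_bar(show.legend = FALSE) +
    ggplot2::labs(x = "ancestral origin", y = "sites") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ancestry run
#'
#' @param object An `ancestry_run`.
#' @param type `"genes"` (default) or `"sites"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ancestry_run <- function(object, type = c("genes", "sites"), ...) {
  switch(match.arg(type),
         genes = plot_gene_categories(object$gene_summary),
         sites = plot_origin_counts(object$assignments))
}
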