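#' Venn-cell bar chart of an overlap report
#'
#' @param object An `overlap_report`.
#' @param ... Unused.
#' @return A ggplot of cell sizes, coloured by the number of lineages
#'   sharing the cell.
#' @export
autoplot.overlap_report <- function(object, ...) {
  cells <- object$cells
  ggplot2::ggplot(cells, ggplot2::aes(
    x = stats::reorder(.data$combination, -.data$n), y = .data$n,
    fill = factor(.data$n_lineages)
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "lineage combination", y = "orthogroups", fill = "lineages"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Per-branch gain/loss bar chart
#'
#' @param summary A [branch_summary()] tibble.
#' @return A ggplot of gene gains (up) and losses (down) per branch.
#' @export
plot_branch_summary <- function(summary) {
  long <- tidyr::pivot_longer(
    summary[, c("branch", "gene_gains", "gene_losses")],
    -"branch",
    names_to = "event", values_to = "n"
  )
  long$n <- ifelse(long$event == "gene_losses", -long$n, long$n)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$branch, y = .data$n, fill = .data$event)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "branch", y = "gene gains (+) / losses (-)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
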