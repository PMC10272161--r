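# ggplot2 display methods for the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.al_decoder_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$duration_ms,
                                       y = .data$accuracy)) +
    ggplot2::geom_hline(yintercept = 1 / 6, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Response duration (ms)",
                  y = "Classification accuracy",
                  title = "Odor decoding vs response duration") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.al_trajectories <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                       colour = .data$odor)) +
    ggplot2::geom_path() +
    ggplot2::labs(title = "PN population odor trajectories (PC1-PC2)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.al_clustering <- function(object, ...) {
  d <- object$assignment |>
    count(.data$cluster, .data$truth_label)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$cluster), y = .data$n,
                                  fill = .data$truth_label)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "Cluster", y = "Cells", fill = "True class",
                  title = sprintf("Hierarchical clustering (accuracy %.2f)",
                                  object$accuracy)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.al_ncells_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$n_cells,
                                              y = .data$accuracy)) +
    ggplot2::geom_jitter(width = 0.6, alpha = 0.4) +
    ggplot2::geom_line(data = object$curve,
                       ggplot2::aes(y = .data$mean_accuracy)) +
    ggplot2::labs(x = "Number of cells", y = "Classification accuracy",
                  title = "Decoding accuracy vs population size") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.al_similarity <- function(object, ...) {
  m <- object$zscore_matrix
  d <- as_tibble(as.data.frame(as.table(m)), .name_repair = "minimal")
  names(d) <- c("a", "b", "z")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$a, y = .data$b,
                                  fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = NULL, y = NULL, fill = "z(NBLAST)",
                  title = "Pairwise morphological similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot the per-glomerulus LN innervation fractions
#' @param summary output of [innervation_summary()].
#' @return A ggplot.
#' @export
plot_innervation <- function(summary) {
  ggplot2::ggplot(summary$glomerulus_fractions,
                  ggplot2::aes(x = .data$fraction,
                               y = stats::reorder(.data$glomerulus,
                                                  .data$fraction))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Fraction of LNs innervating", y = NULL,
                  title = "LN innervation of landmark glomeruli") +
    ggplot2::theme_minimal()
}
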