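# ggplot2 methods for result objects.

#' Plot a PCA report
#'
#' Scatter of the first two principal components of the score vectors,
#' coloured by label when labels were supplied to [pca_report()].
#'
#' @param object A `ppap_pca`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ppap_pca <- function(object, ...) {
  df <- as.data.frame(object$scores[, 1:2, drop = FALSE])
  names(df) <- c("PC1", "PC2")
  vf <- object$variance_fraction
  lab <- function(k) sprintf("PC%d (%.1f%%)", k, 100 * vf[k])
  p <- if (!is.null(object$labels)) {
    df$label <- object$labels
    ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                     colour = .data$label))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2))
  }
  p + ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = lab(1L), y = lab(2L), colour = "reaction type") +
    ggplot2::theme_minimal()
}

#' Plot per-type accuracy of a cross-validation report
#'
#' @param object A `ppap_accuracy_report` from [loocv()] or [rrsv()].
#' @param ... Unused.
#' @return A ggplot bar chart of per-group accuracy with counts.
#' @export
autoplot.ppap_accuracy_report <- function(object, ...) {
  df <- object$per_type
  ggplot2::ggplot(df, ggplot2::aes(.data$true_group, .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = paste0(.data$correct, "/", .data$n)), vjust = -0.4) +
    ggplot2::coord_cartesian(ylim = c(0, 1.05)) +
    ggplot2::labs(x = "true group", y = "accuracy",
                  title = paste0(toupper(object$mode), " accuracy ",
                                 round(object$overall_accuracy, 3))) +
    ggplot2::theme_minimal()
}

#' Plot the six-feature score vectors of a prediction table
#'
#' @param predictions Output of [predict.ppap_model()], optionally joined
#'   with a `true_group` column.
#' @return A ggplot of profile score vs correlation score per target type.
#' @export
plot_score_vectors <- function(predictions) {
  feats <- grep("^(hmm|cor)_", names(predictions), value = TRUE)
  long <- predictions |>
    tidyr::pivot_longer(dplyr::all_of(feats),
                        names_to = c("kind", "type"), names_sep = "_",
                        values_to = "score")
  ggplot2::ggplot(long, ggplot2::aes(.data$type, .data$score,
                                     colour = .data$final_label)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::facet_wrap(~ .data$kind, scales = "free_y") +
    ggplot2::labs(x = "target-type model", y = "score",
                  colour = "predicted") +
    ggplot2::theme_minimal()
}
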