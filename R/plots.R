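# ggplot2 visualizations for the main result types.

#' Plot an empirical FDR curve
#'
#' Shows the capped FDR and the q-value (running minimum) against the score
#' threshold.
#'
#' @param object An `fdr_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fdr_curve
#' @export
autoplot.fdr_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("threshold", "fdr", "q")],
    cols = c("fdr", "q"), names_to = "measure", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$value,
                                   colour = .data$measure)) +
    ggplot2::geom_step() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "coding-score threshold", y = "rate",
                  colour = NULL,
                  title = "Empirical FDR against the mock-ORF null") +
    ggplot2::theme_minimal()
}

#' Plot a coding estimate
#'
#' Coding signal above background, S_T (1 - q_T), across thresholds, with
#' the truncation threshold and the corrected estimate annotated.
#'
#' @param object A `coding_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coding_estimate
#' @export
autoplot.coding_estimate <- function(object, ...) {
  curve <- tibble::as_tibble(object$curve)
  curve$signal <- curve$s_t * (1 - curve$q)
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$threshold,
                                           y = .data$signal)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = object$c_corrected, linetype = 2) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = "coding-score threshold",
      y = expression(S[T] * (1 - q[T])),
      title = sprintf("Coding ORFs above background: C' = %.1f +/- %.1f",
                      object$c_corrected, object$ci95)
    ) +
    ggplot2::theme_minimal()
  if (is.finite(object$t_prime)) {
    p <- p + ggplot2::geom_vline(xintercept = object$t_prime, linetype = 3)
  }
  p
}

#' Score densities of sRNA ORFs against the mock background
#'
#' @param analysis An `srna_coding_analysis`.
#' @return A ggplot object.
#' @export
plot_score_densities <- function(analysis) {
  df <- dplyr::bind_rows(
    tibble::tibble(score = analysis$orfs$coding_score, set = "sRNA ORFs"),
    tibble::tibble(score = unname(analysis$mock_scores), set = "mock ORFs")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$set)) +
    ggplot2::geom_density(alpha = 0.4, adjust = 0.7) +
    ggplot2::labs(x = "coding score", y = "density", fill = NULL,
                  title = "Coding scores: sRNA ORFs vs mock background") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
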