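#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_tile
#'   geom_boxplot geom_jitter scale_x_log10 scale_fill_gradient2 labs
#'   theme_minimal
#' @export
ggplot2::autoplot

#' Plot a fitted dose-response curve
#'
#' Observed replicate-averaged viabilities and the fitted four-parameter
#' logistic on a log concentration axis.
#'
#' @param object A `dr_fit` from [fit_4pl()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dr_fit
#' @export
autoplot.dr_fit <- function(object, ...) {
  lab <- paste(object$cell_line, object$drug, sep = " / ")
  ggplot(object$data, aes(x = .data$concentration_M)) +
    geom_point(aes(y = .data$viability)) +
    geom_line(aes(y = .data$fitted), colour = "steelblue") +
    scale_x_log10() +
    labs(
      x = "concentration (M)", y = "viability fraction",
      title = lab,
      subtitle = sprintf("IC50 = %.3g M, AUC(norm) = %.3f, r = %.4f",
                         object$ic50, object$auc_norm, object$fit_r)
    ) +
    theme_minimal()
}

#' Plot the Bliss excess surface of a combination
#'
#' Heatmap of observed-minus-expected inhibition over the combination cells;
#' blue marks antagonism, red synergy.
#'
#' @param object A `synergy_result` from [bliss_synergy_score()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot synergy_result
#' @export
autoplot.synergy_result <- function(object, ...) {
  ggplot(tidy(object),
         aes(x = factor(.data$col_conc_index),
             y = factor(.data$row_conc_index),
             fill = .data$excess)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    labs(
      x = paste(object$drug_col, "dose index"),
      y = paste(object$drug_row, "dose index"),
      fill = "excess (pp)",
      title = sprintf("%s: %s + %s, Bliss score %.2f", object$cell_line,
                      object$drug_row, object$drug_col, object$score)
    ) +
    theme_minimal()
}

#' Boxplot of a per-line measure split by subtype group
#'
#' The standard screen display: one box per group with jittered per-line
#' points, e.g. drug AUC or Bliss score by basal status.
#'
#' @param data Tibble with one row per cell line.
#' @param value,group Columns (tidy-eval) holding the numeric measure and
#'   the group label.
#' @return A ggplot.
#' @export
plot_group_boxplot <- function(data, value, group) {
  ggplot(as_tibble(data), aes(x = {{ group }}, y = {{ value }})) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.6) +
    theme_minimal()
}
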