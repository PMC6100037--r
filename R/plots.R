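# ggplot2 graphics for the main result types

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Observed-versus-fitted plot of an OPLS model
#'
#' @param object An `opls` model.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.opls <- function(object, ...) {
  df <- tibble(observed = object$y, fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$fitted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 2, colour = "#2c7fb8") +
    ggplot2::labs(
      x = "observed liking score", y = "fitted liking score",
      title = sprintf("OPLS %s: R2Y = %.3f",
                      object$n_components_label, object$stats$r2y)) +
    ggplot2::theme_minimal()
}

#' Permutation-validation plot
#'
#' R2Y and Q2Y of every permuted model against the absolute correlation of
#' the permuted response with the original, with the regression lines whose
#' intercepts summarize model validity.
#'
#' @param object An `opls_permutation` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.opls_permutation <- function(object, ...) {
  long <- object$results %>%
    tidyr::pivot_longer(c("r2y", "q2y"), names_to = "statistic",
                        values_to = "value") %>%
    mutate(statistic = toupper(.data$statistic))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$correlation,
                                     y = .data$value,
                                     colour = .data$statistic)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         fullrange = TRUE, linewidth = 0.5) +
    ggplot2::labs(
      x = "|correlation| of permuted response with original",
      y = "statistic",
      title = sprintf("Permutation test (n = %d): Q2 intercept %.3f",
                      object$n_perm, object$q2_intercept)) +
    ggplot2::theme_minimal()
}

#' VIP plot of a fitted liking pipeline
#'
#' Variables ranked by VIP with the greater-than-one selection line.
#'
#' @param pipeline A `liking_pipeline`.
#' @param top Show only the `top` highest-VIP variables (default 30).
#' @return A ggplot.
#' @export
plot_vip <- function(pipeline, top = 30) {
  stopifnot(inherits(pipeline, "liking_pipeline"))
  df <- tidy(pipeline$model) %>%
    arrange(desc(.data$vip)) %>%
    head(top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$variable, .data$vip), y = .data$vip,
    fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "VIP",
                  title = "Variable importance in projection") +
    ggplot2::theme_minimal()
}

#' Heatmap of series values by cultivar
#'
#' @param series_profile Output of [series_values()].
#' @param tissue Tissue to display (default: all, faceted).
#' @return A ggplot.
#' @export
plot_series_heatmap <- function(series_profile, tissue = NULL) {
  df <- summarize_series(series_profile)
  if (!is.null(tissue)) df <- filter(df, .data$tissue %in% !!tissue)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cultivar_id, y = .data$series,
                                   fill = log10(.data$mean_value + 1))) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~tissue) +
    ggplot2::scale_fill_viridis_c(name = "log10(value + 1)") +
    ggplot2::labs(x = "cultivar", y = "aromatic series") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Radial fingerprint plot of a cultivar
#'
#' Primary series as a radial bar chart, pulp and skin side by side, with
#' marked series drawn at their display scale.
#'
#' @param fingerprint An `aroma_fingerprint`.
#' @param level `"primary"` or `"secondary"`.
#' @return A ggplot.
#' @export
plot_fingerprint <- function(fingerprint, level = c("primary", "secondary")) {
  stopifnot(inherits(fingerprint, "aroma_fingerprint"))
  level <- match.arg(level)
  df <- fingerprint[[level]] %>%
    mutate(display_value = .data$value * .data$display_scale)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$series,
                                   y = .data$display_value,
                                   fill = .data$tissue)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_polar() +
    ggplot2::labs(title = sprintf("%s aromatic fingerprint of %s", level,
                                  fingerprint$cultivar_id),
                  x = NULL, y = "series value (sum of OAVs)") +
    ggplot2::theme_minimal()
}
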