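#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Cross-validation curve
#'
#' Mean held-out binomial deviance against `log10(lambda)`, with the
#' selected (minimal-deviance) penalty marked.
#'
#' @param object A `cv_lasso`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cv_lasso
#' @export
autoplot.cv_lasso <- function(object, ...) {
  df <- tidy.cv_lasso(object)
  sel <- select_lambda(object)
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$lambda), y = .data$deviance)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 0.8, color = "steelblue") +
    ggplot2::geom_vline(xintercept = log10(sel), linetype = "dashed") +
    ggplot2::labs(
      x = expression(log[10](lambda)),
      y = "mean CV binomial deviance",
      title = "Penalty selection by cross-validated deviance"
    ) +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a fitted route model
#'
#' Nonzero standardized coefficients, ordered by magnitude.
#'
#' @param object A `splice_lasso`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot splice_lasso
#' @export
autoplot.splice_lasso <- function(object, ...) {
  df <- tidy.splice_lasso(object)
  df <- df[df$term != "(Intercept)" & df$estimate != 0, ]
  df$term <- stats::reorder(df$term, abs(df$estimate))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::labs(
      x = "standardized coefficient", y = NULL,
      title = paste0("Route ", object$route_tag, " model (lambda = ",
                     signif(object$lambda, 3), ")")
    ) +
    ggplot2::theme_minimal()
}

#' Score distribution of a prediction run
#'
#' Histogram of splice-variant scores per route, with each route's
#' decision cutoff marked.
#'
#' @param predictions Tibble from [predict_splice_variants()].
#' @param models The model list used for prediction (for cutoff lines).
#' @return A ggplot.
#' @export
plot_score_distribution <- function(predictions, models = default_models()) {
  df <- dplyr::filter(predictions, !is.na(.data$score))
  cuts <- tibble::tibble(
    model = names(models),
    cutoff = vapply(models, function(m) m$cutoff, numeric(1))
  )
  cuts <- dplyr::filter(cuts, .data$model %in% unique(df$model))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$effect)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.8) +
    ggplot2::geom_vline(
      data = cuts, ggplot2::aes(xintercept = .data$cutoff),
      linetype = "dashed"
    ) +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(
      x = "splice-variant score", y = "variants",
      title = "Score distribution by route model"
    ) +
    ggplot2::theme_minimal()
}
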