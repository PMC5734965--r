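#' Plot the superposition profile of a match
#'
#' Draws the Gaussian superposition F(x) over the hull of the difference
#' centers (rug marks), with the located peak highlighted. A tall, narrow
#' peak means many letter channels agree on one common positional
#' displacement - the signature of a confusable pair.
#'
#' @param object A `lasa_match` from [match_value()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lasa_match
#' @export
autoplot.lasa_match <- function(object, ...) {
  centers <- object$profile$centers
  sigma <- object$profile$sigma
  s <- if (object$profile$square_sigma) sigma^2 else sigma
  pad <- 3 * sqrt(s)
  lo <- if (length(centers)) min(centers) - pad else -pad
  hi <- if (length(centers)) max(centers) + pad else pad
  xs <- seq(lo, hi, length.out = 600)
  fx <- vapply(xs, function(x) sum(exp(-(centers - x)^2 / s)), numeric(1))
  df <- tibble(x = xs, f = fx)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$f)) +
    ggplot2::geom_line() +
    ggplot2::geom_rug(
      data = tibble(x = centers),
      ggplot2::aes(x = .data$x), inherit.aes = FALSE, sides = "b"
    ) +
    ggplot2::geom_point(
      data = tibble(x = object$profile$x_star, f = object$profile$f_star),
      ggplot2::aes(x = .data$x, y = .data$f), colour = "red", size = 2
    ) +
    ggplot2::labs(
      title = sprintf(
        "%s ~ %s: match %.1f%%", object$word, object$input, object$percent
      ),
      subtitle = sprintf(
        "peak %.3f / l_i %s; %s", object$profile$f_star,
        format(object$l_i), params_fingerprint(object$params)
      ),
      x = "positional displacement x", y = "superposition F(x)"
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of match values with risk-band thresholds
#'
#' @param data A scored pair table (from [score_pairs()]), or any data frame
#'   with a percent column.
#' @param percent_col Column of match percentages.
#' @return A ggplot.
#' @export
plot_band_distribution <- function(data, percent_col = "percent") {
  stopifnot(is.data.frame(data))
  if (!percent_col %in% names(data)) {
    abort(sprintf("Column `%s` not found.", percent_col))
  }
  df <- tibble(percent = as.numeric(data[[percent_col]]))
  df <- filter(df, !is.na(.data$percent))
  thresholds <- tibble(cut = c(1, 33, 66), band = c("low", "medium", "high"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$percent)) +
    ggplot2::geom_histogram(binwidth = 5, boundary = 0, closed = "left",
                            fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(
      data = thresholds, ggplot2::aes(xintercept = .data$cut),
      linetype = "dashed"
    ) +
    ggplot2::scale_x_continuous(limits = c(0, 100.5)) +
    ggplot2::labs(
      x = "match value (%)", y = "pairs",
      title = "Match-value distribution with risk-band thresholds"
    ) +
    ggplot2::theme_minimal()
}
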