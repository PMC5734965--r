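#' Confusion-risk bands for match percentages
#'
#' Match values, stated as percentages, are banded into the standard LASA
#' screening thresholds: high for >= 66, medium for >= 33, low for >= 1.
#' Values below 1 fall in a residual band labelled `none`. Boundaries are
#' inclusive at the lower edge of each band, so the bands partition \[0, 100\].
#'
#' @param percent Numeric vector of match percentages in \[0, 100\]. NA is
#'   passed through (a pair with no score has no band).
#' @param thresholds Named ascending vector of lower band edges,
#'   `c(low = 1, medium = 33, high = 66)` by default.
#' @return An ordered factor with levels `none < low < medium < high`.
#' @examples
#' classify_risk(c(77, 45, 66, 0.5))
#' @export
classify_risk <- function(percent, thresholds = c(low = 1, medium = 33, high = 66)) {
  if (!is.numeric(percent)) {
    abort("`percent` must be numeric.")
  }
  if (!is.numeric(thresholds) || length(thresholds) != 3L ||
    !identical(names(thresholds), c("low", "medium", "high")) ||
    is.unsorted(thresholds, strictly = TRUE) ||
    thresholds[[1L]] <= 0 || thresholds[[3L]] > 100) {
    abort("`thresholds` must be c(low, medium, high), strictly ascending within (0, 100].")
  }
  ok <- is.na(percent) | (percent >= 0 & percent <= 100)
  if (!all(ok)) {
    abort(sprintf(
      "Match percentages must lie in [0, 100]; offending value(s): %s",
      paste(format(percent[!ok]), collapse = ", ")
    ))
  }
  lab <- ifelse(percent >= thresholds[["high"]], "high",
    ifelse(percent >= thresholds[["medium"]], "medium",
      ifelse(percent >= thresholds[["low"]], "low", "none")
    )
  )
  factor(lab, levels = c("none", "low", "medium", "high"), ordered = TRUE)
}

#' Summary statistics for a table of scored name pairs
#'
#' Mean and standard deviation of the match values plus risk-band counts, in
#' the form registry audits report them: the mean on the percent scale, the
#' standard deviation on the 0-1 proportion scale. Pairs without a score are
#' counted as missing and excluded from the numeric summaries; their band
#' comes from `band_col` when one is supplied, otherwise they stay unbanded.
#'
#' @param data Data frame with one row per scored pair.
#' @param percent_col Name of the column holding match percentages (NA =
#'   missing score). Default `"percent"`.
#' @param band_col Optional name of a column of risk labels to tabulate
#'   instead of classifying `percent_col` (useful when a table prints its
#'   own ratings, including for unscored rows).
#' @param sd_type `"population"` (divide by n) or `"sample"` (divide by
#'   n - 1).
#' @return One-row tibble: `n`, `n_scored`, `n_missing`, `mean_percent`,
#'   `sd_proportion`, `sd_percent`, `sd_type`, and band counts `n_high`,
#'   `n_medium`, `n_low`, `n_none`.
#' @examples
#' summarize_matches(data.frame(percent = c(50, 100)))
#' @export
summarize_matches <- function(data, percent_col = "percent", band_col = NULL,
                              sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(is.data.frame(data))
  if (!percent_col %in% names(data)) {
    abort(sprintf("Column `%s` not found.", percent_col))
  }
  p <- as.numeric(data[[percent_col]])
  x <- p[!is.na(p)]
  if (length(x) == 0L) {
    abort("No non-missing match values to summarize.")
  }
  if (any(x < 0 | x > 100)) {
    abort("Match percentages must lie in [0, 100].")
  }
  sd_prop <- if (sd_type == "population") {
    sqrt(mean((x - mean(x))^2)) / 100
  } else {
    stats::sd(x) / 100
  }
  bands <- if (!is.null(band_col)) {
    if (!band_col %in% names(data)) {
      abort(sprintf("Column `%s` not found.", band_col))
    }
    factor(tolower(as.character(data[[band_col]])),
      levels = c("none", "low", "medium", "high"), ordered = TRUE
    )
  } else {
    classify_risk(p)
  }
  counts <- table(bands, useNA = "no")
  tibble(
    n = length(p),
    n_scored = length(x),
    n_missing = sum(is.na(p)),
    mean_percent = mean(x),
    sd_proportion = sd_prop,
    sd_percent = 100 * sd_prop,
    sd_type = sd_type,
    n_high = as.integer(counts[["high"]]),
    n_medium = as.integer(counts[["medium"]]),
    n_low = as.integer(counts[["low"]]),
    n_none = as.integer(counts[["none"]])
  )
}
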