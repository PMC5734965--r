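#' Matching conventions for the spatial-coding match value
#'
#' The match-value definition leaves several conventions open: which member of
#' a pair plays the stored word, what counts as a comparison letter in the
#' denominator, whether first/last-letter marker channels are used, and how
#' repeated letters are bound. `match_params()` bundles them. The defaults are
#' the calibrated convention used throughout the package: sigma = 3, end
#' markers on, the first name of a pair as the stored word, denominator =
#' word letters (+2 for the marker channels), in-order occurrence binding,
#' unit descending position code.
#'
#' @param sigma Letter-position uncertainty, the width parameter of the
#'   Gaussian difference functions (dimensionless, in squared letter-position
#'   units as printed in the defining equations, which divide by sigma
#'   itself). Must be positive. Default 3.
#' @param end_markers Logical. When `TRUE`, two extra comparison channels
#'   compare first-vs-first and last-vs-last letters; a channel fires on
#'   letter equality, contributing the end-position activity difference
#'   (0 for equal-length names), and the comparison-letter count gains 2.
#' @param denominator_mode One of `"word"`, `"input"`, `"longer"`,
#'   `"shorter"`, `"mean"`: which letter count normalizes the superposition
#'   peak (plus 2 whenever `end_markers` is on).
#' @param word_role `"first_name"` or `"second_name"`: which member of a pair
#'   is the stored word node (the other is the input string). Default
#'   `"first_name"`, i.e. the local proprietary name in a registry table.
#' @param binding_mode `"in_order"` (k-th occurrence of a letter binds the
#'   k-th occurrence, deterministic) or `"optimal"` (the one-to-one
#'   assignment per letter type that maximizes the match value).
#' @param code_series `"descending_unit"` (position p of an n-letter name
#'   gets activity n - p + 1) or `"ascending_unit"` (activity -p; still a
#'   strictly descending series). The two are equivalent up to a shift of the
#'   difference multiset and yield identical match values.
#' @param square_sigma Logical; when `TRUE` the Gaussian exponent divides by
#'   sigma squared instead of sigma. Off by default: the defining equations
#'   divide by sigma as printed.
#' @return A `lasa_params` list.
#' @examples
#' match_params()
#' match_params(end_markers = FALSE, denominator_mode = "shorter")
#' @export
match_params <- function(sigma = 3,
                         end_markers = TRUE,
                         denominator_mode = c("word", "input", "longer", "shorter", "mean"),
                         word_role = c("first_name", "second_name"),
                         binding_mode = c("in_order", "optimal"),
                         code_series = c("descending_unit", "ascending_unit"),
                         square_sigma = FALSE) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0) {
    abort("`sigma` must be a single positive number.")
  }
  stopifnot(is.logical(end_markers), length(end_markers) == 1L, !is.na(end_markers))
  stopifnot(is.logical(square_sigma), length(square_sigma) == 1L, !is.na(square_sigma))
  structure(
    list(
      sigma = as.numeric(sigma),
      end_markers = end_markers,
      denominator_mode = match.arg(denominator_mode),
      word_role = match.arg(word_role),
      binding_mode = match.arg(binding_mode),
      code_series = match.arg(code_series),
      square_sigma = square_sigma
    ),
    class = "lasa_params"
  )
}

#' @export
print.lasa_params <- function(x, ...) {
  cat("<lasa_params> ", params_fingerprint(x), "\n", sep = "")
  invisible(x)
}

#' One-line fingerprint of a matching convention
#'
#' Used to stamp scored outputs so every result is auditable back to the
#' convention that produced it.
#'
#' @param params A [match_params()] object.
#' @return A single string.
#' @export
params_fingerprint <- function(params) {
  stopifnot(inherits(params, "lasa_params"))
  paste0(
    "sigma=", format(params$sigma),
    if (params$square_sigma) "^2",
    ";markers=", if (params$end_markers) "on" else "off",
    ";denom=", params$denominator_mode,
    ";word=", params$word_role,
    ";bind=", params$binding_mode,
    ";series=", params$code_series
  )
}
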