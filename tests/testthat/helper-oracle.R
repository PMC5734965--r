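# Independent dense-grid oracle for the superposition peak: exhaustive grid
# at step 1e-4 over [min(c) - 5*sigma, max(c) + 5*sigma], followed by local
# refinement with stats::optimize. Pure R, independent of the package's
# bracketing search.
grid_peak_oracle <- function(centers, sigma, square_sigma = FALSE) {
  s <- if (square_sigma) sigma^2 else sigma
  if (length(centers) == 0L) {
    return(list(x_star = NA_real_, f_star = 0))
  }
  f <- function(x) {
    rowSums(exp(-(outer(x, centers, "-"))^2 / s))
  }
  g <- seq(min(centers) - 5 * sigma, max(centers) + 5 * sigma, by = 1e-4)
  fx <- f(g)
  i <- which.max(fx)
  lo <- g[max(1L, i - 1L)]
  hi <- g[min(length(g), i + 1L)]
  ref <- stats::optimize(function(x) f(x), c(lo, hi), maximum = TRUE, tol = 1e-10)
  if (ref$objective >= fx[i]) {
    list(x_star = ref$maximum, f_star = ref$objective)
  } else {
    list(x_star = g[i], f_star = fx[i])
  }
}

# substitute the letters at `positions` of `name` with letters absent from it
substitute_absent <- function(name, positions) {
  x <- strsplit(name, "", fixed = TRUE)[[1]]
  pool <- setdiff(LETTERS, x)
  x[positions] <- pool[seq_along(positions)]
  paste(x, collapse = "")
}

# every matching convention: 80 combinations
all_params_grid <- function() {
  grid <- expand.grid(
    word_role = c("first_name", "second_name"),
    denominator_mode = c("word", "input", "longer", "shorter", "mean"),
    end_markers = c(TRUE, FALSE),
    binding_mode = c("in_order", "optimal"),
    code_series = c("descending_unit", "ascending_unit"),
    stringsAsFactors = FALSE
  )
  lapply(seq_len(nrow(grid)), function(i) {
    match_params(
      end_markers = grid$end_markers[i],
      denominator_mode = grid$denominator_mode[i],
      word_role = grid$word_role[i],
      binding_mode = grid$binding_mode[i],
      code_series = grid$code_series[i]
    )
  })
}
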