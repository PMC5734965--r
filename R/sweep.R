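#' Grid of matching conventions
#'
#' The match-value definition leaves the word role, the denominator, the end
#' markers and the repeated-letter binding open; this grid enumerates their
#' combinations for the reproduction sweep. The two code series are provably
#' equivalent and are not swept.
#'
#' @param word_role,denominator_mode,end_markers,binding_mode Vectors of
#'   admissible values; defaults span the full grid (40 combinations).
#' @param sigma,square_sigma Held fixed across the grid.
#' @return Tibble with one row per convention and a `fingerprint` column.
#' @export
convention_grid <- function(word_role = c("first_name", "second_name"),
                            denominator_mode = c("word", "input", "longer", "shorter", "mean"),
                            end_markers = c(TRUE, FALSE),
                            binding_mode = c("in_order", "optimal"),
                            sigma = 3, square_sigma = FALSE) {
  grid <- tidyr::expand_grid(
    word_role = word_role,
    denominator_mode = denominator_mode,
    end_markers = end_markers,
    binding_mode = binding_mode
  )
  grid$sigma <- sigma
  grid$square_sigma <- square_sigma
  grid$fingerprint <- purrr::pmap_chr(grid, function(...) {
    params_fingerprint(grid_row_params(list(...)))
  })
  grid
}

grid_row_params <- function(row) {
  match_params(
    sigma = row$sigma,
    end_markers = row$end_markers,
    denominator_mode = row$denominator_mode,
    word_role = row$word_role,
    binding_mode = row$binding_mode,
    square_sigma = row$square_sigma
  )
}

#' Rescore a pair table under a grid of conventions
#'
#' Rescores every pair under every convention of the grid, compares computed
#' match percentages with the printed ones where those exist, and ranks the
#' conventions by median absolute deviation. This is the reproduction report
#' for a printed look-alike table: exact row-by-row agreement is not expected
#' (the printed table under-specifies its conventions), so the ranking, not
#' a pass/fail, is the product.
#'
#' @param data Pair table; rows with NA in `printed_col` are scored but
#'   excluded from deviation statistics.
#' @param grid A [convention_grid()].
#' @param name_cols Length-2 names of the name columns.
#' @param printed_col Column of printed match percentages.
#' @return A `lasa_sweep` object: `cells` (one row per pair x convention:
#'   names, computed percent, printed value, deviation), `conventions` (one
#'   row per convention: median/mean absolute deviation over valued rows,
#'   exact-row count on the integer scale, summary stats), and
#'   `best_convention` (fingerprint with the smallest median absolute
#'   deviation; ties broken by mean absolute deviation then grid order).
#' @examples
#' \donttest{
#' sweep_conventions(gotr_pairs(), convention_grid(binding_mode = "in_order"))
#' }
#' @export
sweep_conventions <- function(data, grid = convention_grid(),
                              name_cols = c("local_proprietary", "overseas_similar"),
                              printed_col = "match_percent") {
  stopifnot(is.data.frame(data), nrow(grid) >= 1L)
  if (!printed_col %in% names(data)) {
    abort(sprintf("Column `%s` not found.", printed_col))
  }
  printed <- as.numeric(data[[printed_col]])
  ids <- if ("row_id" %in% names(data)) data$row_id else seq_len(nrow(data))
  cells <- purrr::map_dfr(seq_len(nrow(grid)), function(g) {
    params <- grid_row_params(as.list(grid[g, ]))
    scored <- score_pairs(data, params, name_cols)
    tibble(
      fingerprint = grid$fingerprint[g],
      row_id = ids,
      first_name = as.character(data[[name_cols[1L]]]),
      second_name = as.character(data[[name_cols[2L]]]),
      computed_percent = scored$percent,
      printed_percent = printed,
      abs_dev = abs(scored$percent - printed)
    )
  })
  conventions <- cells |>
    filter(!is.na(.data$printed_percent)) |>
    group_by(.data$fingerprint) |>
    summarise(
      n_valued = n(),
      median_abs_dev = stats::median(.data$abs_dev),
      mean_abs_dev = mean(.data$abs_dev),
      n_exact_integer = sum(round(.data$computed_percent) == .data$printed_percent),
      mean_computed = mean(.data$computed_percent),
      .groups = "drop"
    )
  conventions <- left_join(grid, conventions, by = "fingerprint") |>
    arrange(.data$median_abs_dev, .data$mean_abs_dev)
  structure(
    list(
      cells = cells,
      conventions = conventions,
      best_convention = conventions$fingerprint[1L]
    ),
    class = "lasa_sweep"
  )
}

#' @export
print.lasa_sweep <- function(x, ...) {
  cat("<lasa_sweep> ", nrow(x$conventions), " convention(s), ",
    nrow(x$cells), " scored cells\n", "best: ", x$best_convention, "\n",
    sep = ""
  )
  print(select(
    x$conventions, "fingerprint", "median_abs_dev", "mean_abs_dev",
    "n_exact_integer"
  ), n = 10, ...)
  invisible(x)
}

#' @describeIn sweep_conventions Per-cell tidy table (pair x convention).
#' @param x A `lasa_sweep` object.
#' @param ... Unused.
#' @export
tidy.lasa_sweep <- function(x, ...) x$cells

#' @describeIn sweep_conventions One row for the best convention.
#' @export
glance.lasa_sweep <- function(x, ...) {
  filter(x$conventions, .data$fingerprint == x$best_convention)
}

#' @describeIn sweep_conventions Deviation distribution per convention.
#' @param object A `lasa_sweep` object.
#' @method autoplot lasa_sweep
#' @export
autoplot.lasa_sweep <- function(object, ...) {
  cells <- filter(object$cells, !is.na(.data$printed_percent))
  ord <- object$conventions$fingerprint
  cells$fingerprint <- factor(cells$fingerprint, levels = rev(ord))
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$abs_dev, y = .data$fingerprint)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(
      x = "absolute deviation from printed match value (percent points)",
      y = NULL, title = "Convention sweep: deviation from printed values"
    ) +
    ggplot2::theme_minimal()
}
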