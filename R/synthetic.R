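#' Edit specification for a synthetic name pair
#'
#' Controlled numbers of letter substitutions, adjacent transpositions,
#' insertions and deletions applied to a base name to produce its look-alike
#' variant. The total number of edits must stay below the base length, so a
#' variant always shares structure with its base.
#'
#' @param n_substitutions,n_adjacent_transpositions,n_insertions,n_deletions
#'   Non-negative integer edit counts.
#' @return A `lasa_edit_spec` list.
#' @examples
#' edit_spec(n_substitutions = 2)
#' @export
edit_spec <- function(n_substitutions = 0, n_adjacent_transpositions = 0,
                      n_insertions = 0, n_deletions = 0) {
  counts <- c(
    n_substitutions = n_substitutions,
    n_adjacent_transpositions = n_adjacent_transpositions,
    n_insertions = n_insertions,
    n_deletions = n_deletions
  )
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Edit counts must be non-negative integers.")
  }
  structure(as.list(setNames(as.integer(counts), names(counts))), class = "lasa_edit_spec")
}

total_edits <- function(spec) {
  spec$n_substitutions + spec$n_adjacent_transpositions +
    spec$n_insertions + spec$n_deletions
}

#' @export
print.lasa_edit_spec <- function(x, ...) {
  cat(
    "<lasa_edit_spec> sub=", x$n_substitutions,
    " transp=", x$n_adjacent_transpositions,
    " ins=", x$n_insertions, " del=", x$n_deletions, "\n",
    sep = ""
  )
  invisible(x)
}

#' Random letter-string name
#'
#' Uniform i.i.d. letters A-Z (or sampling without replacement for
#' repeat-free names, which admit closed-form match values under single
#' edits). Deterministic under `seed`.
#'
#' @param length Name length, 1 to 30 (at most 26 when `repeat_free`).
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @param repeat_free Draw letters without replacement.
#' @return A single character string.
#' @examples
#' random_name(8, seed = 1)
#' @export
random_name <- function(length, seed = NULL, repeat_free = FALSE) {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) ||
    length < 1 || length > 30 || length != round(length)) {
    abort("`length` must be a single integer in [1, 30].")
  }
  if (repeat_free && length > 26) {
    abort("A repeat-free name cannot exceed 26 letters.")
  }
  with_opt_seed(seed, random_name_core(as.integer(length), repeat_free))
}

with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

random_name_core <- function(length, repeat_free = FALSE) {
  paste(sample(LETTERS, length, replace = !repeat_free), collapse = "")
}

#' Apply a controlled edit to a base name
#'
#' Edits are applied in a fixed order - deletions, then substitutions, then
#' adjacent transpositions, then insertions - at seed-determined positions.
#' Substituted-in and inserted letters are drawn from letters absent from
#' the base name, so an edit never creates an accidental letter match;
#' substitution and transposition sites are disjoint, and transposed sites
#' do not overlap each other or swap equal letters.
#'
#' @param base Base name (label; canonicalized internally).
#' @param spec An [edit_spec()]; must be feasible for the base length.
#' @param seed Optional integer seed.
#' @return The edited name as a string, with an `edit_log` attribute (tibble
#'   with columns `op`, `position`, `from`, `to` describing each edit in
#'   application order).
#' @examples
#' mutate_name("LOPRAMIDE", edit_spec(n_substitutions = 1), seed = 7)
#' @export
mutate_name <- function(base, spec, seed = NULL) {
  stopifnot(inherits(spec, "lasa_edit_spec"))
  base_canon <- canonicalize(base)
  with_opt_seed(seed, mutate_core(base_canon, spec))
}

mutate_core <- function(base_canon, spec) {
  x <- strsplit(base_canon, "", fixed = TRUE)[[1]]
  n0 <- length(x)
  if (total_edits(spec) > n0 - 1L) {
    abort(sprintf(
      "Infeasible edit spec: %d edits on a %d-letter base (limit %d).",
      total_edits(spec), n0, n0 - 1L
    ))
  }
  pool <- setdiff(LETTERS, x)
  if ((spec$n_substitutions + spec$n_insertions) > 0L && length(pool) == 0L) {
    abort("No letters left outside the base name for substitutions/insertions.")
  }
  log <- list()
  push <- function(op, position, from, to) {
    log[[length(log) + 1L]] <<- tibble(
      op = op, position = as.integer(position),
      from = from, to = to
    )
  }

  if (spec$n_deletions > 0L) {
    del <- sort(sample.int(length(x), spec$n_deletions), decreasing = TRUE)
    for (p in del) {
      push("deletion", p, x[p], NA_character_)
      x <- x[-p]
    }
  }

  touched <- integer(0) # sites no later site-edit may reuse
  if (spec$n_substitutions > 0L) {
    if (length(x) < spec$n_substitutions) abort("Infeasible edit spec: too few positions to substitute.")
    sub_pos <- sample.int(length(x), spec$n_substitutions)
    repl <- sample(pool, spec$n_substitutions, replace = length(pool) < spec$n_substitutions)
    for (k in seq_along(sub_pos)) {
      push("substitution", sub_pos[k], x[sub_pos[k]], repl[k])
      x[sub_pos[k]] <- repl[k]
    }
    touched <- sub_pos
  }

  if (spec$n_adjacent_transpositions > 0L) {
    candidates <- setdiff(seq_len(length(x) - 1L), c(touched, touched - 1L))
    candidates <- candidates[x[candidates] != x[candidates + 1L]]
    for (k in seq_len(spec$n_adjacent_transpositions)) {
      if (length(candidates) == 0L) {
        abort("Infeasible edit spec: no non-overlapping adjacent transposition site left.")
      }
      p <- candidates[sample.int(length(candidates), 1L)]
      push("transposition", p, paste0(x[p], x[p + 1L]), paste0(x[p + 1L], x[p]))
      tmp <- x[p]
      x[p] <- x[p + 1L]
      x[p + 1L] <- tmp
      candidates <- setdiff(candidates, c(p - 1L, p, p + 1L))
    }
  }

  if (spec$n_insertions > 0L) {
    for (k in seq_len(spec$n_insertions)) {
      gap <- sample.int(length(x) + 1L, 1L) - 1L # 0 = before first letter
      letter <- sample(pool, 1L)
      push("insertion", gap + 1L, NA_character_, letter)
      x <- append(x, letter, after = gap)
    }
  }

  out <- paste(x, collapse = "")
  attr(out, "edit_log") <- if (length(log) > 0L) bind_rows(log) else
    tibble(op = character(0), position = integer(0), from = character(0), to = character(0))
  out
}

#' Cohort specification for synthetic pair generation
#'
#' @param n_pairs Number of pairs to generate (>= 1).
#' @param lengths Admissible base lengths (default 5:13, the typical range of
#'   drug proprietary names).
#' @param length_weights Optional sampling weights over `lengths` (default
#'   uniform).
#' @param edit_grid List of [edit_spec()] cells; pairs cycle through the
#'   cells in order so every cell is populated evenly.
#' @param seed Integer seed; a fixed seed makes the cohort fully
#'   reproducible.
#' @param repeat_free Use repeat-free bases (closed-form property cells).
#' @return A `lasa_cohort_spec` list.
#' @export
cohort_spec <- function(n_pairs, lengths = 5:13, length_weights = NULL,
                        edit_grid = list(edit_spec()), seed = 1L,
                        repeat_free = FALSE) {
  if (!is.numeric(n_pairs) || length(n_pairs) != 1L || is.na(n_pairs) || n_pairs < 1) {
    abort("`n_pairs` must be >= 1.")
  }
  if (length(edit_grid) == 0L || !all(vapply(edit_grid, inherits, TRUE, "lasa_edit_spec"))) {
    abort("`edit_grid` must be a non-empty list of edit_spec() objects.")
  }
  if (!is.null(length_weights) && length(length_weights) != length(lengths)) {
    abort("`length_weights` must match `lengths`.")
  }
  structure(
    list(
      n_pairs = as.integer(n_pairs), lengths = as.integer(lengths),
      length_weights = length_weights, edit_grid = edit_grid,
      seed = as.integer(seed), repeat_free = repeat_free
    ),
    class = "lasa_cohort_spec"
  )
}

#' Generate a synthetic cohort of look-alike name pairs
#'
#' Emits a pair table of (base, variant) names spanning the edit grid, with
#' the true edit structure recorded per row so downstream properties (edit
#' monotonicity, transposition leniency) can be asserted against ground
#' truth. Fully reproducible under the cohort seed.
#'
#' @param spec A [cohort_spec()].
#' @return Tibble: `row_id`, `local_proprietary` (base), `overseas_similar`
#'   (variant), `base_length`, `grid_cell`, and the four edit-count columns.
#'   Scores with [score_pairs()] directly; writes with [write_pairs()].
#' @examples
#' generate_cohort(cohort_spec(4, edit_grid = list(edit_spec(n_substitutions = 1)), seed = 2))
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "lasa_cohort_spec"))
  n <- spec$n_pairs
  n_cells <- length(spec$edit_grid)
  base_w <- if (is.null(spec$length_weights)) rep(1, length(spec$lengths)) else spec$length_weights
  bases <- variants <- character(n)
  lens <- integer(n)
  cell_ids <- ((seq_len(n) - 1L) %% n_cells) + 1L
  withr::with_seed(spec$seed, {
    for (k in seq_len(n)) {
      cell <- spec$edit_grid[[cell_ids[k]]]
      ok <- spec$lengths >= total_edits(cell) + 1L
      if (!any(ok)) {
        abort(sprintf("No admissible length can host %d edits.", total_edits(cell)))
      }
      len <- spec$lengths[sample.int(length(spec$lengths), 1L, prob = base_w * ok)]
      # site-level feasibility (e.g. non-overlapping transposition sites)
      # depends on the sampled positions; redraw a bounded number of times
      variant <- NULL
      for (attempt in seq_len(50L)) {
        base <- random_name_core(len, spec$repeat_free)
        variant <- tryCatch(mutate_core(base, cell), error = function(e) NULL)
        if (!is.null(variant)) break
      }
      if (is.null(variant)) {
        abort(sprintf(
          "Could not place %d edits on length-%d bases after 50 draws.",
          total_edits(cell), len
        ))
      }
      bases[k] <- base
      variants[k] <- as.character(variant)
      lens[k] <- len
    }
  })
  counts <- function(field) vapply(spec$edit_grid, `[[`, integer(1), field)[cell_ids]
  tibble(
    row_id = seq_len(n),
    local_proprietary = bases,
    overseas_similar = variants,
    base_length = lens,
    grid_cell = cell_ids,
    n_substitutions = counts("n_substitutions"),
    n_adjacent_transpositions = counts("n_adjacent_transpositions"),
    n_insertions = counts("n_insertions"),
    n_deletions = counts("n_deletions")
  )
}
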