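#' Encode a name as a spatial code
#'
#' Letter position is coded by a monotonically descending activity series:
#' each letter token of an n-letter name receives a position activity. Under
#' the `"descending_unit"` series the token at 1-based ordinal p gets
#' n - p + 1; under `"ascending_unit"` it gets -p (a reflected series, still
#' strictly descending, and equivalent for matching because the difference
#' multiset only shifts).
#'
#' @param name A label or [canonical_name()] object.
#' @param series Code series tag, `"descending_unit"` or `"ascending_unit"`.
#' @return A `lasa_code`: tibble with columns `letter`, `occurrence`,
#'   `position`, `value`, plus attributes `series` and `name`.
#' @examples
#' encode_spatial("CAT")$value # 3 2 1
#' @export
encode_spatial <- function(name, series = c("descending_unit", "ascending_unit")) {
  series <- match.arg(series)
  nm <- as_lasa_name(name)
  out <- tibble(
    letter = nm$letters,
    occurrence = nm$occurrence,
    position = seq_len(nm$length),
    value = code_values(nm$length, series)
  )
  attr(out, "series") <- series
  attr(out, "name") <- nm
  class(out) <- c("lasa_code", class(out))
  out
}

code_values <- function(n, series) {
  if (series == "descending_unit") n - seq_len(n) + 1 else -seq_len(n)
}

# light token structure used by the scoring hot path (no tibbles)
name_tokens <- function(x) {
  nm <- as_lasa_name(x)
  list(letters = nm$letters, occ = nm$occurrence, n = nm$length, canonical = nm$canonical)
}

#' Bind the letter tokens of a stored word to an input string
#'
#' For each letter token of the word, finds at most one input token of the
#' same letter and computes the signal-weight difference
#' d = (input position activity) - (word position activity). Word tokens with
#' no partner are reported unbound: they contribute no Gaussian term but
#' still count as comparison letters. With `end_markers`, two extra channels
#' compare the first and last letters of the two strings; a channel fires
#' only when its letters agree, contributing the end-position activity
#' difference (0 for names of equal length, so that marker centers translate
#' with the letter centers), and the marker pair adds 2 to the
#' comparison-letter count whether or not it fires.
#'
#' @param word,input Labels or [canonical_name()] objects; `word` plays the
#'   stored word node.
#' @param binding_mode `"in_order"`: the k-th occurrence of a letter in the
#'   word binds the k-th occurrence in the input. `"optimal"`: the one-to-one
#'   assignment per letter type that maximizes the superposition peak (and
#'   hence the match value under every denominator convention); on extreme
#'   repeat structure the enumeration is restricted to order-preserving
#'   matchings, then to in-order binding.
#' @param end_markers Logical, see above.
#' @param code_series Position code series (see [encode_spatial()]).
#' @param sigma,square_sigma Gaussian width convention; used only to rank
#'   assignments under `binding_mode = "optimal"`.
#' @return A `lasa_binding`: list with tibble `bound` (letter, occurrence,
#'   word_position, input_position, d), tibble `unbound_word_tokens`, numeric
#'   `marker_differences`, and the comparison-letter count `l_i`.
#' @examples
#' bind_letters("SINIPHEN", "TINYPHEN", end_markers = FALSE)
#' @export
bind_letters <- function(word, input,
                         binding_mode = c("in_order", "optimal"),
                         end_markers = TRUE,
                         code_series = c("descending_unit", "ascending_unit"),
                         sigma = 3, square_sigma = FALSE) {
  binding_mode <- match.arg(binding_mode)
  code_series <- match.arg(code_series)
  w <- name_tokens(word)
  i <- name_tokens(input)
  b <- bind_core(w, i, binding_mode, end_markers, code_series, sigma, square_sigma)
  ub <- b$unbound_idx
  structure(
    list(
      bound = tibble(
        letter = w$letters[b$word_idx],
        occurrence = w$occ[b$word_idx],
        word_position = b$word_idx,
        input_position = b$input_idx,
        d = b$d
      ),
      unbound_word_tokens = tibble(
        letter = w$letters[ub],
        occurrence = w$occ[ub],
        word_position = ub
      ),
      marker_differences = b$marker_differences,
      l_i = w$n + if (end_markers) 2L else 0L
    ),
    class = "lasa_binding"
  )
}

#' @export
print.lasa_binding <- function(x, ...) {
  cat(
    "<lasa_binding> ", nrow(x$bound), " bound, ", nrow(x$unbound_word_tokens),
    " unbound word token(s), ", length(x$marker_differences),
    " marker channel(s), l_i = ", x$l_i, "\n",
    sep = ""
  )
  print(x$bound, ...)
  invisible(x)
}

# Core binding on token lists. Returns word_idx / input_idx / d for bound
# tokens, unbound word token indices, and marker channel differences.
bind_core <- function(w, i, binding_mode, end_markers, code_series,
                      sigma = 3, square_sigma = FALSE) {
  wv <- code_values(w$n, code_series)
  iv <- code_values(i$n, code_series)
  markers <- numeric(0)
  if (end_markers) {
    # a firing marker behaves like a letter channel pinned to the end
    # position: d is the end-position activity difference, which is 0 for
    # equal-length names and translates with the letter centers otherwise
    # (keeping match values invariant to the code-series choice)
    if (w$letters[1L] == i$letters[1L]) markers <- c(markers, iv[1L] - wv[1L])
    if (w$letters[w$n] == i$letters[i$n]) markers <- c(markers, iv[i$n] - wv[w$n])
  }
  if (binding_mode == "in_order") {
    bind_in_order(w, i, wv, iv, markers)
  } else {
    bind_optimal(w, i, wv, iv, markers, sigma, square_sigma)
  }
}

bind_in_order <- function(w, i, wv, iv, markers) {
  idx <- match(
    paste0(w$letters, ".", w$occ),
    paste0(i$letters, ".", i$occ)
  )
  bound <- which(!is.na(idx))
  list(
    word_idx = bound,
    input_idx = idx[bound],
    d = iv[idx[bound]] - wv[bound],
    unbound_idx = which(is.na(idx)),
    marker_differences = markers
  )
}

# Choose, per shared letter type, the injective occurrence matching whose
# joint superposition peaks highest. The comparison-letter count does not
# depend on the assignment, so this maximizes the match value too. For a
# fixed probe x the letter types contribute independently, so the peak over
# joint assignments equals the peak of the upper envelope
#   sum(singles) + sum over types of (best option at x),
# which .peak_envelope() scans without enumerating the joint product.
# Deterministic tie-break: first option in enumeration order. A letter type
# with more than 2000 candidate matchings is restricted to order-preserving
# matchings; past the same bound the whole binding falls back to in-order.
bind_optimal <- function(w, i, wv, iv, markers, sigma, square_sigma) {
  s <- if (square_sigma) sigma^2 else sigma
  shared <- intersect(unique(w$letters), unique(i$letters))
  singles_d <- markers
  fixed_pairs <- NULL
  opt_matchings <- list()
  opt_d <- list()
  for (lt in shared) {
    wp <- which(w$letters == lt)
    ip <- which(i$letters == lt)
    if (length(wp) == 1L && length(ip) == 1L) {
      fixed_pairs <- rbind(fixed_pairs, c(wp, ip))
      singles_d <- c(singles_d, iv[ip] - wv[wp])
    } else {
      matchings <- letter_matchings(wp, ip)
      if (length(matchings) > 2000L) matchings <- letter_matchings_monotone(wp, ip)
      if (length(matchings) > 2000L) {
        return(bind_in_order(w, i, wv, iv, markers))
      }
      m <- nrow(matchings[[1L]])
      dvals <- vapply(
        matchings,
        function(pm) iv[pm[, 2L]] - wv[pm[, 1L]],
        numeric(m)
      )
      k <- length(opt_matchings) + 1L
      opt_matchings[[k]] <- matchings
      opt_d[[k]] <- if (m == 1L) matrix(dvals, ncol = 1L) else t(dvals)
    }
  }
  res <- .peak_envelope(singles_d, opt_d, s)
  chosen <- Map(function(opts, j) opts[[j]], opt_matchings, as.list(res$choice))
  pairs <- do.call(rbind, c(list(fixed_pairs), chosen))
  if (is.null(pairs)) pairs <- matrix(integer(0), ncol = 2L)
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  list(
    word_idx = as.integer(pairs[, 1L]),
    input_idx = as.integer(pairs[, 2L]),
    d = iv[pairs[, 2L]] - wv[pairs[, 1L]],
    unbound_idx = setdiff(seq_len(w$n), pairs[, 1L]),
    marker_differences = markers
  )
}

# combn() treats a length-1 x as seq_len(x); guard against that
combn_safe <- function(x, m) {
  if (length(x) == 1L) list(x) else utils::combn(x, m, simplify = FALSE)
}

# all injective matchings of min(|wp|,|ip|) word occurrences to input
# occurrences of one letter, as two-column (word_pos, input_pos) matrices
letter_matchings <- function(wp, ip) {
  m <- min(length(wp), length(ip))
  wsub <- combn_safe(wp, m)
  isub <- combn_safe(ip, m)
  perms <- permutations(m)
  out <- list()
  for (ws in wsub) {
    for (is in isub) {
      for (p in seq_len(nrow(perms))) {
        out[[length(out) + 1L]] <- cbind(ws, is[perms[p, ]])
      }
    }
  }
  out
}

# order-preserving matchings only: choose(a,m) * choose(b,m) per letter
letter_matchings_monotone <- function(wp, ip) {
  m <- min(length(wp), length(ip))
  wsub <- combn_safe(wp, m)
  isub <- combn_safe(ip, m)
  out <- list()
  for (ws in wsub) {
    for (is in isub) {
      out[[length(out) + 1L]] <- cbind(ws, is)
    }
  }
  out
}

permutations <- function(m) {
  if (m == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  sub <- permutations(m - 1L)
  out <- matrix(0L, nrow = m * nrow(sub), ncol = m)
  r <- 1L
  for (k in seq_len(m)) {
    rest <- seq_len(m)[-k]
    for (j in seq_len(nrow(sub))) {
      out[r, ] <- c(k, rest[sub[j, ]])
      r <- r + 1L
    }
  }
  out
}

#' Peak of a Gaussian superposition
#'
#' Finds the global maximum of `F(x) = sum_j exp(-(c_j - x)^2 / sigma)` over
#' the reals. All Gaussians share one width, so the maximum lies within the
#' convex hull of the centers; it is located by a bracketing grid (step
#' 0.02 * sqrt(sigma)) with golden-section refinement to machine-level
#' tolerance, the smallest maximizer winning ties.
#'
#' @param centers Numeric vector of difference-function centers (the d
#'   values). May be empty, in which case the peak value is 0.
#' @param sigma Positive width parameter.
#' @param square_sigma Divide the exponent by sigma squared instead of sigma.
#' @return A list with `x_star` (location; NA for empty centers) and
#'   `f_star` (peak value).
#' @examples
#' find_peak(c(0, 1), sigma = 3) # x_star 0.5, f_star 2 * exp(-1/12)
#' @export
find_peak <- function(centers, sigma = 3, square_sigma = FALSE) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0) {
    abort("`sigma` must be a single positive number.")
  }
  stopifnot(is.numeric(centers), !anyNA(centers))
  s <- if (square_sigma) sigma^2 else sigma
  res <- .peak_superposition(as.numeric(centers), s)
  list(x_star = res[1L], f_star = res[2L])
}

#' Spatial-coding match value of a pair of names
#'
#' The full match computation: assign word/input roles, encode both names,
#' bind letter tokens, superpose a Gaussian difference function per bound
#' channel (marker channels included), find the superposition peak, and
#' normalize by the comparison-letter count. The result lies in \[0, 1\] by
#' construction and is conventionally reported as a percentage.
#'
#' @param name_a,name_b Labels or [canonical_name()] objects. Which one plays
#'   the stored word is set by `params$word_role` (default: `name_a`).
#' @param params A [match_params()] convention bundle.
#' @return A `lasa_match` object: `value` (in \[0, 1\]), `percent`, `params`,
#'   `profile` (centers, sigma, peak location and value), `binding`, `l_i`.
#' @examples
#' match_value("TINYPHEN®", "SINIPHEN")$percent # 70
#' @export
match_value <- function(name_a, name_b, params = match_params()) {
  stopifnot(inherits(params, "lasa_params"))
  a <- name_tokens(name_a)
  b <- name_tokens(name_b)
  core <- match_core(a, b, params)
  w <- if (params$word_role == "first_name") a else b
  i <- if (params$word_role == "first_name") b else a
  binding <- structure(
    list(
      bound = tibble(
        letter = w$letters[core$word_idx],
        occurrence = w$occ[core$word_idx],
        word_position = core$word_idx,
        input_position = core$input_idx,
        d = core$d
      ),
      unbound_word_tokens = tibble(
        letter = w$letters[core$unbound_idx],
        occurrence = w$occ[core$unbound_idx],
        word_position = core$unbound_idx
      ),
      marker_differences = core$marker_differences,
      l_i = core$l_i
    ),
    class = "lasa_binding"
  )
  structure(
    list(
      value = core$value,
      percent = 100 * core$value,
      params = params,
      profile = list(
        centers = core$centers,
        sigma = params$sigma,
        square_sigma = params$square_sigma,
        x_star = core$x_star,
        f_star = core$f_star
      ),
      binding = binding,
      l_i = core$l_i,
      word = w$canonical,
      input = i$canonical
    ),
    class = "lasa_match"
  )
}

# hot path shared by match_value() and the vectorized scorer
match_core <- function(a, b, params) {
  if (params$word_role == "first_name") {
    w <- a
    i <- b
  } else {
    w <- b
    i <- a
  }
  bc <- bind_core(
    w, i, params$binding_mode, params$end_markers, params$code_series,
    params$sigma, params$square_sigma
  )
  centers <- c(bc$d, bc$marker_differences)
  s <- if (params$square_sigma) params$sigma^2 else params$sigma
  pk <- .peak_superposition(centers, s)
  l_i <- switch(params$denominator_mode,
    word = w$n,
    input = i$n,
    longer = max(w$n, i$n),
    shorter = min(w$n, i$n),
    mean = (w$n + i$n) / 2
  ) + if (params$end_markers) 2 else 0
  c(bc, list(
    centers = centers, x_star = pk[1L], f_star = pk[2L],
    l_i = l_i, value = pk[2L] / l_i
  ))
}

# Vectorized percent scores for parallel name vectors under one convention.
# Tokenizes each distinct name once.
match_percent <- function(first_names, second_names, params = match_params()) {
  stopifnot(length(first_names) == length(second_names))
  if (length(first_names) == 0L) {
    return(numeric(0))
  }
  all_names <- c(first_names, second_names)
  uniq <- unique(all_names)
  toks <- lapply(uniq, name_tokens)
  ia <- match(first_names, uniq)
  ib <- match(second_names, uniq)
  vapply(
    seq_along(ia),
    function(k) 100 * match_core(toks[[ia[k]]], toks[[ib[k]]], params)$value,
    numeric(1)
  )
}

#' @export
print.lasa_match <- function(x, ...) {
  cat(
    "<lasa_match> ", x$word, " ~ ", x$input, ": ",
    format(round(x$percent, 2)), "% (peak ", format(round(x$profile$f_star, 4)),
    " / l_i ", format(x$l_i), ")\n  ", params_fingerprint(x$params), "\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn match_value Per-channel tidy table of a match: one row per
#'   bound letter channel, unbound word token, and marker channel.
#' @param x A `lasa_match` object.
#' @param ... Unused.
#' @export
tidy.lasa_match <- function(x, ...) {
  b <- x$binding
  bind_rows(
    mutate(b$bound, channel = "letter", bound = TRUE),
    mutate(b$unbound_word_tokens, channel = "letter", bound = FALSE,
           input_position = NA_integer_, d = NA_real_),
    tibble(
      letter = rep(NA_character_, length(b$marker_differences)),
      occurrence = NA_integer_, word_position = NA_integer_,
      input_position = NA_integer_, d = b$marker_differences,
      channel = "marker", bound = TRUE
    )
  )
}

#' @describeIn match_value One-row summary of a match.
#' @export
glance.lasa_match <- function(x, ...) {
  tibble(
    word = x$word,
    input = x$input,
    value = x$value,
    percent = x$percent,
    band = classify_risk(x$percent),
    f_star = x$profile$f_star,
    x_star = x$profile$x_star,
    l_i = x$l_i,
    n_bound = nrow(x$binding$bound),
    n_unbound = nrow(x$binding$unbound_word_tokens),
    n_markers = length(x$binding$marker_differences),
    convention = params_fingerprint(x$params)
  )
}
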