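# Structural invariants of the match value, on seeded random material.
# The large-scale versions live in the acceptance suite; these runs are
# sized for quick feedback.

random_pair_table <- function(n, seed) {
  generate_cohort(cohort_spec(
    n_pairs = n,
    edit_grid = list(
      edit_spec(), edit_spec(n_substitutions = 1),
      edit_spec(n_substitutions = 2, n_insertions = 1),
      edit_spec(n_adjacent_transpositions = 1, n_deletions = 1)
    ),
    seed = seed
  ))
}

test_that("identity pairs score exactly 1 under every convention", {
  names <- vapply(1:8, function(s) random_name(sample(3:13, 1), seed = s), character(1))
  for (params in all_params_grid()) {
    for (nm in names) {
      expect_identical(match_value(nm, nm, params)$value, 1)
    }
  }
})

test_that("match values stay inside [0, 1] across conventions", {
  tbl <- random_pair_table(40, seed = 11)
  for (params in all_params_grid()) {
    pct <- score_pairs(tbl, params)$percent
    expect_true(all(pct >= 0 & pct <= 100))
  }
})

test_that("the peak never exceeds the center count, with equality iff coincident", {
  withr::with_seed(21, {
    for (rep in 1:50) {
      k <- sample(1:8, 1)
      centers <- round(runif(k, -4, 4) * 2) / 2
      f <- find_peak(centers, sigma = 3)$f_star
      expect_lte(f, k + 1e-9)
      if (length(unique(centers)) == 1L) {
        expect_equal(f, k)
      } else {
        expect_lt(f, k)
      }
    }
  })
})

test_that("the superposition peak is shift invariant", {
  withr::with_seed(31, {
    for (rep in 1:40) {
      centers <- runif(sample(1:6, 1), -5, 5)
      shift <- runif(1, -20, 20)
      a <- find_peak(centers, sigma = 3)
      b <- find_peak(centers + shift, sigma = 3)
      # the peak value (hence the match value) is what translation preserves;
      # the argmax may hop between near-tied local maxima
      expect_equal(b$f_star, a$f_star, tolerance = 1e-9)
    }
  })
})

test_that("descending and ascending code series give identical match values", {
  tbl <- random_pair_table(30, seed = 41)
  for (markers in c(TRUE, FALSE)) {
    for (denom in c("word", "shorter", "mean")) {
      pd <- match_params(end_markers = markers, denominator_mode = denom)
      pa <- match_params(
        end_markers = markers, denominator_mode = denom,
        code_series = "ascending_unit"
      )
      expect_equal(score_pairs(tbl, pa)$percent, score_pairs(tbl, pd)$percent,
        tolerance = 1e-9
      )
    }
  }
})

test_that("reversing both repeat-free names leaves the match unchanged", {
  rev_name <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")
  withr::with_seed(51, {
    for (rep in 1:30) {
      a <- random_name(sample(5:12, 1), repeat_free = TRUE)
      b <- as.character(mutate_name(a, edit_spec(
        n_substitutions = sample(0:2, 1),
        n_adjacent_transpositions = sample(0:1, 1)
      )))
      for (markers in c(TRUE, FALSE)) {
        p <- match_params(end_markers = markers)
        expect_equal(
          match_value(rev_name(a), rev_name(b), p)$value,
          match_value(a, b, p)$value,
          tolerance = 1e-9
        )
      }
    }
  })
})

test_that("degrading a bound input letter never increases the match", {
  withr::with_seed(61, {
    for (rep in 1:40) {
      a <- random_name(sample(5:12, 1), repeat_free = TRUE)
      b <- as.character(mutate_name(a, edit_spec(n_substitutions = sample(0:1, 1))))
      p <- match_params()
      m0 <- match_value(a, b, p)
      bound <- m0$binding$bound
      if (nrow(bound) == 0L) next
      pos <- bound$input_position[sample.int(nrow(bound), 1)]
      bl <- strsplit(b, "", fixed = TRUE)[[1]]
      pool <- setdiff(LETTERS, c(strsplit(a, "", fixed = TRUE)[[1]], bl))
      bl[pos] <- pool[1]
      worse <- paste(bl, collapse = "")
      expect_lte(match_value(a, worse, p)$value, m0$value + 1e-12)
    }
  })
})

test_that("one adjacent transposition beats two substitutions at the same sites", {
  base <- "BRADICUMS" # 9 letters, repeat-free
  p <- match_params(end_markers = FALSE)
  transposed <- "BRADICUSM" # swap the last two letters
  doubled <- substitute_absent(base, c(8, 9))
  mt <- match_value(base, transposed, p)$value
  ms <- match_value(base, doubled, p)$value
  expect_gt(mt, ms)
  expect_equal(mt, (7 + 2 * exp(-1 / 3)) / 9, tolerance = 1e-9)
  expect_equal(ms, 7 / 9, tolerance = 1e-12)
})
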