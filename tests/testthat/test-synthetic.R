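test_that("random names are seeded, bounded, and optionally repeat-free", {
  expect_identical(random_name(8, seed = 1), random_name(8, seed = 1))
  expect_false(identical(random_name(8, seed = 1), random_name(8, seed = 2)))
  expect_equal(nchar(random_name(1, seed = 3)), 1L)
  expect_error(random_name(0), "\\[1, 30\\]")
  expect_error(random_name(31), "\\[1, 30\\]")
  expect_error(random_name(27, repeat_free = TRUE), "26")
  rf <- random_name(20, seed = 4, repeat_free = TRUE)
  expect_false(any(duplicated(strsplit(rf, "")[[1]])))
  # sampling leaves the caller's RNG stream untouched
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(random_name(8, seed = 1))
  expect_identical(runif(1), before)
})

test_that("a zero-edit spec is the identity with an empty log", {
  out <- mutate_name("LOPRAMIDE", edit_spec(), seed = 1)
  expect_equal(as.character(out), "LOPRAMIDE")
  expect_equal(nrow(attr(out, "edit_log")), 0L)
})

test_that("edits are logged in application order with sensible fields", {
  out <- mutate_name("ABCDEFGH", edit_spec(
    n_deletions = 1, n_substitutions = 1,
    n_adjacent_transpositions = 1, n_insertions = 1
  ), seed = 5)
  log <- attr(out, "edit_log")
  expect_equal(log$op, c("deletion", "substitution", "transposition", "insertion"))
  expect_equal(nchar(as.character(out)), 8L) # -1 deletion +1 insertion
  # substituted-in and inserted letters are absent from the base
  added <- c(log$to[log$op == "substitution"], log$to[log$op == "insertion"])
  expect_false(any(added %in% strsplit("ABCDEFGH", "")[[1]]))
})

test_that("single edits on repeat-free bases hit their closed-form scores", {
  p <- match_params(end_markers = FALSE)
  withr::with_seed(17, {
    for (rep in 1:10) {
      base <- random_name(8, repeat_free = TRUE)
      sub1 <- mutate_name(base, edit_spec(n_substitutions = 1))
      expect_equal(match_value(base, sub1, p)$value, 7 / 8, tolerance = 1e-12)
      tr1 <- mutate_name(base, edit_spec(n_adjacent_transpositions = 1))
      expect_equal(
        match_value(base, tr1, p)$value,
        (6 + 2 * exp(-1 / 3)) / 8,
        tolerance = 1e-9
      )
    }
  })
})

test_that("infeasible edit specs are errors", {
  expect_error(mutate_name("ABC", edit_spec(n_substitutions = 3)), "Infeasible")
  expect_error(mutate_name("AB", edit_spec(n_deletions = 1, n_substitutions = 1)), "Infeasible")
  expect_error(edit_spec(n_substitutions = -1), "non-negative")
})

test_that("cohorts are reproducible and span the edit grid cyclically", {
  spec <- cohort_spec(
    n_pairs = 12,
    edit_grid = list(edit_spec(), edit_spec(n_substitutions = 1), edit_spec(n_insertions = 1)),
    seed = 33
  )
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  expect_equal(nrow(a), 12L)
  expect_equal(a$grid_cell, rep(1:3, 4))
  expect_true(all(nchar(a$local_proprietary) == a$base_length))
  # the zero-edit cell yields identical strings
  zero <- a[a$grid_cell == 1L, ]
  expect_identical(zero$local_proprietary, zero$overseas_similar)
  # written tables are byte-identical across runs
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_pairs(a, f1)
  write_pairs(generate_cohort(spec), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("mean match decreases with substitution count at fixed length", {
  spec <- cohort_spec(
    n_pairs = 90, lengths = 9, repeat_free = TRUE,
    edit_grid = list(
      edit_spec(n_substitutions = 1),
      edit_spec(n_substitutions = 2),
      edit_spec(n_substitutions = 3)
    ),
    seed = 71
  )
  scored <- score_pairs(generate_cohort(spec), match_params(end_markers = FALSE))
  means <- tapply(scored$percent, scored$n_substitutions, mean)
  expect_true(all(diff(means) < 0))
  # repeat-free bases with markers off have exact per-cell values
  expect_equal(as.numeric(means), 100 * c(8, 7, 6) / 9, tolerance = 1e-9)
})
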