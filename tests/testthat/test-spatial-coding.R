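test_that("position encoding follows the descending unit series", {
  expect_equal(encode_spatial("CAT")$value, c(3, 2, 1))
  expect_equal(encode_spatial("A")$value, 1)

  aa <- encode_spatial("AA")
  expect_equal(aa$letter, c("A", "A"))
  expect_equal(aa$occurrence, c(1L, 2L))
  expect_equal(aa$value, c(2, 1))

  asc <- encode_spatial("CAT", "ascending_unit")
  expect_equal(asc$value, c(-1, -2, -3))
  expect_true(all(diff(asc$value) < 0)) # still strictly descending

  expect_error(encode_spatial("®"), "®")
})

test_that("in-order binding matches occurrences and reports unbound tokens", {
  ident <- bind_letters("ABC", "ABC", end_markers = FALSE)
  expect_equal(ident$bound$d, c(0, 0, 0))
  expect_equal(nrow(ident$unbound_word_tokens), 0L)
  expect_equal(ident$l_i, 3)

  # shared suffix at a constant ordinal offset: one common difference value
  cip <- bind_letters("CIPLEX", "IPLEX", end_markers = FALSE)
  expect_equal(nrow(cip$bound), 5L)
  expect_setequal(cip$bound$letter, c("I", "P", "L", "E", "X"))
  expect_length(unique(cip$bound$d), 1L)
  expect_equal(cip$unbound_word_tokens$letter, "C")

  sin <- bind_letters("SINIPHEN", "TINYPHEN", end_markers = FALSE)
  expect_equal(nrow(sin$bound), 6L)
  expect_equal(sin$bound$d, rep(0, 6))
  expect_setequal(
    paste0(sin$unbound_word_tokens$letter, sin$unbound_word_tokens$occurrence),
    c("S1", "I2")
  )
  expect_equal(sin$l_i, 8)
})

test_that("end-marker channels fire on letter equality and widen l_i by two", {
  b <- bind_letters("TINYPHEN", "SINIPHEN", end_markers = TRUE)
  expect_equal(b$marker_differences, 0) # last letters agree, first differ
  expect_equal(b$l_i, 10)

  both <- bind_letters("LOPRAX", "LOPROX", end_markers = TRUE)
  expect_equal(both$marker_differences, c(0, 0))

  none <- bind_letters("ABC", "XYZ", end_markers = TRUE)
  expect_length(none$marker_differences, 0L)
  expect_equal(none$l_i, 5)
})

test_that("find_peak locates the superposition maximum", {
  p1 <- find_peak(0, sigma = 3)
  expect_equal(p1$x_star, 0)
  expect_equal(p1$f_star, 1)

  # symmetry forces the midpoint; closed-form peak value
  p2 <- find_peak(c(0, 1), sigma = 3)
  expect_equal(p2$x_star, 0.5, tolerance = 1e-6)
  expect_equal(p2$f_star, 2 * exp(-1 / 12), tolerance = 1e-9)

  # frozen from the dense-grid oracle
  p3 <- find_peak(c(0, 0, 0, 1, 1, 1, 1), sigma = 3)
  expect_equal(p3$f_star, 6.453407, tolerance = 1e-5)

  empty <- find_peak(numeric(0), sigma = 3)
  expect_equal(empty$f_star, 0)

  expect_error(find_peak(c(0, 1), sigma = 0), "sigma")
  expect_error(find_peak(c(0, 1), sigma = -1), "sigma")
})

test_that("find_peak breaks ties toward the smallest maximizer", {
  # two far-apart equal peaks under a narrow width
  p <- find_peak(c(0, 10), sigma = 0.5)
  expect_lt(abs(p$x_star - 0), 1e-6)
  expect_equal(p$f_star, 1, tolerance = 1e-9)
})

test_that("match values reproduce the worked examples", {
  expect_equal(match_value("LOPRAX", "LOPRAX")$percent, 100)
  off <- match_params(end_markers = FALSE)
  expect_equal(match_value("LOPRAX", "LOPRAX", off)$percent, 100)

  abc <- match_value("ABC", "ABD", off)
  expect_equal(abc$value, 2 / 3)

  tin <- match_value("TINYPHEN®", "SINIPHEN")
  expect_equal(tin$percent, 70)
  expect_equal(tin$profile$f_star, 7) # six letters + one marker, all at d = 0
  expect_equal(tin$l_i, 10)
})

test_that("optimal binding never scores below in-order and handles repeats", {
  pairs <- list(
    c("AAB", "ABA"), c("BANANA", "ANANAB"), c("AABB", "BBAA"),
    c("PANTOSS", "PANTOSSE"), c("AAAA", "AAAA")
  )
  for (pr in pairs) {
    for (markers in c(TRUE, FALSE)) {
      po <- match_params(end_markers = markers, binding_mode = "optimal")
      pi <- match_params(end_markers = markers, binding_mode = "in_order")
      expect_gte(
        match_value(pr[1], pr[2], po)$value + 1e-9,
        match_value(pr[1], pr[2], pi)$value
      )
    }
  }
  expect_equal(match_value("BANANA", "BANANA", match_params(binding_mode = "optimal"))$percent, 100)

  # a letter with one occurrence on one side must bind its true position,
  # wherever that is
  b <- bind_letters("XBYB", "ZBQ", binding_mode = "optimal", end_markers = FALSE)
  expect_true(all(b$bound$input_position %in% 2L))
  expect_equal(b$bound$letter, "B")
})

test_that("tidy and glance expose the match anatomy", {
  m <- match_value("TINYPHEN", "SINIPHEN")
  td <- tidy(m)
  expect_equal(nrow(td), 8 + 1) # 8 word tokens (6 bound, 2 unbound) + 1 marker
  expect_equal(sum(td$channel == "marker"), 1L)
  expect_equal(sum(!td$bound), 2L)

  gl <- glance(m)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$percent, 70)
  expect_equal(gl$band, factor("high", c("none", "low", "medium", "high"), ordered = TRUE))
  expect_match(gl$convention, "markers=on")
})
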