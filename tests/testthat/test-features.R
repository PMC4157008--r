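test_that("moving_average_value averages a truncated centered window", {
  s <- eeg_signal(c(1, 2, 3, 4, 5), fs = 1)
  expect_equal(moving_average_value(s, 2, 3), 3)           # (2+3+4)/3
  expect_equal(moving_average_value(s, 2, 1), 3)           # degenerate window
  expect_equal(moving_average_value(s, 0, 5), 2)           # truncated: (1+2+3)/3
  c_sig <- eeg_signal(rep(7.5, 20), fs = 1)
  expect_equal(moving_average_value(c_sig, 10, 9), 7.5)    # constant signal
  expect_error(moving_average_value(s, 7, 3), "outside")
  expect_error(moving_average_value(s, 2, 4), "odd")
  # the full-signal curve agrees with the pointwise definition
  set.seed(3)
  r <- eeg_signal(rnorm(50), fs = 1)
  expect_equal(peakswarm:::mac_curve(r, 7),
               vapply(0:49, function(i) moving_average_value(r, i, 7),
                      numeric(1)))
})

test_that("turning points follow the >50% slope-drop rule with valley fallback", {
  # slopes 4 then 1.5: drop beyond half, endpoint of 2nd segment is the TP
  s <- eeg_signal(c(9, 10, 6, 4.5, 4.2, 4.0, 4.4), fs = 1)
  expect_identical(find_turning_point(s, pp = 1, vp = 5), 3L)
  # slopes 4 then exactly 2: not "more than 50%", walk continues (0.5 < 1)
  s2 <- eeg_signal(c(0, 10, 6, 4, 3.5, 3, 4), fs = 1)
  expect_identical(find_turning_point(s2, pp = 1, vp = 5), 4L)
  # constant slope: no qualifying segment, falls back to the valley
  s3 <- eeg_signal(c(0, 10, 8, 6, 4, 2, 3), fs = 1)
  expect_identical(find_turning_point(s3, pp = 1, vp = 5), 5L)
  # valley adjacent to the peak: only the fallback is possible
  s4 <- eeg_signal(c(5, 1, 4, 2, 6, 3, 7, 0), fs = 1)
  expect_identical(find_turning_point(s4, pp = 4, vp = 3), 3L)
})

test_that("half points are the first sample at or below the mid level", {
  s <- eeg_signal(c(0, 10, 7, 4, 0, 1), fs = 1)
  expect_identical(find_half_point(s, pp = 1, vp = 4), 3L)  # h = 5, value 4
  s2 <- eeg_signal(c(5, 1, 4, 2, 6, 3, 7, 0), fs = 1)
  expect_identical(find_half_point(s2, pp = 4, vp = 3), 3L) # adjacent valley
  # symmetric triangle: half points equidistant from the apex
  tri <- eeg_signal(c(0, 2, 4, 6, 8, 6, 4, 2, 0) + 0.01 * c(1, 0, 0, 0, 0, 0, 0, 0, 1),
                    fs = 1)
  expect_identical(4L - find_half_point(tri, 4, 0),
                   find_half_point(tri, 4, 8) - 4L)
})

test_that("the toy candidate reproduces hand-computed feature values", {
  s <- eeg_signal(c(5, 1, 4, 2, 6, 3, 7, 0), fs = 256)
  f <- extract_features(s, pp = 4, vp1 = 3, vp2 = 5, mac_window = 1)
  expect_equal(unname(f[c(1, 2, 6, 7, 8, 11, 12)]),
               c(4, 3, 2, 1, 1, 4, 3))
  # adjacent valleys force turning-point fallback: f3/f4 mirror f1/f2
  expect_equal(unname(f[3:4]), c(4, 3))
  expect_equal(unname(f[c(9, 10, 13, 14)]), c(2, 2, 4, 3))
  expect_equal(unname(f[5]), 0)                      # window 1: MAC = x(pp)
  f3 <- extract_features(s, pp = 4, vp1 = 3, vp2 = 5, mac_window = 3)
  expect_equal(unname(f3[5]), 6 - (2 + 6 + 3) / 3)   # direct window mean
})

test_that("the literal f12 denominator reproduces the printed formula", {
  s <- eeg_signal(c(0, 1, 0.5, 3, 9, 5, 4.5, 2, 1, 2), fs = 1)
  cand <- detect_candidates(s)
  row <- cand[cand$pp == 4L, ]
  f_fix <- extract_features(s, row$pp, row$vp1, row$vp2, mac_window = 1)
  f_lit <- extract_features(s, row$pp, row$vp1, row$vp2, mac_window = 1,
                            literal_f12 = TRUE)
  expect_equal(unname(f_fix[12]), abs((9 - 1) / (4 - 8)))   # corrected: /|pp-vp2|
  expect_equal(unname(f_lit[12]), abs((9 - 1) / (4 - 2)))   # printed: /|pp-vp1|
  expect_equal(f_fix[-12], f_lit[-12])
})

test_that("features are finite, non-negative, and mirror correctly", {
  set.seed(11)
  checked <- 0L
  for (i in 1:40) {
    n <- sample(30:120, 1)
    x <- random_test_signal(n)
    s <- eeg_signal(x, fs = 1)
    cand <- detect_candidates(s)
    if (nrow(cand) == 0L) next
    fmat <- peak_features(s, cand, mac_window = 9)
    expect_true(all(is.finite(fmat)) && all(fmat >= 0))
    # left-right mirroring swaps the paired features and fixes the rest
    rs <- eeg_signal(rev(x), fs = 1)
    for (k in seq_len(nrow(cand))) {
      f <- fmat[k, ]
      g <- extract_features(rs, n - 1L - cand$pp[k], n - 1L - cand$vp2[k],
                            n - 1L - cand$vp1[k], mac_window = 9)
      swap <- c(2, 1, 4, 3, 5, 6, 8, 7, 9, 10, 12, 11, 14, 13)
      expect_equal(unname(g), unname(f[swap]), tolerance = 1e-12)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 50L)
})

test_that("with window 1 the moving-average amplitude f5 vanishes", {
  set.seed(12)
  s <- eeg_signal(rnorm(200), fs = 1)
  cand <- detect_candidates(s)
  fmat <- peak_features(s, cand, mac_window = 1)
  expect_true(all(fmat[, 5] == 0))
})

test_that("the peak-model catalogue matches the published subsets", {
  cat_ <- peak_model_catalog()
  expect_named(cat_, c("dumpala", "acir", "liu", "dingle"))
  expect_identical(lengths(cat_), c(dumpala = 4L, acir = 6L, liu = 11L,
                                    dingle = 4L))
  expect_identical(model_subset("dingle"), c(5L, 6L, 11L, 12L))
  expect_identical(model_subset("acir"), c(1L, 2L, 7L, 8L, 13L, 14L))
  expect_identical(model_subset("liu"),
                   c(1L, 2L, 3L, 4L, 6L, 9L, 10L, 11L, 12L, 13L, 14L))
  expect_identical(model_subset("dumpala"), c(1L, 6L, 11L, 12L))
  expect_error(model_subset("bogus"), "dumpala")
})
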