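# A kymograph stub with prescribed tips and CI rows, bypassing images.
stub_kymo <- function(ci, head, tail) {
  nf <- nrow(ci)
  structure(list(ci = ci, n_points = ncol(ci),
                 offsets = data.frame(frame = seq_len(nf), shift = 0L,
                                      flipped = FALSE, cost = 0,
                                      reanchored = FALSE),
                 tips = data.frame(frame = seq_len(nf),
                                   head = rep_len(head, nf),
                                   tail = rep_len(tail, nf))),
            class = "kymograph")
}

test_that("exclusion zones leave the documented index set", {
  k <- stub_kymo(matrix(0.01, 1, 300), head = 1L, tail = 151L)
  inc <- included_points(k, 25L)[[1L]]
  expect_length(inc, 198L)
  expect_true(all(larvacurv:::circ_dist(inc, 1L, 300L) > 25))
  expect_true(all(larvacurv:::circ_dist(inc, 151L, 300L) > 25))
  # brute-force reconstruction of the same set
  brute <- Filter(function(i)
    larvacurv:::circ_dist(i, 1L, 300L) > 25 &&
      larvacurv:::circ_dist(i, 151L, 300L) > 25, 1:300)
  expect_identical(inc, as.integer(brute))
  expect_length(included_points(k, 0L)[[1L]], 298L)
  expect_error(included_points(k, 80L), "overlap")
})

test_that("control cutoff is the median of pooled positive CI", {
  row <- rep(0, 300)
  row[100:102] <- c(0.01, 0.02, 0.03)
  k1 <- stub_kymo(matrix(row, 1, 300, byrow = TRUE), 1L, 151L)
  expect_equal(cutoff_from_control(list(k1)), 0.02)
  row2 <- row; row2[103] <- 0.05
  k2 <- stub_kymo(matrix(row2, 1, 300, byrow = TRUE), 1L, 151L)
  expect_equal(cutoff_from_control(list(k2)), 0.025)
  # pooling two identical animals leaves the median unchanged
  expect_equal(cutoff_from_control(list(k1, k1)), 0.02)
  zero <- stub_kymo(matrix(-0.01, 1, 300), 1L, 151L)
  expect_error(cutoff_from_control(list(zero)), "positive")
})

test_that("per-animal percentages count low/high with ties going high", {
  row <- rep(-0.01, 300)
  row[100:103] <- c(0.01, 0.05, 0.05, 0.09)
  k <- stub_kymo(matrix(row, 1, 300, byrow = TRUE), 1L, 151L)
  s <- summarize_animal(k, cutoff = 0.027)
  expect_equal(s$pct_low, 25)
  expect_equal(s$pct_high, 75)
  expect_equal(s$pct_low + s$pct_high, 100)
  # all positives below the cutoff
  row2 <- rep(-0.01, 300); row2[100:104] <- 0.0135
  k2 <- stub_kymo(matrix(row2, 1, 300, byrow = TRUE), 1L, 151L)
  s2 <- summarize_animal(k2, cutoff = 0.027)
  expect_equal(s2$pct_low, 100)
  expect_equal(s2$pct_high, 0)
  # a value exactly at the cutoff is high
  row3 <- rep(-0.01, 300); row3[100:101] <- c(0.027, 0.01)
  k3 <- stub_kymo(matrix(row3, 1, 300, byrow = TRUE), 1L, 151L)
  s3 <- summarize_animal(k3, cutoff = 0.027)
  expect_equal(s3$pct_high, 50)
  none <- stub_kymo(matrix(-0.01, 1, 300), 1L, 151L)
  expect_error(summarize_animal(none, cutoff = 0.027), "no included")
})

test_that("cutoff-on-control splits the control pool in half", {
  set.seed(11)
  rows <- matrix(abs(rnorm(5 * 300, 0.02, 0.01)) + 1e-5, 5, 300)
  k <- stub_kymo(rows, 1L, 151L)
  cut <- cutoff_from_control(list(k))
  s <- summarize_animal(k, cut)
  expect_lt(abs(s$pct_low - 50), 1)
  expect_lt(abs(s$pct_high - 50), 1)
})

test_that("group comparison matches the exhaustive permutation oracle", {
  mk <- function(vals) lapply(vals, function(v)
    data.frame(animal_id = "x", pct_low = 100 - v, pct_high = v,
               n_included = 198, cutoff = 0.02, exclusion = 25L))
  A <- mk(c(10, 12, 11, 13))
  B <- mk(c(30, 31, 29, 32))
  res <- compare_groups(A, B)
  expect_lt(res$p_value, 0.001)
  expect_gt(res$statistic, 0)  # B > A
  # oracle: permutation distribution of the Welch t over all 70 splits
  pooled <- c(10, 12, 11, 13, 30, 31, 29, 32)
  splits <- combn(8, 4)
  tstats <- apply(splits, 2, function(ix)
    tryCatch(stats::t.test(pooled[-ix], pooled[ix])$statistic,
             error = function(e) NA))
  t_obs <- stats::t.test(c(30, 31, 29, 32), c(10, 12, 11, 13))$statistic
  p_perm <- mean(abs(tstats) >= abs(t_obs) - 1e-12, na.rm = TRUE)
  # both routes call the difference significant at the same decision level
  expect_lt(p_perm, 0.05)
  expect_equal(p_perm < 0.05, res$p_value < 0.05)
  # identical groups: t = 0, p = 1
  res0 <- compare_groups(A, A)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # degenerate variance falls back to the exact permutation test
  C <- mk(c(20, 20, 20))
  D <- mk(c(20, 20, 20))
  resd <- compare_groups(C, D)
  expect_match(resd$method, "permutation")
  expect_equal(resd$p_value, 1)
  expect_error(compare_groups(A[1], B), ">= 2")
})

test_that("deeper synthetic bends score higher pct_high", {
  shallow <- make_cohort(1, 1 / 170, n_frames = 6, seed = 21)[[1]]
  deep <- make_cohort(1, 1 / 85, n_frames = 6, seed = 22)[[1]]
  ks <- process_scene(shallow)$kymo
  kd <- process_scene(deep)$kymo
  cut <- cutoff_from_control(list(ks))
  s_sh <- summarize_animal(ks, cut, animal_id = "shallow")
  s_dp <- summarize_animal(kd, cut, animal_id = "deep")
  expect_gt(s_dp$pct_high, s_sh$pct_high)
  expect_equal(s_sh$pct_low + s_sh$pct_high, 100)
  expect_equal(s_dp$pct_low + s_dp$pct_high, 100)
})
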