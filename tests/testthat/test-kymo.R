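make_test_boundary <- function(seed = 1) {
  spec <- cbend_spec(R = 80)
  extract_boundary(make_worm_mask(spec))
}

shift_ring <- function(points, s, flip = FALSE) {
  n <- nrow(points)
  i0 <- 0:(n - 1L)
  j <- if (flip) (s - i0) %% n else (i0 + s) %% n
  # build Q so that P[i] corresponds to Q[(+-i + s) mod n]
  out <- points
  out[j + 1L, ] <- points
  out
}

test_that("alignment recovers exact cyclic shifts", {
  b <- make_test_boundary()
  res0 <- align_boundaries(b, b)
  expect_equal(res0[c("shift", "flipped", "cost")],
               list(shift = 0L, flipped = FALSE, cost = 0))
  shifted <- as_worm_boundary(shift_ring(b$points, 17L))
  res <- align_boundaries(b, shifted)
  expect_equal(res$shift, 17L)
  expect_false(res$flipped)
  expect_equal(res$cost, 0)
  flipped <- as_worm_boundary(shift_ring(b$points, 93L, flip = TRUE))
  resf <- align_boundaries(b, flipped)
  expect_equal(resf$shift, 93L)
  expect_true(resf$flipped)
  expect_equal(resf$cost, 0)
  small <- as_worm_boundary(b$points[1:10, ])
  expect_error(align_boundaries(b, small), "n_points")
})

test_that("jittered shifts are recovered and cost matches brute force", {
  b <- asym_boundary()
  set.seed(42)
  for (case in 1:5) {
    s <- sample(0:299, 1)
    flip <- sample(c(TRUE, FALSE), 1)
    jitter <- matrix(rnorm(600, 0, 0.5), ncol = 2)
    Q <- shift_ring(b$points + jitter, s, flip)
    res <- align_boundaries(b, as_worm_boundary(Q))
    oracle <- naive_align(b$points, Q)
    expect_equal(res$shift, oracle$shift)
    expect_equal(res$flipped, oracle$flipped)
    expect_equal(res$cost, oracle$cost, tolerance = 1e-9)
    expect_equal(res$shift, s)
    expect_equal(res$flipped, flip)
    # recovered cost is the sum of squared jitters
    expect_equal(res$cost, sum(jitter^2), tolerance = 1e-9)
  }
})

test_that("alignment cost never exceeds the unaligned cost", {
  spec <- worm_spec(body_length = 220, kappa = 1 / 200,
                    image_height = 360, image_width = 360)
  sc <- make_bend_sequence(spec, 1 / 80, 4)
  bs <- lapply(sc$masks, extract_boundary)
  for (t in 2:4) {
    res <- align_boundaries(bs[[t - 1L]], bs[[t]])
    unaligned <- sum((bs[[t - 1L]]$points - bs[[t]]$points)^2)
    expect_lte(res$cost, unaligned)
  }
})

test_that("alignment composes along a chain of rigid shifts", {
  b <- make_test_boundary()
  B <- as_worm_boundary(shift_ring(b$points, 40L))
  C <- as_worm_boundary(shift_ring(b$points, 70L))
  ab <- align_boundaries(b, B)
  bc <- align_boundaries(B, C)
  ac <- align_boundaries(b, C)
  expect_lte(abs(((ab$shift + bc$shift) %% 300) - ac$shift), 1)
})

test_that("tips are found on worms, stable across frames, absent on disks", {
  spec <- worm_spec(body_length = 220, max_half_width = 12, kappa = 0,
                    image_height = 340, image_width = 340)
  b <- extract_boundary(make_worm_mask(spec))
  p <- curvature_profile(b)
  tips <- detect_tips(p)
  # ground truth: boundary points nearest the midline endpoints
  ml <- larvacurv:::worm_midline(spec)
  ends <- cbind(c(ml$x[1L], ml$x[length(ml$x)]),
                c(ml$y[1L], ml$y[length(ml$y)]))
  true_idx <- apply(ends, 1, function(e)
    which.min((b$points[, 1L] - e[1L])^2 + (b$points[, 2L] - e[2L])^2))
  d <- larvacurv:::circ_dist(sort(tips), sort(true_idx), 300L)
  expect_true(all(d <= 5))
  expect_error(detect_tips(curvature_profile(circle_boundary(40))),
               "no tips")
})

test_that("kymographs of static scenes have identical rows, zero offsets", {
  spec <- cbend_spec(R = 90)
  b <- extract_boundary(make_worm_mask(spec))
  p <- curvature_profile(b)
  k <- build_kymograph(list(b, b, b), list(p, p, p))
  expect_equal(k$offsets$shift, c(0L, 0L, 0L))
  expect_false(any(k$offsets$flipped))
  expect_equal(k$ci[1L, ], k$ci[2L, ])
  expect_equal(k$ci[1L, ], k$ci[3L, ])
  expect_equal(k$tips$head, rep(k$tips$head[1L], 3))
})

test_that("progressively re-parametrised copies align back to one row", {
  spec <- cbend_spec(R = 90)
  b <- extract_boundary(make_worm_mask(spec))
  p0 <- curvature_profile(b)
  shifts <- c(0L, 23L, 46L, 69L)
  bs <- lapply(shifts, function(s)
    as_worm_boundary(shift_ring(b$points, s)))
  ps <- lapply(bs, curvature_profile)
  k <- build_kymograph(bs, ps)
  for (t in 2:4) expect_equal(k$ci[t, ], k$ci[1L, ], tolerance = 1e-12)
})

test_that("head labels persist through a deepening bend", {
  spec <- worm_spec(body_length = 220, kappa = 1 / 300,
                    image_height = 380, image_width = 380)
  sc <- make_bend_sequence(spec, 1 / 80, 6)
  res <- process_scene(sc)
  drift <- diff(res$kymo$tips$head)
  drift <- pmin(abs(drift), 300 - abs(drift))
  expect_true(all(drift <= 15))
  # deepening bend: column-wise max concave CI rises over frames
  expect_gt(max(res$kymo$ci[6L, ]), max(res$kymo$ci[1L, ]))
})
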