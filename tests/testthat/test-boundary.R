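test_that("thresholding recovers the generator's mask and rejects blanks", {
  expect_error(threshold_frame(matrix(0, 5, 5), 10), "no animal")
  img <- matrix(10, 40, 40)
  img[15:25, 10:30] <- 200
  expect_identical(threshold_frame(img, 100), img > 100)
  spec <- worm_spec(body_length = 150, kappa = 1 / 100,
                    image_height = 260, image_width = 260)
  mask <- make_worm_mask(spec)
  frame <- matrix(10, 260, 260)
  frame[mask] <- 200
  expect_identical(threshold_frame(frame, 100), mask)
  # Otsu default lands between the two modes
  expect_identical(threshold_frame(frame), mask)
})

test_that("size filter keeps only the animal", {
  spec <- worm_spec(body_length = 180, kappa = 0,
                    image_height = 280, image_width = 280)
  mask <- make_worm_mask(spec)
  dirty <- add_artifacts(mask, 3, c(5, 20), seed = 2)
  clean <- size_filter(dirty, min_area = 100)
  expect_identical(clean, mask)
  expect_identical(size_filter(mask, min_area = 100), mask)
  expect_error(size_filter(dirty, min_area = 1e6), "every component")
})

test_that("two large components resolve to the largest, ties to centre", {
  m <- matrix(FALSE, 60, 60)
  m[5:14, 5:14] <- TRUE      # 100 px
  m[30:44, 30:44] <- TRUE    # 225 px
  kept <- size_filter(m, min_area = 50)
  expect_equal(sum(kept), 225)
  expect_true(kept[35, 35])
  # equal areas: the more central square wins
  m2 <- matrix(FALSE, 60, 60)
  m2[2:11, 2:11] <- TRUE
  m2[26:35, 26:35] <- TRUE
  kept2 <- size_filter(m2, min_area = 50)
  expect_true(kept2[30, 30] && !kept2[5, 5])
})

test_that("square boundary has the analytic perimeter and equal spacing", {
  b <- extract_boundary(square_mask(50), 300)
  expect_equal(b$n_points, 300L)
  expect_lt(abs(b$perimeter - 200) / 200, 0.02)
  gaps <- sqrt(rowSums((rbind(b$points[-1L, ], b$points[1L, ]) -
                          b$points)^2))
  # resampling is uniform in arclength; chord gaps contract slightly where
  # the path turns through the four corners, and are exact elsewhere
  expect_lt(max(abs(gaps - b$perimeter / 300)), 0.05 * b$perimeter / 300)
  expect_lt(stats::median(abs(gaps - b$perimeter / 300)),
            0.001 * b$perimeter / 300)
})

test_that("smooth boundaries are equally spaced within 1%", {
  b <- extract_boundary(disk_mask(40))
  gaps <- sqrt(rowSums((rbind(b$points[-1L, ], b$points[1L, ]) -
                          b$points)^2))
  expect_lt(max(abs(gaps - b$perimeter / 300)), 0.01 * b$perimeter / 300)
  # a worm's chords are uniform away from its pointed tips
  bw <- extract_boundary(make_worm_mask(
    worm_spec(body_length = 180, kappa = 1 / 100,
              image_height = 300, image_width = 300)))
  gw <- sqrt(rowSums((rbind(bw$points[-1L, ], bw$points[1L, ]) -
                        bw$points)^2))
  expect_gt(mean(abs(gw - bw$perimeter / 300) <
                   0.01 * bw$perimeter / 300), 0.9)
})

test_that("disk boundary points sit on the circle", {
  r <- 40
  m <- disk_mask(r)
  b <- extract_boundary(m)
  ctr <- (nrow(m) + 1) / 2
  d <- sqrt((b$points[, 1L] - ctr)^2 + (b$points[, 2L] - ctr)^2)
  expect_true(all(abs(d - r) <= 1))
  # perimeter within 2% of 2*pi*r for disks of radius >= 20
  for (rr in c(20, 40, 60)) {
    bb <- extract_boundary(disk_mask(rr))
    expect_lt(abs(bb$perimeter - 2 * pi * rr) / (2 * pi * rr), 0.02)
  }
})

test_that("four points on a square are symmetric", {
  b <- extract_boundary(square_mask(50), 4L)
  gaps <- sqrt(rowSums((rbind(b$points[-1L, ], b$points[1L, ]) -
                          b$points)^2))
  expect_equal(unname(gaps), rep(gaps[1L], 4), tolerance = 1e-9)
})

test_that("extraction is idempotent under re-rasterisation", {
  spec <- worm_spec(body_length = 180, kappa = 1 / 90,
                    image_height = 300, image_width = 300)
  b1 <- extract_boundary(make_worm_mask(spec))
  m2 <- larvacurv:::rasterize_polygon(b1$points[, 1L], b1$points[, 2L],
                                      300, 300)
  b2 <- extract_boundary(m2)
  # nearest-point distance from each re-extracted point to the original ring
  d <- vapply(seq_len(300), function(i)
    min(sqrt((b1$points[, 1L] - b2$points[i, 1L])^2 +
               (b1$points[, 2L] - b2$points[i, 2L])^2)), numeric(1))
  expect_lt(max(d), 1)
})

test_that("degenerate masks are rejected", {
  thin <- matrix(FALSE, 20, 20)
  thin[10, 5:15] <- TRUE  # 1 px wide line
  expect_error(extract_boundary(matrix(FALSE, 5, 5)), "empty")
  b <- tryCatch(extract_boundary(thin), error = function(e) e)
  expect_true(inherits(b, "error") || b$perimeter > 0)
})

test_that("boundary orientation and start are canonical across frames", {
  spec <- worm_spec(body_length = 200, kappa = 0,
                    image_height = 340, image_width = 340)
  sc <- make_bend_sequence(spec, 1 / 90, 4)
  bs <- lapply(sc$masks, extract_boundary)
  areas <- vapply(bs, function(b)
    larvacurv:::polygon_signed_area(b$points[, 1L], b$points[, 2L]),
    numeric(1))
  expect_true(all(areas > 0))
  starts <- vapply(bs, function(b) {
    o <- order(b$points[, 2L], b$points[, 1L])[1L]
    sum(abs(b$points[1L, ] - b$points[o, ]))
  }, numeric(1))
  expect_true(all(starts < 2))
})
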