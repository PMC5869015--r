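# Index maps on the ring are affine: j = (a * i + b) mod n with a = +/-1
# (0-based indices). `a = -1` is a reversed (mirrored) parametrisation.
apply_ring_map <- function(i0, a, b, n) ((a * i0 + b) %% n)

#' Align two boundary parametrisations
#'
#' Finds, over all `n_points` cyclic shifts with and without index
#' reversal, the correspondence minimising the sum of squared distances
#' between matched points of consecutive frames. The search is exhaustive
#' (2n candidates), so the optimum is exact; ties are broken in favour of
#' the smallest non-reversed shift.
#'
#' @param prev,curr `worm_boundary` objects with equal `n_points` and the
#'   same orientation convention.
#' @return List with `shift` (0-based), `flipped` (logical), `cost`
#'   (pixels^2): point `i` of `prev` matches point `(i + shift) mod n` of
#'   `curr`, or `(shift - i) mod n` when flipped.
#' @export
align_boundaries <- function(prev, curr) {
  stopifnot(inherits(prev, "worm_boundary"), inherits(curr, "worm_boundary"))
  n <- prev$n_points
  if (curr$n_points != n)
    stop("boundaries have different n_points (", n, " vs ",
         curr$n_points, ")")
  P <- prev$points
  Q <- curr$points
  i0 <- 0:(n - 1L)
  best <- list(shift = 0L, flipped = FALSE, cost = Inf)
  for (flip in c(FALSE, TRUE)) {
    a <- if (flip) -1L else 1L
    for (s in i0) {
      j <- apply_ring_map(i0, a, s, n) + 1L
      cost <- sum((P - Q[j, , drop = FALSE])^2)
      if (cost < best$cost) best <- list(shift = s, flipped = flip,
                                         cost = cost)
    }
  }
  best
}

#' Locate head and tail tips on a curvature profile
#'
#' The two body tips of an elongated animal are the sharpest convex points
#' of its outline, i.e. the two strict local minima of the curvature
#' profile with the most negative CI, constrained to lie at least
#' `min_separation` index positions apart on the ring. Shapes without two
#' such minima (a disk, a blob) raise an error.
#'
#' @param profile a `curvature_profile`.
#' @param min_separation minimum circular index distance between tips.
#' @param prev_head head index of the previous frame; the detected tip
#'   nearer to it is labelled head (first frame: the sharper tip).
#' @param window half-width of the strict-local-minimum neighbourhood.
#' @param prominence_frac a local minimum only counts as a tip when it
#'   drops below every window neighbour by more than this fraction of the
#'   profile's CI range, so numerically flat profiles (a disk) yield no
#'   tips.
#' @return Integer vector `c(head, tail)` of 1-based indices.
#' @export
detect_tips <- function(profile, min_separation = 100L, prev_head = NULL,
                        window = 5L, prominence_frac = 0.02) {
  stopifnot(inherits(profile, "curvature_profile"))
  ci <- profile$ci
  n <- length(ci)
  if (min_separation >= n / 2)
    stop("min_separation must be below n_points / 2")
  prom <- max(1e-6, prominence_frac * diff(range(ci)))
  is_min <- vapply(seq_len(n), function(i) {
    nb <- ((i - 1L + c(-(window:1L), 1L:window)) %% n) + 1L
    ci[i] < 0 && all(ci[i] <= ci[nb]) && max(ci[nb]) - ci[i] > prom
  }, logical(1))
  cand <- which(is_min)
  if (length(cand) < 2L) stop("shape has no tips")
  cand <- cand[order(ci[cand])]
  tip1 <- cand[1L]
  rest <- cand[circ_dist(cand, tip1, n) >= min_separation]
  if (length(rest) == 0L) stop("shape has no tips")
  tip2 <- rest[1L]
  tips <- c(tip1, tip2)
  if (!is.null(prev_head) &&
      circ_dist(tip2, prev_head, n) < circ_dist(tip1, prev_head, n))
    tips <- c(tip2, tip1)
  stats::setNames(tips, c("head", "tail"))
}

#' Build a curvature kymograph with cross-frame point correspondence
#'
#' Chains pairwise alignments ([align_boundaries()]) so every frame's
#' curvature profile is re-indexed into the coordinates of frame 1, then
#' locates head and tail tips per frame in aligned coordinates. If the
#' aligned head index drifts by more than `reanchor` points between
#' consecutive frames (a misalignment the exhaustive match cannot rule out
#' when the outline deforms), the frame's offset is re-anchored to keep the
#' head fixed — an automated stand-in for correcting head/tail slippage by
#' hand.
#'
#' @param boundaries list of per-frame `worm_boundary` objects.
#' @param profiles list of matching `curvature_profile` objects.
#' @param min_separation,window passed to [detect_tips()].
#' @param reanchor head drift (index positions) that triggers re-anchoring.
#' @return An object of class `kymograph`: list with `ci` (frames x
#'   n_points matrix in aligned coordinates), `offsets` (per-frame data
#'   frame: `shift`, `flipped`, `cost`, `reanchored`), `tips` (per-frame
#'   data frame: `head`, `tail`), `n_points`.
#' @export
build_kymograph <- function(boundaries, profiles, min_separation = 100L,
                            window = 5L, reanchor = 15L) {
  stopifnot(length(boundaries) == length(profiles),
            length(boundaries) >= 1L)
  nf <- length(boundaries)
  n <- boundaries[[1L]]$n_points
  ci_mat <- matrix(NA_real_, nf, n)
  off <- data.frame(frame = seq_len(nf), shift = 0L, flipped = FALSE,
                    cost = 0, reanchored = FALSE)
  tips <- data.frame(frame = seq_len(nf), head = NA_integer_,
                     tail = NA_integer_)
  a_tot <- 1L; b_tot <- 0L
  i0 <- 0:(n - 1L)
  prev_head <- NULL
  for (t in seq_len(nf)) {
    if (t > 1L) {
      st <- align_boundaries(boundaries[[t - 1L]], boundaries[[t]])
      a_s <- if (st$flipped) -1L else 1L
      # compose: frame1 -> frame t-1 (a_tot, b_tot), then t-1 -> t
      b_tot <- (a_s * b_tot + st$shift) %% n
      a_tot <- a_s * a_tot
      off$shift[t] <- st$shift
      off$flipped[t] <- st$flipped
      off$cost[t] <- st$cost
    }
    row <- profiles[[t]]$ci[apply_ring_map(i0, a_tot, b_tot, n) + 1L]
    prof_aligned <- structure(list(ci = row, flank = profiles[[t]]$flank,
                                   boundary = boundaries[[t]]),
                              class = "curvature_profile")
    tp <- detect_tips(prof_aligned, min_separation = min_separation,
                      prev_head = prev_head, window = window)
    if (!is.null(prev_head)) {
      drift <- ((tp["head"] - prev_head) %% n)
      drift <- min(drift, n - drift)
      if (drift > reanchor) {
        # shift the map so the head stays where the previous frame had it
        d <- (tp["head"] - prev_head) %% n
        b_tot <- (a_tot * d + b_tot) %% n
        off$reanchored[t] <- TRUE
        row <- profiles[[t]]$ci[apply_ring_map(i0, a_tot, b_tot, n) + 1L]
        prof_aligned$ci <- row
        tp <- detect_tips(prof_aligned, min_separation = min_separation,
                          prev_head = prev_head, window = window)
      }
    }
    ci_mat[t, ] <- row
    tips$head[t] <- tp[["head"]]
    tips$tail[t] <- tp[["tail"]]
    prev_head <- tp[["head"]]
  }
  structure(list(ci = ci_mat, offsets = off, tips = tips,
                 n_points = n), class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d frame(s) x %d boundary points; CI range [%.4g, %.4g] 1/px\n",
              nrow(x$ci), x$n_points, min(x$ci), max(x$ci)))
  if (any(x$offsets$reanchored))
    cat("  re-anchored frames:",
        paste(which(x$offsets$reanchored), collapse = ", "), "\n")
  invisible(x)
}

#' Plot a kymograph heat map
#'
#' Boundary position against time, coloured by CI on a diverging scale:
#' warm colours are positive (concave) CI, cool colours negative (convex).
#' Rendering only — never an analysis input.
#'
#' @param x a `kymograph`.
#' @param ... passed to [graphics::image()].
#' @export
plot.kymograph <- function(x, ...) {
  z <- x$ci
  lim <- max(abs(z))
  pal <- grDevices::colorRampPalette(
    c("#2166ac", "#f7f7f7", "#b2182b"))(101)
  graphics::image(x = seq_len(nrow(z)), y = seq_len(ncol(z)), z = z,
                  zlim = c(-lim, lim), col = pal,
                  xlab = "frame", ylab = "boundary point", ...)
  invisible(x)
}
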