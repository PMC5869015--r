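#' Circumradius of three planar points
#'
#' Radius of the unique circle through three points. Near-collinear point
#' triples (twice the triangle area below `tol`) return `Inf`, the
#' flat-boundary sentinel.
#'
#' @param p1,p2,p3 numeric length-2 points (x, y).
#' @param tol collinearity tolerance on twice the triangle area, px^2.
#' @return Radius in pixels, or `Inf` if collinear.
#' @export
circumcircle_radius <- function(p1, p2, p3, tol = 1e-6) {
  if (identical(all.equal(p1, p2), TRUE) ||
      identical(all.equal(p2, p3), TRUE) ||
      identical(all.equal(p1, p3), TRUE))
    stop("coincident points have no circumcircle")
  a <- sqrt(sum((p2 - p3)^2))
  b <- sqrt(sum((p1 - p3)^2))
  cc <- sqrt(sum((p1 - p2)^2))
  cross <- abs((p2[1L] - p1[1L]) * (p3[2L] - p1[2L]) -
                 (p3[1L] - p1[1L]) * (p2[2L] - p1[2L]))
  if (cross < tol) return(Inf)
  a * b * cc / (2 * cross)
}

# Vectorised circumradius for point triples given as three n x 2 matrices.
circumradius_vec <- function(P1, P2, P3, tol = 1e-6) {
  a <- sqrt(rowSums((P2 - P3)^2))
  b <- sqrt(rowSums((P1 - P3)^2))
  cc <- sqrt(rowSums((P1 - P2)^2))
  cross <- abs((P2[, 1L] - P1[, 1L]) * (P3[, 2L] - P1[, 2L]) -
                 (P3[, 1L] - P1[, 1L]) * (P2[, 2L] - P1[, 2L]))
  r <- a * b * cc / (2 * cross)
  r[cross < tol] <- Inf
  r
}

#' Signed curvature index at one boundary point
#'
#' The curvature index (CI) at boundary point `i` is the reciprocal of the
#' radius of the circle through the point and its two neighbours `flank`
#' index positions away (taken modulo the ring length), so tighter local
#' bending gives a larger |CI|. The sign encodes concavity: if the midpoint
#' of the segment joining the two flanking points falls outside the body
#' outline the CI is positive (concave boundary, e.g. the inside of a
#' C-bend); otherwise it is negative (convex). Near-collinear triples get
#' CI = 0.
#'
#' @param boundary a `worm_boundary`.
#' @param i point index (1-based).
#' @param flank neighbour offset in boundary-point index units (default 10).
#' @param tol collinearity tolerance, px^2.
#' @return Signed CI in 1/pixels.
#' @export
curvature_index <- function(boundary, i, flank = 10L, tol = 1e-6) {
  stopifnot(inherits(boundary, "worm_boundary"),
            i >= 1, i <= boundary$n_points)
  n <- boundary$n_points
  im <- ((i - 1L - flank) %% n) + 1L
  ip <- ((i - 1L + flank) %% n) + 1L
  p <- boundary$points
  r <- unname(circumcircle_radius(p[im, ], p[i, ], p[ip, ], tol = tol))
  if (!is.finite(r)) return(0)
  mid <- (p[im, ] + p[ip, ]) / 2
  outside <- !points_in_polygon(mid[1L], mid[2L], p[, 1L], p[, 2L])
  if (outside) 1 / r else -1 / r
}

#' Curvature profile of a boundary
#'
#' Computes the signed curvature index at every boundary point (see
#' [curvature_index()]); the in/out sign test runs against the full
#' resampled boundary polygon.
#'
#' @param boundary a `worm_boundary`.
#' @param flank neighbour offset in index units (default 10).
#' @param tol collinearity tolerance, px^2.
#' @return An object of class `curvature_profile`: list with `ci`
#'   (length `n_points`, 1/pixels), `flank`, `boundary`.
#' @export
curvature_profile <- function(boundary, flank = 10L, tol = 1e-6) {
  stopifnot(inherits(boundary, "worm_boundary"))
  n <- boundary$n_points
  p <- boundary$points
  idx <- seq_len(n)
  im <- ((idx - 1L - flank) %% n) + 1L
  ip <- ((idx - 1L + flank) %% n) + 1L
  r <- circumradius_vec(p[im, , drop = FALSE], p, p[ip, , drop = FALSE],
                        tol = tol)
  midx <- (p[im, 1L] + p[ip, 1L]) / 2
  midy <- (p[im, 2L] + p[ip, 2L]) / 2
  outside <- !points_in_polygon(midx, midy, p[, 1L], p[, 2L])
  ci <- ifelse(is.finite(r), ifelse(outside, 1, -1) / r, 0)
  structure(list(ci = ci, flank = as.integer(flank), boundary = boundary),
            class = "curvature_profile")
}

#' @export
print.curvature_profile <- function(x, ...) {
  cat(sprintf(
    "curvature_profile: %d points, flank %d; CI range [%.4g, %.4g] 1/px\n",
    length(x$ci), x$flank, min(x$ci), max(x$ci)))
  invisible(x)
}

#' @export
plot.curvature_profile <- function(x, ...) {
  plot(seq_along(x$ci), x$ci, type = "l", xlab = "boundary point",
       ylab = "curvature index (1/px)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
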