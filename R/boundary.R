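#' Threshold a grayscale frame
#'
#' Foreground = pixels strictly brighter than `level`. When `level` is
#' `NULL` an Otsu threshold is computed on the frame (the field-standard
#' automatic choice when the acquisition threshold is not recorded).
#'
#' @param image numeric matrix, row 1 = top of the image.
#' @param level intensity threshold, or `NULL` for Otsu.
#' @return Logical mask of the same dimensions.
#' @export
threshold_frame <- function(image, level = NULL) {
  stopifnot(is.matrix(image), length(image) > 0)
  if (is.null(level)) {
    rng <- max(image)
    scale <- if (rng > 1) 255 else 1
    level <- EBImage::otsu(EBImage::Image(image / scale)) * scale
  }
  mask <- image > level
  if (!any(mask)) stop("no animal detected: empty foreground at level ",
                       signif(level, 4))
  mask
}

#' Remove debris components by size
#'
#' Drops 8-connected components smaller than `min_area`; if several remain,
#' only the largest is kept (ties: component whose centroid is closest to
#' the image centre, then lowest label). The default `min_area` is 1\% of
#' the image area.
#'
#' @param mask logical matrix with at least one foreground component.
#' @param min_area minimum component area in pixels^2.
#' @return Mask containing exactly one component.
#' @export
size_filter <- function(mask, min_area = NULL) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) stop("mask has no foreground components")
  if (is.null(min_area)) min_area <- 0.01 * length(mask)
  lab <- label_components(mask)
  areas <- component_areas(lab)
  keep <- which(areas >= min_area)
  if (length(keep) == 0)
    stop("size filter removed every component (min_area = ",
         signif(min_area, 4), ")")
  if (length(keep) > 1L) {
    amax <- max(areas[keep])
    cand <- keep[areas[keep] == amax]
    if (length(cand) > 1L) {
      ctr <- c((nrow(mask) + 1) / 2, (ncol(mask) + 1) / 2)
      d2 <- vapply(cand, function(l) {
        idx <- which(lab == l, arr.ind = TRUE)
        sum((colMeans(idx) - ctr)^2)
      }, numeric(1))
      cand <- cand[order(d2, cand)]
    }
    keep <- cand[1L]
  }
  lab == keep
}

#' Extract a closed equal-arclength boundary from a mask
#'
#' Traces the outer contour of the (single-component) mask at sub-pixel
#' precision along foreground pixel-edge midpoints (marching squares at
#' level 0.5), ignores holes, fixes the orientation, sets the canonical
#' start vertex (minimal y, then minimal x), and resamples the contour to
#' `n_points` points equally spaced by arclength via linear interpolation
#' along the traced polyline.
#'
#' Coordinates are (x = column, y = row), pixel centres at integers.
#'
#' The raw marching-squares polyline zigzags around oblique edges, which
#' inflates perimeter (and hence arclength spacing) by several percent;
#' `smooth_iters` passes of a circular three-point vertex average remove
#' that quantisation ripple while moving vertices by well under half a
#' pixel. Set `smooth_iters = 0` for the raw traced polyline.
#'
#' @param mask logical matrix containing one cleaned component.
#' @param n_points number of boundary points (default 300).
#' @param smooth_iters vertex-averaging passes applied to the traced
#'   polyline before resampling (default 2).
#' @return An object of class `worm_boundary`: list with `points`
#'   (`n_points` x 2 matrix, columns x, y), `n_points`, `perimeter`.
#' @export
extract_boundary <- function(mask, n_points = 300L, smooth_iters = 2L) {
  stopifnot(is.matrix(mask), n_points >= 3)
  if (!any(mask)) stop("empty mask")
  # pad so contours of edge-touching components still close
  pad <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask * 1
  cl <- grDevices::contourLines(x = 0:(nrow(mask) + 1L),
                                y = 0:(ncol(mask) + 1L),
                                z = pad, levels = 0.5)
  if (length(cl) == 0) stop("degenerate component: no traceable contour")
  # contourLines' x follows rows, y follows columns; convert to pixel (x, y)
  polys <- lapply(cl, function(p) cbind(x = p$y, y = p$x))
  # outer contour = largest absolute enclosed area (holes are smaller)
  areas <- vapply(polys, function(p) {
    m <- nrow(p)
    abs(polygon_signed_area(p[-m, 1L], p[-m, 2L]))
  }, numeric(1))
  poly <- polys[[which.max(areas)]]
  poly <- poly[-nrow(poly), , drop = FALSE]       # drop repeated closing vertex
  if (nrow(poly) < 3 || max(areas) < 1)
    stop("degenerate component: contour encloses no area")
  for (it in seq_len(smooth_iters)) {
    m <- nrow(poly)
    prv <- poly[c(m, seq_len(m - 1L)), , drop = FALSE]
    nxt <- poly[c(seq_len(m)[-1L], 1L), , drop = FALSE]
    poly <- (prv + poly + nxt) / 3
  }
  # fixed orientation: positive signed area in the (x right, y down) frame
  if (polygon_signed_area(poly[, 1L], poly[, 2L]) < 0)
    poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  # canonical start vertex: minimal y, then minimal x
  start <- order(poly[, 2L], poly[, 1L])[1L]
  if (start > 1L)
    poly <- poly[c(start:nrow(poly), 1:(start - 1L)), , drop = FALSE]
  # arclength resampling
  seg <- sqrt(rowSums((rbind(poly[-1L, , drop = FALSE], poly[1L, ]) -
                         poly)^2))
  cum <- c(0, cumsum(seg))
  perim <- cum[length(cum)]
  targets <- (seq_len(n_points) - 1L) * perim / n_points
  xs <- stats::approx(cum, c(poly[, 1L], poly[1L, 1L]), xout = targets)$y
  ys <- stats::approx(cum, c(poly[, 2L], poly[1L, 2L]), xout = targets)$y
  structure(list(points = cbind(x = xs, y = ys),
                 n_points = as.integer(n_points), perimeter = perim),
            class = "worm_boundary")
}

#' Construct a boundary from explicit points
#'
#' Wraps an ordered closed ring of planar points as a `worm_boundary`
#' without tracing a mask; intended for boundaries that are already
#' parametrised (analytic shapes, files written by [write_boundary()]).
#'
#' @param points numeric matrix with columns x, y (ring open: last point
#'   is not a repeat of the first).
#' @return A `worm_boundary`.
#' @export
as_worm_boundary <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, nrow(points) >= 3L)
  colnames(points) <- c("x", "y")
  seg <- sqrt(rowSums((rbind(points[-1L, , drop = FALSE],
                             points[1L, ]) - points)^2))
  structure(list(points = points, n_points = nrow(points),
                 perimeter = sum(seg)), class = "worm_boundary")
}

#' @export
print.worm_boundary <- function(x, ...) {
  cat(sprintf("worm_boundary: %d points, perimeter %.1f px\n",
              x$n_points, x$perimeter))
  invisible(x)
}

#' @export
plot.worm_boundary <- function(x, ...) {
  plot(x$points[, 1L], -x$points[, 2L], type = "l", asp = 1,
       xlab = "x (px)", ylab = "-y (px)", ...)
  invisible(x)
}
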