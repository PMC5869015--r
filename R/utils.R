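# Internal geometry and RNG helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Circular index distance on a ring of n positions (indices 1-based).
circ_dist <- function(i, j, n) {
  d <- abs(i - j) %% n
  pmin(d, n - d)
}

# Signed polygon area by the shoelace formula; vertices as columns x, y,
# ring open (last vertex != first). Positive = counterclockwise in the
# (x right, y down) pixel frame.
polygon_signed_area <- function(x, y) {
  xn <- c(x[-1L], x[1L])
  yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

# Even-odd point-in-polygon test, vectorised over query points.
# Points lying on an edge (within `edge_tol` px) are classified inside:
# the sign rule sends boundary cases to the convex ("otherwise") branch.
points_in_polygon <- function(qx, qy, px, py, edge_tol = 1e-9) {
  n <- length(px)
  x1 <- px; y1 <- py
  x2 <- c(px[-1L], px[1L]); y2 <- c(py[-1L], py[1L])
  m <- length(qx)
  inside <- logical(m)
  on_edge <- logical(m)
  # crossing-count parity, one edge at a time (n ~ 300, m ~ 300: cheap)
  for (e in seq_len(n)) {
    a1 <- y1[e]; a2 <- y2[e]
    if (a1 != a2) {
      crosses <- (a1 > qy) != (a2 > qy)
      if (any(crosses)) {
        xi <- x1[e] + (qy[crosses] - a1) * (x2[e] - x1[e]) / (a2 - a1)
        hit <- qx[crosses] < xi
        idx <- which(crosses)[hit]
        inside[idx] <- !inside[idx]
      }
    }
    # distance from query points to this segment
    ex <- x2[e] - x1[e]; ey <- y2[e] - y1[e]
    len2 <- ex * ex + ey * ey
    if (len2 > 0) {
      t <- ((qx - x1[e]) * ex + (qy - y1[e]) * ey) / len2
      t <- pmin(pmax(t, 0), 1)
      dx <- qx - (x1[e] + t * ex); dy <- qy - (y1[e] + t * ey)
      on_edge <- on_edge | (dx * dx + dy * dy) <= edge_tol^2
    } else {
      on_edge <- on_edge |
        ((qx - x1[e])^2 + (qy - y1[e])^2) <= edge_tol^2
    }
  }
  inside | on_edge
}

# Rasterise a simple polygon onto an integer pixel grid by scanline fill:
# pixel (row r, col c) is foreground iff its center (x = c, y = r) lies
# inside the polygon (even-odd rule).
rasterize_polygon <- function(px, py, nrow, ncol) {
  mask <- matrix(FALSE, nrow, ncol)
  x1 <- px; y1 <- py
  x2 <- c(px[-1L], px[1L]); y2 <- c(py[-1L], py[1L])
  r0 <- max(1L, floor(min(py)))
  r1 <- min(nrow, ceiling(max(py)))
  for (r in r0:r1) {
    crosses <- (y1 > r) != (y2 > r)
    if (!any(crosses)) next
    xi <- sort(x1[crosses] +
                 (r - y1[crosses]) * (x2[crosses] - x1[crosses]) /
                 (y2[crosses] - y1[crosses]))
    for (k in seq(1L, length(xi) - 1L, by = 2L)) {
      ca <- ceiling(xi[k]); cb <- floor(xi[k + 1L])
      if (cb >= ca) {
        ca <- max(1L, ca); cb <- min(ncol, cb)
        if (cb >= ca) mask[r, ca:cb] <- TRUE
      }
    }
  }
  mask
}

# 8-connected component labelling. EBImage::bwlabel is 4-connected; labels
# touching diagonally are merged through the label-adjacency graph.
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- NULL
  for (dd in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nr - 1L), , drop = FALSE]
    b <- lab[seq_len(nr - 1L) + 1L, , drop = FALSE]
    if (dd[2L] == 1L) {
      a <- a[, seq_len(nc - 1L), drop = FALSE]
      b <- b[, seq_len(nc - 1L) + 1L, drop = FALSE]
    } else {
      a <- a[, seq_len(nc - 1L) + 1L, drop = FALSE]
      b <- b[, seq_len(nc - 1L), drop = FALSE]
    }
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  }
  if (is.null(pairs)) return(lab)
  pu <- unique(pairs)
  g <- igraph::graph_from_edgelist(
    cbind(as.character(pu[, 1L]), as.character(pu[, 2L])),
    directed = FALSE)
  g <- igraph::add_vertices(g, sum(!as.character(seq_len(nlab)) %in%
                                     igraph::V(g)$name),
                            name = setdiff(as.character(seq_len(nlab)),
                                           igraph::V(g)$name))
  comp <- igraph::components(g)$membership
  remap <- integer(nlab)
  remap[as.integer(names(comp))] <- comp
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

component_areas <- function(lab) {
  tabulate(lab[lab > 0])
}
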