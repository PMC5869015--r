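# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths.

# Least-squares (Kasa) circle fit: algebraic solve of the normal equations.
fit_circle_lsq <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(A, b)
  list(cx = sol[1L], cy = sol[2L],
       r = sqrt(sol[3L] + sol[1L]^2 + sol[2L]^2))
}

# Naive alignment search: plain double loop over all 2n candidates,
# summing squared distances term by term.
naive_align <- function(P, Q) {
  n <- nrow(P)
  best <- list(shift = NA, flipped = NA, cost = Inf)
  for (flip in c(FALSE, TRUE)) {
    for (s in 0:(n - 1L)) {
      cost <- 0
      for (i in 0:(n - 1L)) {
        j <- if (flip) (s - i) %% n else (i + s) %% n
        cost <- cost + sum((P[i + 1L, ] - Q[j + 1L, ])^2)
      }
      if (cost < best$cost) best <- list(shift = s, flipped = flip,
                                         cost = cost)
    }
  }
  best
}

# Exhaustive DFS over simple directed paths with bounded edge count.
dfs_paths <- function(edges, sources, sinks, max_hops) {
  adj <- split(edges$post, edges$pre)
  out <- list()
  walk <- function(path) {
    tail_id <- path[length(path)]
    if (length(path) > 1L && tail_id %in% sinks) out[[length(out) + 1L]] <<- path
    if (length(path) - 1L >= max_hops) return()
    for (nxt in adj[[tail_id]]) {
      if (nxt %in% path) next
      walk(c(path, nxt))
    }
  }
  for (s in sources) walk(s)
  keys <- vapply(out, paste, "", collapse = "\r")
  out[order(keys)]
}

# Analytic closed ring of n points on a circle.
circle_boundary <- function(r, n = 300L, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  as_worm_boundary(cbind(cx + r * cos(th), cy + r * sin(th)))
}

# Filled disk / square masks for boundary tests.
disk_mask <- function(r, pad = 10L) {
  n <- 2L * ceiling(r) + 2L * pad
  ctr <- (n + 1) / 2
  rows <- matrix(seq_len(n), n, n)
  cols <- t(rows)
  (rows - ctr)^2 + (cols - ctr)^2 <= r^2
}

square_mask <- function(side, pad = 10L) {
  n <- side + 2L * pad
  m <- matrix(FALSE, n, n)
  m[(pad + 1L):(pad + side), (pad + 1L):(pad + side)] <- TRUE
  m
}

# Chiral worm (monotone curvature along the body): no mirror symmetry, so
# reversed-parametrisation matches cannot masquerade as good alignments.
asym_boundary <- function() {
  spec <- worm_spec(body_length = 230, max_half_width = 12,
                    kappa = function(s) 1 / 150 + (1 / 70 - 1 / 150) * s,
                    image_height = 380, image_width = 380)
  extract_boundary(make_worm_mask(spec))
}

# Standard mid-size C-bend worm used by several files.
cbend_spec <- function(R = 60, w = 12, len = NULL) {
  if (is.null(len)) len <- min(0.85 * 2 * pi * R, 300)
  sz <- ceiling(2 * (R + w) + 140)
  worm_spec(body_length = len, max_half_width = w, kappa = 1 / R,
            image_height = sz, image_width = sz)
}
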