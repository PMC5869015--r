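#' Specify a synthetic larva
#'
#' Describes a larva as a ribbon: a midline of given arclength and (possibly
#' varying) signed curvature, swept by a half-width profile that tapers to a
#' point at both ends. The default profile is flat over the mid-body with a
#' raised-cosine taper over the terminal 15\% at each end, which produces
#' pointed, convex tips like a real larva so that tip detection is
#' exercised by downstream code.
#'
#' @param body_length midline arclength in pixels.
#' @param max_half_width mid-body half-width in pixels.
#' @param kappa signed midline curvature in 1/pixels; either a single number
#'   (circular bend; 0 = straight) or a function of normalised arclength
#'   `s` in `[0, 1]`.
#' @param image_height,image_width frame dimensions in pixels.
#' @param anchor numeric length-2, pixel coordinates (x, y) of the midline
#'   start. `NULL` centres the midline bounding box in the frame.
#' @param heading initial midline tangent direction, radians (0 = +x).
#' @param taper_frac fraction of the body length tapered at each end.
#' @param seed integer seed recorded with the spec (generators that consume
#'   randomness use it).
#'
#' @return An object of class `worm_spec`.
#' @export
worm_spec <- function(body_length = 200, max_half_width = 12,
                      kappa = 0, image_height = 400, image_width = 400,
                      anchor = NULL, heading = 0, taper_frac = 0.15,
                      seed = 1L) {
  stopifnot(body_length > 0, max_half_width > 0,
            taper_frac > 0, taper_frac < 0.5)
  half_width <- function(s) {
    w <- rep(max_half_width, length(s))
    lo <- s < taper_frac
    hi <- s > 1 - taper_frac
    w[lo] <- max_half_width * 0.5 * (1 - cos(pi * s[lo] / taper_frac))
    w[hi] <- max_half_width * 0.5 * (1 - cos(pi * (1 - s[hi]) / taper_frac))
    w
  }
  kfun <- if (is.function(kappa)) kappa else function(s) rep(kappa, length(s))
  spec <- structure(list(
    body_length = body_length, max_half_width = max_half_width,
    half_width_profile = half_width, midline_curvature = kfun,
    kappa = if (is.function(kappa)) NA_real_ else kappa,
    image_height = image_height, image_width = image_width,
    anchor = anchor, heading = heading, taper_frac = taper_frac,
    seed = as.integer(seed)), class = "worm_spec")
  validate_worm_spec(spec)
  spec
}

validate_worm_spec <- function(spec) {
  s <- seq(0, 1, length.out = 512)
  w <- spec$half_width_profile(s)
  if (w[1L] >= 2 || w[length(w)] >= 2)
    stop("half-width at the tips must be < 2 px (pointed tips)")
  kmax <- max(abs(spec$midline_curvature(s)))
  if (kmax * max(w) >= 1)
    stop("ribbon self-overlaps: max |curvature| * max half-width = ",
         signif(kmax * max(w), 3), " >= 1")
  invisible(spec)
}

# Midline samples: positions, tangent angles, and half-widths at `n` points.
worm_midline <- function(spec, n = 800) {
  s <- seq(0, 1, length.out = n)
  ds <- spec$body_length / (n - 1)
  k <- spec$midline_curvature(s)
  # tangent angle by cumulative trapezoidal integration of curvature
  theta <- spec$heading +
    c(0, cumsum((k[-n] + k[-1L]) / 2 * ds))
  x <- c(0, cumsum((cos(theta[-n]) + cos(theta[-1L])) / 2 * ds))
  y <- c(0, cumsum((sin(theta[-n]) + sin(theta[-1L])) / 2 * ds))
  anchor <- spec$anchor
  if (is.null(anchor)) {
    anchor <- c((spec$image_width - (max(x) + min(x))) / 2,
                (spec$image_height - (max(y) + min(y))) / 2)
  }
  list(s = s, x = x + anchor[1L], y = y + anchor[2L], theta = theta,
       w = spec$half_width_profile(s), anchor = anchor)
}

# Closed ribbon outline polygon swept by the midline.
worm_polygon <- function(spec, n = 800) {
  m <- worm_midline(spec, n)
  nx <- -sin(m$theta); ny <- cos(m$theta)  # left normal
  px <- c(m$x + m$w * nx, rev(m$x - m$w * nx))
  py <- c(m$y + m$w * ny, rev(m$y - m$w * ny))
  list(x = px, y = py, midline = m)
}

#' Classify boundary points of a circular-bend worm by ground truth
#'
#' For a constant-curvature (C-bent) spec, labels each point of an
#' extracted boundary as lying on the mid-body inner edge (the concave
#' side, at distance `1/kappa - w` from the bend centre), the mid-body
#' outer edge (`1/kappa + w`), or neither (tips, taper). This is generator
#' bookkeeping: it uses only the known midline geometry, never the
#' curvature analysis, so it serves as an independent reference in tests.
#'
#' @param spec a scalar-curvature [worm_spec()] with `kappa != 0`.
#' @param boundary a `worm_boundary` extracted from the spec's mask.
#' @param s_range normalised-arclength span counted as mid-body.
#' @param tol radial tolerance in pixels for edge membership.
#' @return Character vector (`"inner"`, `"outer"`, `"other"`) per
#'   boundary point, with the bend centre in the `center` attribute.
#' @export
edge_regions <- function(spec, boundary, s_range = c(0.2, 0.8),
                         tol = 1.5) {
  stopifnot(inherits(spec, "worm_spec"), inherits(boundary, "worm_boundary"))
  if (is.na(spec$kappa) || spec$kappa == 0)
    stop("edge classification needs a nonzero constant curvature")
  R <- 1 / abs(spec$kappa)
  w <- spec$max_half_width
  ml <- worm_midline(spec)
  i <- length(ml$x) %/% 2L
  side <- sign(spec$kappa)
  ctr <- c(ml$x[i] - side * sin(ml$theta[i]) * R,
           ml$y[i] + side * cos(ml$theta[i]) * R)
  p <- boundary$points
  d <- sqrt((p[, 1L] - ctr[1L])^2 + (p[, 2L] - ctr[2L])^2)
  nearest <- vapply(seq_len(nrow(p)), function(q)
    which.min((ml$x - p[q, 1L])^2 + (ml$y - p[q, 2L])^2), integer(1))
  s <- ml$s[nearest]
  midbody <- s > s_range[1L] & s < s_range[2L]
  out <- rep("other", nrow(p))
  out[midbody & abs(d - (R - w)) < tol] <- "inner"
  out[midbody & abs(d - (R + w)) < tol] <- "outer"
  attr(out, "center") <- ctr
  out
}

#' Rasterise a synthetic larva to a binary mask
#'
#' Sweeps the midline by the half-width profile and rasterises the resulting
#' ribbon polygon with the pixel-centre-in-polygon rule: pixel (row, col) is
#' foreground iff its centre lies inside the ribbon outline.
#'
#' @param spec a [worm_spec()].
#' @return A logical matrix (`image_height` x `image_width`), `TRUE` = animal.
#' @export
make_worm_mask <- function(spec) {
  stopifnot(inherits(spec, "worm_spec"))
  validate_worm_spec(spec)
  poly <- worm_polygon(spec)
  bounds <- c(left = min(poly$x), right = max(poly$x),
              top = min(poly$y), bottom = max(poly$y))
  lim <- c(left = 2, right = spec$image_width - 1,
           top = 2, bottom = spec$image_height - 1)
  bad <- c(bounds["left"] < lim["left"], bounds["right"] > lim["right"],
           bounds["top"] < lim["top"], bounds["bottom"] > lim["bottom"])
  if (any(bad))
    stop("worm exits image bounds: ",
         paste(names(lim)[bad], collapse = ", "))
  rasterize_polygon(poly$x, poly$y, spec$image_height, spec$image_width)
}

#' Generate a bend-deepening silhouette scene
#'
#' Produces `n_frames` grayscale frames of a larva whose constant midline
#' curvature ramps linearly from the starting spec's value to `kappa_final`,
#' emulating the deepening C-bend of a nocifensive escape bout. Each frame
#' is re-centred in the image (as a tracking camera would), and the ground
#' truth (per-frame curvature, anchor, heading) is recorded in the scene.
#'
#' @param spec0 starting [worm_spec()] with scalar curvature.
#' @param kappa_final final midline curvature, 1/pixels.
#' @param n_frames number of frames (>= 2).
#' @param fg,bg foreground and background intensities of the rendered
#'   frames (8-bit scale).
#' @return An object of class `synthetic_scene`: list with `frames`
#'   (list of numeric matrices), `masks`, `ground_truth` (data frame with
#'   `frame`, `kappa`, `anchor_x`, `anchor_y`, `heading`), `specs`, and
#'   `artifact_blobs`.
#' @export
make_bend_sequence <- function(spec0, kappa_final, n_frames,
                               fg = 200, bg = 10) {
  stopifnot(inherits(spec0, "worm_spec"), n_frames >= 2)
  if (is.na(spec0$kappa))
    stop("bend sequences require a scalar-curvature starting spec")
  kappas <- spec0$kappa +
    (kappa_final - spec0$kappa) * (seq_len(n_frames) - 1) / (n_frames - 1)
  if (max(abs(kappas)) * spec0$max_half_width >= 1)
    stop("ribbon self-overlaps at curvature ",
         signif(kappas[which.max(abs(kappas))], 4))
  specs <- lapply(kappas, function(k) {
    s <- spec0; s$kappa <- k
    s$midline_curvature <- local({
      kk <- k; function(s) rep(kk, length(s))
    })
    s
  })
  masks <- lapply(specs, make_worm_mask)
  anchors <- t(vapply(specs, function(s) worm_midline(s)$anchor,
                      numeric(2)))
  frames <- lapply(masks, function(m) {
    f <- matrix(bg, nrow(m), ncol(m)); f[m] <- fg; f
  })
  structure(list(
    frames = frames, masks = masks,
    ground_truth = data.frame(frame = seq_len(n_frames), kappa = kappas,
                              anchor_x = anchors[, 1L],
                              anchor_y = anchors[, 2L],
                              heading = spec0$heading),
    specs = specs,
    artifact_blobs = vector("list", n_frames),
    fg = fg, bg = bg), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("synthetic_scene: %d frame(s) of %d x %d px, kappa %s to %s\n",
              length(x$frames), d[1L], d[2L],
              signif(x$ground_truth$kappa[1L], 4),
              signif(x$ground_truth$kappa[nrow(x$ground_truth)], 4)))
  invisible(x)
}

#' Inject debris blobs into a mask
#'
#' Adds `n_blobs` roughly circular foreground blobs, disjoint from existing
#' foreground, emulating the debris and light specks that the size filter
#' must remove. Deterministic for a fixed seed.
#'
#' @param mask logical matrix.
#' @param n_blobs number of blobs to add.
#' @param area_range length-2 numeric, admissible blob area in pixels^2.
#' @param seed integer seed.
#' @param max_tries placement retries per blob before giving up.
#' @return Mask with `1 + n_blobs` connected components.
#' @export
add_artifacts <- function(mask, n_blobs, area_range = c(5, 20), seed = 1L,
                          max_tries = 500L) {
  stopifnot(is.matrix(mask), n_blobs >= 0, length(area_range) == 2L,
            area_range[1L] <= area_range[2L])
  if (n_blobs == 0) return(mask)
  with_seed(seed, {
    out <- mask
    nr <- nrow(out); nc <- ncol(out)
    for (b in seq_len(n_blobs)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        area <- stats::runif(1, area_range[1L], area_range[2L])
        rad <- sqrt(area / pi)
        cx <- stats::runif(1, rad + 2, nc - rad - 1)
        cy <- stats::runif(1, rad + 2, nr - rad - 1)
        rr <- max(1L, floor(cy - rad)):min(nr, ceiling(cy + rad))
        cc <- max(1L, floor(cx - rad)):min(nc, ceiling(cx + rad))
        sub <- outer(rr, cc, function(r, c)
          (r - cy)^2 + (c - cx)^2 <= rad^2)
        if (!any(sub)) next
        npx <- sum(sub)
        if (npx < area_range[1L] || npx > area_range[2L]) next
        # require a 2 px clear margin so the blob is a separate component
        mr <- max(1L, min(rr) - 2L):min(nr, max(rr) + 2L)
        mc <- max(1L, min(cc) - 2L):min(nc, max(cc) + 2L)
        if (any(out[mr, mc])) next
        out[rr, cc] <- out[rr, cc] | sub
        placed <- TRUE
        break
      }
      if (!placed)
        stop("no free space for blob ", b, " after ", max_tries, " tries")
    }
    out
  })
}

#' Generate a thermal-ramp fluorescence/temperature trace pair
#'
#' Emulates ramp calcium imaging: a probe temperature trace sampled at 4 Hz
#' (the digitiser rate) rises linearly from `temp_start` to `temp_peak`
#' over the first `rise_frac` of the recording, then falls linearly to
#' `temp_end`. Fluorescence frames are sampled independently at
#' `frame_rate`; the generative model is
#' `F = f_base * (1 + gain * plogis((T - threshold) / sigmoid_scale))`
#' plus Gaussian noise, so the signal rises once the probe crosses the
#' activation threshold and saturates `gain`-fold above baseline.
#'
#' @param n_frames number of fluorescence frames.
#' @param frame_rate fluorescence sampling rate, Hz.
#' @param temp_start,temp_peak,temp_end ramp temperatures, degrees C.
#' @param threshold activation threshold, degrees C.
#' @param gain saturating fractional fluorescence increase (dimensionless).
#' @param noise_sd Gaussian noise s.d. in fluorescence units.
#' @param seed integer seed.
#' @param f_base baseline fluorescence, arbitrary units.
#' @param rise_frac fraction of the recording spent heating.
#' @param sigmoid_scale logistic width of the activation, degrees C; the
#'   default 0.5 saturates the response over roughly 3 degrees above
#'   threshold.
#' @return List with `fluor` (data frame `time`, `value`), `temp`
#'   (data frame `time`, `value`, sampled at 4 Hz), and `ground_truth`.
#' @export
make_ramp_trace <- function(n_frames, frame_rate = 5,
                            temp_start = 25, temp_peak = 49, temp_end = 31,
                            threshold = 39, gain = 1, noise_sd = 0,
                            seed = 1L, f_base = 100, rise_frac = 0.6,
                            sigmoid_scale = 0.5) {
  if (frame_rate <= 0) stop("frame_rate must be positive")
  stopifnot(n_frames >= 2)
  frame_times <- (seq_len(n_frames) - 1) / frame_rate
  duration <- frame_times[n_frames]
  temp_times <- seq(0, by = 0.25,
                    length.out = ceiling(duration / 0.25) + 1L)
  t_peak <- rise_frac * duration
  temp_vals <- ifelse(
    temp_times <= t_peak,
    temp_start + (temp_peak - temp_start) * temp_times / t_peak,
    temp_peak + (temp_end - temp_peak) * (temp_times - t_peak) /
      (duration - t_peak))
  t_at_frame <- stats::approx(temp_times, temp_vals, xout = frame_times,
                              rule = 2)$y
  fluor <- with_seed(seed,
    f_base * (1 + gain * stats::plogis((t_at_frame - threshold) /
                                         sigmoid_scale)) +
      stats::rnorm(n_frames, 0, noise_sd))
  list(fluor = data.frame(time = frame_times, value = fluor),
       temp = data.frame(time = temp_times, value = temp_vals),
       ground_truth = list(threshold = threshold, gain = gain,
                           f_base = f_base, noise_sd = noise_sd,
                           t_peak = t_peak, rise_frac = rise_frac,
                           sigmoid_scale = sigmoid_scale))
}

#' Generate a toy connectome with known input fractions
#'
#' Builds a small directed weighted connectome: `n_classes` upstream cell
#' classes of `n_per_class` neurons each, plus one designated target class
#' (`TARGET`). Every upstream neuron synapses onto every target neuron with
#' a positive integer synapse count drawn from `weight_spec`; sparse random
#' lateral edges between upstream classes give path enumeration something
#' to traverse. The per-class fraction of total input onto the target set
#' is tallied during generation and recorded as ground truth.
#'
#' @param n_classes number of upstream classes (>= 1).
#' @param n_per_class neurons per class (>= 1), recycled across classes.
#' @param weight_spec function(n) returning n positive integer synapse
#'   counts; default samples 1..8 uniformly.
#' @param seed integer seed.
#' @param n_targets neurons in the target class.
#' @param p_lateral probability of a lateral upstream-upstream edge.
#' @return A [connectivity_table()] with a `ground_truth` attribute listing
#'   the generated per-class input percentages onto the target set.
#' @export
make_toy_connectome <- function(n_classes, n_per_class,
                                weight_spec = function(n)
                                  sample.int(8L, n, replace = TRUE),
                                seed = 1L, n_targets = 2L,
                                p_lateral = 0.15) {
  stopifnot(n_classes >= 1)
  n_per_class <- rep_len(n_per_class, n_classes)
  if (any(n_per_class < 1)) stop("every class must contain >= 1 neuron")
  with_seed(seed, {
    classes <- sprintf("C%02d", seq_len(n_classes))
    ids <- unlist(lapply(seq_len(n_classes), function(i)
      sprintf("%s_n%02d", classes[i], seq_len(n_per_class[i]))))
    class_map <- rep(classes, times = n_per_class)
    names(class_map) <- ids
    targets <- sprintf("TARGET_n%02d", seq_len(n_targets))
    class_map <- c(class_map, stats::setNames(rep("TARGET", n_targets),
                                              targets))
    pre <- rep(ids, each = n_targets)
    post <- rep(targets, times = length(ids))
    w <- as.integer(weight_spec(length(pre)))
    if (any(w <= 0)) stop("weight_spec must return positive integers")
    edges <- data.frame(pre = pre, post = post, count = w,
                        stringsAsFactors = FALSE)
    # lateral upstream edges (never target -> anything: targets are sinks)
    if (length(ids) > 1L && p_lateral > 0) {
      cand <- expand.grid(pre = ids, post = ids, stringsAsFactors = FALSE)
      cand <- cand[cand$pre != cand$post, ]
      keep <- stats::runif(nrow(cand)) < p_lateral
      if (any(keep)) {
        lat <- cand[keep, ]
        lat$count <- as.integer(weight_spec(nrow(lat)))
        edges <- rbind(edges, lat)
      }
    }
    tab <- connectivity_table(edges, class_map)
    by_class <- tapply(w, class_map[pre], sum)
    gt <- stats::setNames(as.numeric(100 * by_class / sum(w)),
                          names(by_class))
    attr(tab, "ground_truth") <- list(
      target_ids = targets,
      input_percent = gt[order(names(gt))])
    tab
  })
}
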