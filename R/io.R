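# Delimited-text and image I/O for every pipeline stage. All tables are
# tab-separated with a header so they round-trip through read.delim.

#' Write and read boundaries as delimited text
#'
#' One row per boundary point: `frame`, `index`, `x`, `y`.
#'
#' @param boundaries a `worm_boundary` or list of them (one per frame).
#' @param path output file.
#' @export
write_boundary <- function(boundaries, path) {
  if (inherits(boundaries, "worm_boundary")) boundaries <- list(boundaries)
  tab <- do.call(rbind, lapply(seq_along(boundaries), function(t) {
    b <- boundaries[[t]]
    data.frame(frame = t, index = seq_len(b$n_points),
               x = b$points[, 1L], y = b$points[, 2L])
  }))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_boundary
#' @return `read_boundary()`: a list of `worm_boundary` objects.
#' @export
read_boundary <- function(path) {
  tab <- utils::read.delim(path)
  lapply(split(tab, tab$frame), function(d)
    as_worm_boundary(cbind(d$x[order(d$index)], d$y[order(d$index)])))
}

#' Write curvature profiles as delimited text
#'
#' One row per boundary point: `frame`, `index`, `x`, `y`, `ci`.
#'
#' @param profiles a `curvature_profile` or list of them.
#' @param path output file.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "curvature_profile")) profiles <- list(profiles)
  tab <- do.call(rbind, lapply(seq_along(profiles), function(t) {
    p <- profiles[[t]]
    data.frame(frame = t, index = seq_along(p$ci),
               x = p$boundary$points[, 1L], y = p$boundary$points[, 2L],
               ci = p$ci)
  }))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a kymograph to delimited text and a heat-map image
#'
#' `write_kymograph()` writes the aligned CI matrix (frames x points) as
#' tab-separated text plus a per-frame offsets/tips table; if `png_path`
#' is given it also renders the diverging-colour heat map.
#'
#' @param kymo a `kymograph`.
#' @param matrix_path CI matrix output file.
#' @param meta_path offsets/tips table output file (default: derived).
#' @param png_path optional heat-map PNG.
#' @export
write_kymograph <- function(kymo, matrix_path,
                            meta_path = paste0(matrix_path, ".meta"),
                            png_path = NULL) {
  stopifnot(inherits(kymo, "kymograph"))
  utils::write.table(kymo$ci, matrix_path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- cbind(kymo$offsets, kymo$tips[, c("head", "tail")])
  utils::write.table(meta, meta_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(png_path)) {
    z <- kymo$ci
    lim <- max(abs(z), 1e-12)
    pal <- grDevices::colorRampPalette(
      c("#2166ac", "#f7f7f7", "#b2182b"))(255)
    col_idx <- matrix(findInterval(z, seq(-lim, lim,
                                          length.out = 256)[-256]),
                      nrow(z), ncol(z))
    rgb <- grDevices::col2rgb(pal[col_idx]) / 255
    arr <- array(NA_real_, c(ncol(z), nrow(z), 3))  # rows = points
    for (k in 1:3)
      arr[, , k] <- t(matrix(rgb[k, ], nrow(z), ncol(z)))
    png::writePNG(arr, png_path)
  }
  invisible(matrix_path)
}

#' Read a kymograph CI matrix written by [write_kymograph()]
#' @param matrix_path CI matrix file.
#' @return Numeric matrix (frames x points).
#' @export
read_kymograph_matrix <- function(matrix_path) {
  as.matrix(utils::read.delim(matrix_path, header = FALSE))
}

#' Write and read fluorescence/temperature traces
#'
#' Plain two-column (`time`, `value`) tab-separated tables, with an
#' optional `roi` column.
#'
#' @param trace data frame with `time`, `value` (and optionally `roi`).
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(trace, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  utils::read.delim(path)
}

#' Read a connectome from edge-list and class-map files
#'
#' `edges_path`: tab-separated with header `pre`, `post`, `count`;
#' `classes_path`: header `id`, `class` (optional `side`).
#'
#' @param edges_path,classes_path file paths.
#' @return A [connectivity_table()].
#' @export
read_connectome <- function(edges_path, classes_path) {
  e <- utils::read.delim(edges_path, colClasses = c(pre = "character",
                                                    post = "character"))
  cm <- utils::read.delim(classes_path, colClasses = "character")
  class_map <- stats::setNames(cm$class, cm$id)
  side_map <- if ("side" %in% names(cm)) stats::setNames(cm$side, cm$id)
  connectivity_table(e, class_map, side_map)
}

#' Write a connectome's edge list and class map
#' @param table a `connectivity_table`.
#' @param edges_path,classes_path output file paths.
#' @export
write_connectome <- function(table, edges_path, classes_path) {
  stopifnot(inherits(table, "connectivity_table"))
  utils::write.table(table$edges, edges_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cm <- data.frame(id = names(table$class_map),
                   class = unname(table$class_map))
  if (!is.null(table$side_map))
    cm$side <- unname(table$side_map[cm$id])
  utils::write.table(cm, classes_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(edges_path)
}

#' Write and read a synthetic scene
#'
#' Frames go to a multi-page TIFF (intensities rescaled to `[0, 1]` by
#' `/255`); the ground truth (frame, kappa, anchor, heading) to a
#' tab-separated sidecar.
#'
#' @param scene a `synthetic_scene`.
#' @param tiff_path multi-page TIFF output path.
#' @param truth_path ground-truth table path (default: derived).
#' @export
write_scene <- function(scene, tiff_path,
                        truth_path = paste0(tiff_path, ".truth")) {
  stopifnot(inherits(scene, "synthetic_scene"))
  tiff::writeTIFF(lapply(scene$frames, function(f) f / 255), tiff_path)
  utils::write.table(scene$ground_truth, truth_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(tiff_path)
}

#' @rdname write_scene
#' @return `read_scene_frames()`: list of numeric matrices on the original
#'   0-255 intensity scale.
#' @export
read_scene_frames <- function(tiff_path) {
  fr <- tiff::readTIFF(tiff_path, all = TRUE)
  lapply(fr, function(f) f * 255)
}

#' Read a directory of numbered PNG frames
#'
#' Frames are read in lexicographic filename order (zero-pad frame numbers
#' when writing); colour images are averaged to grayscale.
#'
#' @param dir directory containing `.png` frames.
#' @return List of numeric matrices on the 0-255 intensity scale.
#' @export
read_frame_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no PNG frames found in ", dir)
  lapply(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 3L) a <- apply(a[, , 1:3, drop = FALSE], c(1, 2),
                                         mean)
    a * 255
  })
}

#' Write a scene as numbered PNG frames
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if missing).
#' @export
write_frame_dir <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in seq_along(scene$frames))
    png::writePNG(scene$frames[[t]] / 255,
                  file.path(dir, sprintf("frame_%04d.png", t)))
  invisible(dir)
}
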