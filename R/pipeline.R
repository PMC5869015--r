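#' Pipeline configuration
#'
#' Collects the tunable parameters of the curvature and calcium pipelines
#' with their standard defaults: 300 boundary points, a flank distance of
#' 10 index positions for the curvature circle, a 25-point head/tail
#' exclusion zone, the low/high cutoff recomputed from the control group
#' (`"auto"`; the literal 0.027 1/px used on the original recordings can
#' be supplied instead, but is only meaningful at that recording's
#' resolution), automatic (Otsu) thresholding, a size filter at 1\% of
#' the image area, and temperature bin edges `c(25, 38.5, 49)`.
#'
#' @param n_points,flank,exclusion,cutoff,threshold,min_area,bin_edges,seed
#'   see Details; `cutoff` and `threshold` accept `"auto"` or a number.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_points = 300L, flank = 10L, exclusion = 25L,
                       cutoff = "auto", threshold = "auto",
                       min_area = NULL, bin_edges = c(25, 38.5, 49),
                       seed = 1L) {
  structure(list(n_points = as.integer(n_points), flank = as.integer(flank),
                 exclusion = as.integer(exclusion), cutoff = cutoff,
                 threshold = threshold, min_area = min_area,
                 bin_edges = bin_edges, seed = as.integer(seed)),
            class = "run_config")
}

#' Write and read a configuration as key: value text
#' @param config a [run_config()].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste0(k, ": ", paste(config[[k]], collapse = ",")), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  kv <- regmatches(lines, regexec("^([^:]+): ?(.*)$", lines))
  cfg <- run_config()
  for (m in kv) {
    if (length(m) < 3) next
    key <- m[2L]; val <- m[3L]
    if (!key %in% names(cfg)) next
    parsed <- strsplit(val, ",", fixed = TRUE)[[1L]]
    num <- suppressWarnings(as.numeric(parsed))
    cfg[[key]] <- if (any(is.na(num))) parsed else num
  }
  cfg$n_points <- as.integer(cfg$n_points)
  cfg$flank <- as.integer(cfg$flank)
  cfg$exclusion <- as.integer(cfg$exclusion)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Process one silhouette scene into a kymograph
#'
#' Runs the per-frame stages: threshold (unless the scene already provides
#' masks), size filter, boundary extraction, curvature profile, then
#' cross-frame alignment into a kymograph.
#'
#' @param scene a `synthetic_scene`, a list of grayscale frame matrices,
#'   or a list of logical masks.
#' @param config a [run_config()].
#' @return List with `boundaries`, `profiles`, `kymo`.
#' @export
process_scene <- function(scene, config = run_config()) {
  frames <- if (inherits(scene, "synthetic_scene")) scene$frames else scene
  level <- if (identical(config$threshold, "auto")) NULL else
    as.numeric(config$threshold)
  boundaries <- vector("list", length(frames))
  profiles <- vector("list", length(frames))
  for (t in seq_along(frames)) {
    f <- frames[[t]]
    mask <- if (is.logical(f)) f else threshold_frame(f, level)
    mask <- size_filter(mask, config$min_area)
    boundaries[[t]] <- extract_boundary(mask, config$n_points)
    profiles[[t]] <- curvature_profile(boundaries[[t]], config$flank)
  }
  kymo <- build_kymograph(boundaries, profiles)
  list(boundaries = boundaries, profiles = profiles, kymo = kymo)
}

#' Run the two-group curvature study end to end
#'
#' The complete posture workflow: every scene is thresholded, cleaned,
#' parametrised and aligned into a kymograph; the low/high CI cutoff is
#' taken from the control group (median of pooled positive included CI)
#' unless fixed in the config; each animal is summarised as percent
#' low/high concave curvature; groups are compared on `pct_high`.
#'
#' @param control_scenes,test_scenes lists of scenes (see
#'   [process_scene()]); >= 2 per group for the group test.
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, every intermediate
#'   (boundaries, profiles, kymographs, summaries, config) is persisted
#'   as delimited text.
#' @return List of class `curvature_study`: `cutoff`, `summaries` (data
#'   frame), `test` (a `curvature_group_test`), `kymos`.
#' @export
run_curvature_study <- function(control_scenes, test_scenes,
                                config = run_config(), out_dir = NULL) {
  stopifnot(length(control_scenes) >= 1, length(test_scenes) >= 1)
  proc <- function(scenes, tag) lapply(seq_along(scenes), function(i) {
    res <- tryCatch(process_scene(scenes[[i]], config),
                    error = function(e) stop(tag, " scene ", i, ": ",
                                             conditionMessage(e)))
    res
  })
  ctrl <- proc(control_scenes, "control")
  test <- proc(test_scenes, "test")
  cutoff <- if (identical(config$cutoff, "auto"))
    cutoff_from_control(lapply(ctrl, `[[`, "kymo"), config$exclusion)
  else as.numeric(config$cutoff)
  summ <- function(group, tag) do.call(rbind, lapply(
    seq_along(group), function(i)
      summarize_animal(group[[i]]$kymo, cutoff, config$exclusion,
                       animal_id = paste0(tag, i))))
  s_ctrl <- summ(ctrl, "control")
  s_test <- summ(test, "test")
  test_report <- if (nrow(s_ctrl) >= 2 && nrow(s_test) >= 2)
    compare_groups(s_ctrl, s_test) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_config(config, file.path(out_dir, "config.txt"))
    all_g <- c(ctrl, test)
    tags <- c(paste0("control", seq_along(ctrl)),
              paste0("test", seq_along(test)))
    for (i in seq_along(all_g)) {
      write_boundary(all_g[[i]]$boundaries,
                     file.path(out_dir, paste0(tags[i], "_boundary.tsv")))
      write_profiles(all_g[[i]]$profiles,
                     file.path(out_dir, paste0(tags[i], "_profiles.tsv")))
      write_kymograph(all_g[[i]]$kymo,
                      file.path(out_dir, paste0(tags[i], "_kymo.tsv")),
                      png_path = file.path(out_dir,
                                           paste0(tags[i], "_kymo.png")))
    }
    utils::write.table(rbind(s_ctrl, s_test),
                       file.path(out_dir, "summaries.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  structure(list(cutoff = cutoff, summaries = rbind(s_ctrl, s_test),
                 test = test_report,
                 kymos = list(control = lapply(ctrl, `[[`, "kymo"),
                              test = lapply(test, `[[`, "kymo"))),
            class = "curvature_study")
}

#' @export
print.curvature_study <- function(x, ...) {
  cat(sprintf("curvature_study: cutoff %.4g 1/px, %d animals\n",
              x$cutoff, nrow(x$summaries)))
  print(x$summaries[, c("animal_id", "pct_low", "pct_high")],
        row.names = FALSE)
  if (!is.null(x$test)) print(x$test)
  invisible(x)
}

#' Build a synthetic cohort of bend scenes
#'
#' One bend-deepening scene per animal, with per-animal jitter in body
#' length and final curvature so cohorts have realistic between-animal
#' variability.
#'
#' @param n_animals scenes to generate.
#' @param kappa_final mean final midline curvature, 1/px.
#' @param n_frames frames per scene.
#' @param seed integer seed (per-animal seeds derive from it).
#' @param body_length,max_half_width,image_size base larva geometry, px.
#' @param jitter fractional s.d. of per-animal length/curvature jitter.
#' @return List of `synthetic_scene` objects.
#' @export
make_cohort <- function(n_animals, kappa_final, n_frames = 8L, seed = 1L,
                        body_length = 220, max_half_width = 12,
                        image_size = 360, jitter = 0.08) {
  with_seed(seed, {
    lapply(seq_len(n_animals), function(i) {
      len <- body_length * (1 + stats::rnorm(1, 0, jitter))
      kf <- kappa_final * (1 + stats::rnorm(1, 0, jitter))
      spec <- worm_spec(body_length = len,
                        max_half_width = max_half_width,
                        kappa = kappa_final / 10,
                        image_height = image_size,
                        image_width = image_size,
                        seed = seed + i)
      make_bend_sequence(spec, kf, n_frames)
    })
  })
}

#' Write the standard fixture bundle
#'
#' Generates and persists the scenes, traces, and toy connectome the test
#' suite exercises: a straight worm scene, a C-bend deepening scene, a
#' thermal-ramp trace pair, and a toy connectome — all deterministic for a
#' fixed seed.
#'
#' @param out_dir writable output directory (created if missing).
#' @param seed integer seed.
#' @return Invisibly, the list of files written.
#' @export
generate_fixtures <- function(out_dir, seed = 1L) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable")
  straight <- make_bend_sequence(
    worm_spec(body_length = 200, max_half_width = 12,
              image_height = 300, image_width = 300, seed = seed),
    kappa_final = 1e-4, n_frames = 2L)
  bend <- make_bend_sequence(
    worm_spec(body_length = 220, max_half_width = 12,
              image_height = 360, image_width = 360, seed = seed),
    kappa_final = 1 / 80, n_frames = 6L)
  ramp <- make_ramp_trace(n_frames = 150, frame_rate = 5, gain = 1,
                          noise_sd = 1, seed = seed)
  conn <- make_toy_connectome(4, 3, seed = seed)
  files <- c(
    straight = write_scene(straight, file.path(out_dir, "straight.tiff")),
    bend = write_scene(bend, file.path(out_dir, "bend.tiff")),
    fluor = write_trace(ramp$fluor, file.path(out_dir, "ramp_fluor.tsv")),
    temp = write_trace(ramp$temp, file.path(out_dir, "ramp_temp.tsv")),
    edges = write_connectome(conn, file.path(out_dir, "connectome_edges.tsv"),
                             file.path(out_dir, "connectome_classes.tsv")))
  invisible(files)
}
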