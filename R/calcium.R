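# Accept either a numeric vector or a data.frame(time, value) trace.
trace_values <- function(trace) {
  if (is.data.frame(trace)) {
    stopifnot(all(c("time", "value") %in% names(trace)))
    if (any(diff(trace$time) <= 0))
      stop("trace times must be strictly increasing")
    trace$value
  } else as.numeric(trace)
}

#' Lowest-decile baseline fluorescence
#'
#' Baseline F0 for ramp imaging: the mean of the lowest 10\% of the
#' fluorescence samples (sample count rounded up, so n = 10 uses the
#' single smallest value). With zero-mean noise this estimator is biased
#' low by about 1.75 standard deviations of the noise — see the package
#' vignette for when that matters.
#'
#' @param trace numeric vector or data frame with `time`, `value`;
#'   >= 10 samples.
#' @return Baseline F0 (> 0).
#' @export
baseline_lowest_decile <- function(trace) {
  v <- trace_values(trace)
  if (length(v) < 10) stop("need >= 10 samples for a decile baseline")
  k <- ceiling(0.1 * length(v))
  f0 <- mean(sort(v)[seq_len(k)])
  if (f0 <= 0) stop("baseline F0 <= 0: dF/F undefined")
  f0
}

#' Pre-stimulus baseline fluorescence
#'
#' Baseline F0 for activation imaging: the mean fluorescence over a window
#' of at least 3 s ending at stimulus onset (`[onset - window, onset)`).
#'
#' @param trace data frame with `time` (s), `value`.
#' @param stim_onset stimulus onset time, s.
#' @param window baseline window length, s (>= 3).
#' @return Baseline F0.
#' @export
baseline_prestim <- function(trace, stim_onset, window = 3) {
  stopifnot(is.data.frame(trace))
  if (window < 3) stop("baseline window must be at least 3 s")
  if (stim_onset - window < trace$time[1L])
    stop("baseline window extends before the start of the trace")
  sel <- trace$time >= stim_onset - window & trace$time < stim_onset
  if (!any(sel)) stop("no samples in the baseline window")
  mean(trace$value[sel])
}

#' Fractional fluorescence change
#'
#' Elementwise `(F - F0) / F0`. Values are fractions; multiply by 100 for
#' percent when rendering.
#'
#' @param trace numeric vector or data frame with `value`.
#' @param f0 baseline fluorescence (> 0).
#' @return Numeric vector of dF/F0 values.
#' @export
dff <- function(trace, f0) {
  if (f0 <= 0) stop("F0 must be positive")
  (trace_values(trace) - f0) / f0
}

#' Interpolate probe temperature at frame times
#'
#' The temperature probe is digitised at 4 Hz, asynchronously from the
#' imaging frames, so the temperature at each frame is estimated by
#' piecewise-linear interpolation of the probe trace. Frame times outside
#' the probe record are clamped to the first/last probe sample and flagged
#' in the `clamped` attribute.
#'
#' @param temp data frame with `time` (s), `value` (degrees C).
#' @param frame_times numeric vector of frame acquisition times, s.
#' @return Numeric vector of per-frame temperatures with a logical
#'   `clamped` attribute.
#' @export
temperature_at_frames <- function(temp, frame_times) {
  stopifnot(is.data.frame(temp))
  if (nrow(temp) == 0) stop("empty temperature trace")
  if (any(diff(temp$time) <= 0))
    stop("temperature times must be strictly increasing")
  out <- stats::approx(temp$time, temp$value, xout = frame_times,
                       rule = 2)$y
  clamped <- frame_times < temp$time[1L] |
    frame_times > temp$time[nrow(temp)]
  if (any(clamped))
    warning(sum(clamped), " frame time(s) outside the probe record; ",
            "clamped to the endpoint values")
  attr(out, "clamped") <- clamped
  out
}

#' Bin dF/F by stimulus temperature
#'
#' Splits the recording at the peak-temperature frame into heating and
#' cooling phases, then averages dF/F in three bins: heating frames below
#' the noxious threshold edge, heating frames at or above it, and all
#' post-peak (cooling) frames. The default edges `c(25, 38.5, 49)` place
#' the sub/supra split midway in the gap between the conventional 25-38
#' and 39-49 degree bins. Empty bins are reported as `NA` and flagged,
#' never as zero.
#'
#' @param dff_series numeric vector of per-frame dF/F values.
#' @param frame_temps numeric vector of per-frame temperatures (degrees C).
#' @param bin_edges numeric length-3: lower bound, sub/supra split edge,
#'   upper bound of the heating bins.
#' @param peak_split if `TRUE` (default) the cooling bin is every frame
#'   after the global temperature maximum; if `FALSE` no cooling bin is
#'   reported and all frames are binned by temperature alone.
#' @return Data frame with one row per bin: `bin`, `mean_dff`, `n`,
#'   `empty`.
#' @export
bin_by_temperature <- function(dff_series, frame_temps,
                               bin_edges = c(25, 38.5, 49),
                               peak_split = TRUE) {
  stopifnot(length(dff_series) == length(frame_temps),
            length(bin_edges) == 3, !is.unsorted(bin_edges))
  n <- length(dff_series)
  peak <- which.max(frame_temps)
  heating <- if (peak_split) seq_len(n) <= peak else rep(TRUE, n)
  sub <- heating & frame_temps >= bin_edges[1L] &
    frame_temps < bin_edges[2L]
  supra <- heating & frame_temps >= bin_edges[2L]
  bins <- list(sub_threshold = sub, supra_threshold = supra)
  if (peak_split) bins$cooling <- !heating
  out <- do.call(rbind, lapply(names(bins), function(b) {
    sel <- bins[[b]]
    data.frame(bin = b,
               mean_dff = if (any(sel)) mean(dff_series[sel]) else NA_real_,
               n = sum(sel), empty = !any(sel),
               stringsAsFactors = FALSE)
  }))
  out
}
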