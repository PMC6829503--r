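#' Compute delta-F/F0 from a raw fluorescence trace
#'
#' Normalizes a ROI-mean fluorescence series against its grand mean:
#' `dff[i] = (f[i] - mean(f)) / mean(f)`. The result is dimensionless and
#' has zero mean by construction, which puts the 0.04 event threshold on
#' the conventional delta-F/F0 scale.
#'
#' @param trace A [fluorescence_trace()].
#' @return A `DffTrace` (not yet baseline corrected).
#' @export
compute_dff <- function(trace) {
  stopifnot(inherits(trace, "FluorescenceTrace"))
  f0 <- mean(trace$f)
  if (!is.finite(f0) || f0 <= 0)
    stop("mean fluorescence must be positive; empty or invalid ROI?",
         call. = FALSE)
  dff_trace(trace$t, (trace$f - f0) / f0, trace$rate_hz,
            baseline_corrected = FALSE)
}

#' Correct slow baseline drift in a delta-F/F0 trace
#'
#' Removes photobleaching and other slow drift by subtracting, at every
#' sample, the mean of the sub-median values (all window values strictly
#' below the window median) within a sliding window centered on the
#' sample. Windows are truncated at the trace edges. Using only the lower
#' half of the window makes the baseline estimate insensitive to the
#' positive-going calcium transients riding on it.
#'
#' For a window whose values are all identical (no value strictly below
#' the median) the baseline is defined as the median itself, so constant
#' traces pass through unchanged.
#'
#' @param dff A `DffTrace`.
#' @param window_s Sliding window width in seconds (default 20). Must span
#'   at least 3 samples at the trace's sampling rate.
#' @return A `DffTrace` with `baseline_corrected = TRUE`.
#' @export
correct_drift <- function(dff, window_s = 20) {
  stopifnot(inherits(dff, "DffTrace"))
  x <- dff$dff
  n <- length(x)
  if (round(window_s * dff$rate_hz) < 3)
    stop("window_s must span at least 3 samples", call. = FALSE)
  h <- max(1L, as.integer(round(window_s * dff$rate_hz / 2)))
  base <- numeric(n)
  for (i in seq_len(n)) {
    w <- x[max(1L, i - h):min(n, i + h)]
    med <- stats::median(w)
    low <- w[w < med]
    base[i] <- if (length(low)) mean(low) else med
  }
  dff_trace(dff$t, x - base, dff$rate_hz, baseline_corrected = TRUE)
}

#' Detect calcium uptake events
#'
#' Flags maximal runs of samples whose drift-corrected delta-F/F0 exceeds
#' the threshold (default 0.04). Two deterministic curation rules replace
#' the manual review of the original procedure: runs separated by a
#' sub-threshold gap of at most `merge_gap_s` are merged into a single
#' event, and merged runs lasting `min_dur_s` or less are discarded —
#' seizure-associated calcium transients last seconds, so an isolated
#' supra-threshold blip of one or two frames at 2 Hz is noise (the
#' sub-median baseline estimator of [correct_drift()] sits slightly below
#' the noise mean, which makes such blips more likely than the raw
#' threshold suggests). Event onset is the time of the first
#' supra-threshold sample; offset is the time of the first sub-threshold
#' sample after the run (half-open window). Events clipped by the trace
#' boundary are kept and flagged `truncated`.
#'
#' @param dff A `DffTrace`; a warning is issued if drift correction has
#'   not been applied.
#' @param threshold Event threshold in delta-F/F0 units (default 0.04).
#' @param merge_gap_s Maximum sub-threshold gap (seconds) across which two
#'   runs are merged (default 1).
#' @param min_dur_s Minimum event duration in seconds, strict (default 1,
#'   i.e. at least three frames at 2 Hz).
#' @return A `DetectedEvents` data frame (possibly zero rows).
#' @export
detect_calcium_events <- function(dff, threshold = 0.04, merge_gap_s = 1,
                                  min_dur_s = 1) {
  stopifnot(inherits(dff, "DffTrace"))
  if (!isTRUE(dff$baseline_corrected))
    warning("detecting events on a trace without drift correction",
            call. = FALSE)
  .detect_runs(dff$t, dff$dff, dff$dff > threshold, dff$rate_hz,
               merge_gap_s = merge_gap_s, min_dur_s = min_dur_s,
               peak_fun = which.max)
}

#' Event rate in events per hour
#'
#' @param events A `DetectedEvents` data frame.
#' @param duration_s Recording duration in seconds.
#' @return Events per hour.
#' @export
event_rate <- function(events, duration_s) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be > 0", call. = FALSE)
  nrow(events) * 3600 / duration_s
}
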