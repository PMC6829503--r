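#' Zero-phase band-pass filter for LFP traces
#'
#' Applies the acquisition band of the electrophysiology setup — a 0.1 Hz
#' high-pass and a 1 kHz low-pass — as zero-phase digital Butterworth
#' filters (forward-backward, [signal::filtfilt()]). The high-pass stage
#' (order 1) removes DC and electrode drift; the low-pass stage (order 4)
#' removes high-frequency noise. Run as two cascaded stages because a
#' single band-pass with such an extreme cutoff ratio is numerically
#' fragile.
#'
#' @param trace An [lfp_trace()].
#' @param hp_hz High-pass cutoff in Hz (default 0.1).
#' @param lp_hz Low-pass cutoff in Hz (default 1000). Must satisfy
#'   `hp_hz < lp_hz < rate_hz / 2`.
#' @return A filtered `LfpTrace`.
#' @export
bandpass_lfp <- function(trace, hp_hz = 0.1, lp_hz = 1000) {
  stopifnot(inherits(trace, "LfpTrace"))
  nyq <- trace$rate_hz / 2
  if (!(hp_hz < lp_hz && lp_hz < nyq))
    stop("cutoffs must satisfy hp_hz < lp_hz < rate_hz/2 (nyquist ",
         nyq, " Hz)", call. = FALSE)
  hp <- signal::butter(1, hp_hz / nyq, type = "high")
  lp <- signal::butter(4, lp_hz / nyq, type = "low")
  # explicit demeaning: in short records the 0.1 Hz high-pass alone
  # cannot settle on the DC level
  v <- trace$v - mean(trace$v)
  v <- signal::filtfilt(lp, signal::filtfilt(hp, v))
  lfp_trace(trace$t, v, trace$rate_hz)
}

#' Detect ictal-like events in an LFP trace
#'
#' An event is a downward membrane-potential deflection below `amp_mv`
#' (default -0.3 mV, signed threshold on the baseline-centered signal)
#' lasting more than `min_dur_s` (default 100 ms). Because ictal-like
#' discharges are multi-spike bursts whose envelope briefly re-crosses the
#' threshold between spikes, sub-threshold gaps of at most `merge_gap_s`
#' (default 50 ms) are bridged before the duration rule is applied, so a
#' burst counts as one event. Duration is measured between the threshold
#' crossings, and the peak is the most negative sample of the run.
#'
#' The trace is assumed baseline-centered (apply [bandpass_lfp()] to raw
#' recordings first).
#'
#' @param trace An `LfpTrace`.
#' @param amp_mv Amplitude threshold in mV, negative (default -0.3).
#' @param min_dur_s Minimum event duration in seconds, strict (default 0.1).
#' @param merge_gap_s Maximum bridged sub-threshold gap in seconds
#'   (default 0.05).
#' @return A `DetectedEvents` data frame.
#' @export
detect_lfp_events <- function(trace, amp_mv = -0.3, min_dur_s = 0.1,
                              merge_gap_s = 0.05) {
  stopifnot(inherits(trace, "LfpTrace"))
  if (amp_mv >= 0) stop("amp_mv must be negative (downward events)", call. = FALSE)
  .detect_runs(trace$t, trace$v, trace$v < amp_mv, trace$rate_hz,
               merge_gap_s = merge_gap_s, min_dur_s = min_dur_s,
               peak_fun = which.min)
}
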