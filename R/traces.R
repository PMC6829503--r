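#' Fluorescence trace
#'
#' Container for a region-of-interest mean fluorescence time series sampled
#' on a uniform grid, e.g. the optic-tectum ROI mean of a GCaMP recording
#' acquired at 2 Hz.
#'
#' @param t Sample times in seconds, strictly increasing, uniformly spaced.
#' @param f Fluorescence values (arbitrary units), same length as `t`.
#' @param rate_hz Sampling rate in Hz; must agree with the spacing of `t`
#'   to a relative tolerance of 1e-6.
#' @return An object of class `FluorescenceTrace` with fields `t`, `f`,
#'   `rate_hz`.
#' @export
fluorescence_trace <- function(t, f, rate_hz) {
  .check_grid(t, f, rate_hz, "f")
  structure(list(t = as.numeric(t), f = as.numeric(f), rate_hz = rate_hz),
            class = "FluorescenceTrace")
}

#' Normalized fluorescence (delta-F/F0) trace
#'
#' @param t Sample times in seconds.
#' @param dff Dimensionless delta-F/F0 values.
#' @param rate_hz Sampling rate in Hz.
#' @param baseline_corrected Logical; `TRUE` once slow drift has been
#'   removed by [correct_drift()].
#' @return An object of class `DffTrace`.
#' @export
dff_trace <- function(t, dff, rate_hz, baseline_corrected = FALSE) {
  .check_grid(t, dff, rate_hz, "dff")
  structure(list(t = as.numeric(t), dff = as.numeric(dff), rate_hz = rate_hz,
                 baseline_corrected = isTRUE(baseline_corrected)),
            class = "DffTrace")
}

#' Local field potential trace
#'
#' @param t Sample times in seconds.
#' @param v Voltage in mV.
#' @param rate_hz Sampling rate in Hz.
#' @return An object of class `LfpTrace`.
#' @export
lfp_trace <- function(t, v, rate_hz) {
  .check_grid(t, v, rate_hz, "v")
  structure(list(t = as.numeric(t), v = as.numeric(v), rate_hz = rate_hz),
            class = "LfpTrace")
}

.check_grid <- function(t, x, rate_hz, name) {
  if (length(t) != length(x))
    stop("t and ", name, " must have the same length", call. = FALSE)
  if (length(t) < 2) stop("trace needs at least 2 samples", call. = FALSE)
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop("rate_hz must be > 0", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0)) stop("t must be strictly increasing", call. = FALSE)
  if (max(abs(dt * rate_hz - 1)) > 1e-6)
    stop("rate_hz inconsistent with the spacing of t", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.FluorescenceTrace <- function(x, ...) {
  cat(sprintf("FluorescenceTrace: %d samples at %g Hz (%.1f s)\n",
              length(x$t), x$rate_hz, x$t[length(x$t)] - x$t[1]))
  invisible(x)
}

#' @export
print.DffTrace <- function(x, ...) {
  cat(sprintf("DffTrace: %d samples at %g Hz, baseline_corrected = %s\n",
              length(x$t), x$rate_hz, x$baseline_corrected))
  invisible(x)
}

#' @export
print.LfpTrace <- function(x, ...) {
  cat(sprintf("LfpTrace: %d samples at %g Hz (%.1f s)\n",
              length(x$t), x$rate_hz, x$t[length(x$t)] - x$t[1]))
  invisible(x)
}

#' Build an event table
#'
#' Events are stored as a data frame with one row per detected event and
#' columns `onset_s`, `offset_s`, `peak_value`, `peak_time_s`,
#' `duration_s`, `truncated`. Windows are half-open `[onset, offset)`,
#' sorted and non-overlapping.
#'
#' @param onset_s,offset_s Event window bounds in seconds.
#' @param peak_value Extreme value inside the window (max delta-F/F0 for
#'   calcium, min mV for LFP).
#' @param peak_time_s Time of the extreme value.
#' @param truncated Logical; event clipped by a trace boundary.
#' @return A `DetectedEvents` data frame.
#' @export
detected_events <- function(onset_s = numeric(), offset_s = numeric(),
                            peak_value = numeric(), peak_time_s = numeric(),
                            truncated = logical()) {
  if (any(offset_s <= onset_s)) stop("offset must exceed onset", call. = FALSE)
  if (length(onset_s) > 1) {
    o <- order(onset_s)
    onset_s <- onset_s[o]; offset_s <- offset_s[o]
    peak_value <- peak_value[o]; peak_time_s <- peak_time_s[o]
    truncated <- truncated[o]
    if (any(onset_s[-1] < offset_s[-length(offset_s)]))
      stop("event windows must not overlap", call. = FALSE)
  }
  out <- data.frame(onset_s = onset_s, offset_s = offset_s,
                    peak_value = peak_value, peak_time_s = peak_time_s,
                    duration_s = offset_s - onset_s,
                    truncated = truncated)
  class(out) <- c("DetectedEvents", "data.frame")
  out
}

# Threshold run detector shared by the calcium and LFP paths.
# above: logical vector marking supra-threshold samples. Runs closer than
# merge_gap_s (gap measured in seconds between the offset of one run and
# the onset of the next) are merged; runs with duration <= min_dur_s are
# dropped ("lasting more than" is strict). Offset is the time of the first
# sub-threshold sample after the run, or t[n] + dt when the run touches the
# trace end (truncated = TRUE).
.detect_runs <- function(t, x, above, rate_hz, merge_gap_s, min_dur_s,
                         peak_fun) {
  n <- length(x)
  dt <- 1 / rate_hz
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  s <- starts[keep]; e <- ends[keep]
  if (length(s) == 0) return(detected_events())
  if (length(s) > 1) {
    # gap between run i offset (t[e_i]+dt boundary) and run i+1 onset
    gap_s <- t[s[-1]] - (t[e[-length(e)]] + dt)
    merge <- gap_s <= merge_gap_s
    grp <- cumsum(c(TRUE, !merge))
    s <- tapply(s, grp, min)
    e <- tapply(e, grp, max)
  }
  onset <- t[s]
  truncated <- (s == 1L) | (e == n)
  offset <- ifelse(e < n, t[e + 1L], t[n] + dt)
  pk_idx <- mapply(function(a, b) (a:b)[peak_fun(x[a:b])], s, e)
  ok <- (offset - onset) > min_dur_s
  detected_events(onset_s = onset[ok], offset_s = offset[ok],
                  peak_value = x[pk_idx][ok], peak_time_s = t[pk_idx][ok],
                  truncated = truncated[ok])
}

#' Write / read a trace as a two-column CSV
#'
#' @param trace A `FluorescenceTrace`, `DffTrace` or `LfpTrace`.
#' @param path Output CSV path (`time_s,value`).
#' @export
write_trace_csv <- function(trace, path) {
  val <- if (inherits(trace, "LfpTrace")) trace$v
         else if (inherits(trace, "DffTrace")) trace$dff
         else trace$f
  utils::write.csv(data.frame(time_s = trace$t, value = val), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param kind One of `"fluorescence"`, `"dff"`, `"lfp"`.
#' @export
read_trace_csv <- function(path, kind = c("fluorescence", "dff", "lfp")) {
  kind <- match.arg(kind)
  d <- utils::read.csv(path)
  if (ncol(d) < 2) stop("expected a two-column CSV (time_s, value)", call. = FALSE)
  t <- d[[1]]; x <- d[[2]]
  rate <- 1 / stats::median(diff(t))
  switch(kind,
         fluorescence = fluorescence_trace(t, x, rate),
         dff = dff_trace(t, x, rate),
         lfp = lfp_trace(t, x, rate))
}
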