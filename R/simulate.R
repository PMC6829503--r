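#' Simulation configuration
#'
#' Collects every knob of the trace simulators. Defaults emulate the
#' acquisition regime of the source experiments: calcium imaging at 2 Hz
#' for 1 h, LFP at 10 kHz (a desk-scale stand-in for the acquisition-rate
#' recording; configurable), seizure transients exceeding the 0.04
#' delta-F/F0 detection threshold and ictal-like bursts exceeding the
#' -0.3 mV / 100 ms rule.
#'
#' @param seed Integer RNG seed; a fixed seed makes every simulator
#'   bit-reproducible.
#' @param duration_s Recording length in seconds (default 3600).
#' @param calcium_rate_hz Calcium sampling rate in Hz (default 2).
#' @param lfp_rate_hz LFP sampling rate in Hz (default 10000).
#' @param n_events Number of planted events (>= 0).
#' @param event_amplitude_dff Peak transient amplitude in delta-F/F0 units
#'   (default 0.1; must exceed `calcium_threshold_dff`).
#' @param event_duration_s Mean above-threshold event duration in seconds
#'   (default 6). For [simulate_lfp_trace()] this is the burst envelope
#'   width at the -0.3 mV crossing; for [simulate_coupled_recording()] it
#'   is the LFP duration from which the calcium duration is derived.
#' @param event_duration_jitter_s Half-width of the uniform duration
#'   jitter in seconds (default 2; durations are
#'   `event_duration_s +/- jitter`).
#' @param lfp_amplitude_mv Burst envelope minimum in mV, negative
#'   (default -0.5; must be below `lfp_threshold_mv`).
#' @param noise_sd Gaussian noise SD of the calcium trace in delta-F/F0
#'   units (default 0.01).
#' @param lfp_noise_sd_mv Gaussian noise SD of the LFP trace in mV
#'   (default 0.05).
#' @param drift_model Baseline drift of the calcium trace: `"none"`,
#'   `"linear"` or `"exponential"`.
#' @param drift_magnitude Drift amplitude as a fraction of baseline
#'   fluorescence (e.g. 0.02 = 2% over the recording).
#' @param coupling_slope,coupling_intercept Linear map from LFP event
#'   duration to calcium event duration in the coupled simulator
#'   (defaults 1 and 2 s: the calcium transient outlasts the discharge).
#' @param coupling_jitter_sd SD in seconds of the Gaussian noise added to
#'   the calcium duration (see [coupling_jitter_for_r2()]).
#' @param onset_jitter_sd_s SD in seconds of the calcium-vs-LFP onset
#'   offset in the coupled simulator (default 0.2).
#' @param calcium_threshold_dff Detection threshold defining calcium truth
#'   windows (default 0.04).
#' @param lfp_threshold_mv Detection threshold defining LFP truth windows
#'   (default -0.3).
#' @param baseline_f Baseline fluorescence in arbitrary units (default 100).
#' @param lfp_spike_hz Intra-burst spike rate in Hz (default 80); bursts
#'   are rectified oscillations under a Gaussian envelope, giving the
#'   multi-spike character of ictal-like discharges.
#' @return A validated list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L,
                       duration_s = 3600,
                       calcium_rate_hz = 2,
                       lfp_rate_hz = 10000,
                       n_events = 10L,
                       event_amplitude_dff = 0.1,
                       event_duration_s = 6,
                       event_duration_jitter_s = 2,
                       lfp_amplitude_mv = -0.5,
                       noise_sd = 0.01,
                       lfp_noise_sd_mv = 0.05,
                       drift_model = c("none", "linear", "exponential"),
                       drift_magnitude = 0,
                       coupling_slope = 1,
                       coupling_intercept = 2,
                       coupling_jitter_sd = 0,
                       onset_jitter_sd_s = 0.2,
                       calcium_threshold_dff = 0.04,
                       lfp_threshold_mv = -0.3,
                       baseline_f = 100,
                       lfp_spike_hz = 80) {
  drift_model <- match.arg(drift_model)
  cfg <- list(seed = as.integer(seed), duration_s = duration_s,
              calcium_rate_hz = calcium_rate_hz, lfp_rate_hz = lfp_rate_hz,
              n_events = as.integer(n_events),
              event_amplitude_dff = event_amplitude_dff,
              event_duration_s = event_duration_s,
              event_duration_jitter_s = event_duration_jitter_s,
              lfp_amplitude_mv = lfp_amplitude_mv,
              noise_sd = noise_sd, lfp_noise_sd_mv = lfp_noise_sd_mv,
              drift_model = drift_model, drift_magnitude = drift_magnitude,
              coupling_slope = coupling_slope,
              coupling_intercept = coupling_intercept,
              coupling_jitter_sd = coupling_jitter_sd,
              onset_jitter_sd_s = onset_jitter_sd_s,
              calcium_threshold_dff = calcium_threshold_dff,
              lfp_threshold_mv = lfp_threshold_mv,
              baseline_f = baseline_f, lfp_spike_hz = lfp_spike_hz)
  stopifnot(cfg$n_events >= 0, cfg$duration_s > 0,
            cfg$calcium_rate_hz > 0, cfg$lfp_rate_hz > 0,
            cfg$event_duration_s > 0,
            cfg$event_duration_jitter_s >= 0,
            cfg$event_duration_jitter_s < cfg$event_duration_s,
            cfg$coupling_slope > 0, cfg$noise_sd >= 0,
            cfg$lfp_noise_sd_mv >= 0)
  if (cfg$event_amplitude_dff <= cfg$calcium_threshold_dff)
    stop("event_amplitude_dff must exceed calcium_threshold_dff",
         call. = FALSE)
  if (cfg$lfp_amplitude_mv >= cfg$lfp_threshold_mv)
    stop("lfp_amplitude_mv must be below lfp_threshold_mv", call. = FALSE)
  class(cfg) <- "SimConfig"
  cfg
}

# Draw n sorted onsets in [lo, hi] with consecutive spacing >= min_gap.
# Uses the exact construction (sorted uniforms in the slack interval plus
# the enforced gaps), which samples uniformly over admissible
# configurations and always terminates.
.place_onsets <- function(n, lo, hi, min_gap) {
  if (n == 0) return(numeric(0))
  slack <- (hi - lo) - (n - 1) * min_gap
  if (slack < 0)
    stop(sprintf(paste0("cannot fit %d events of span %.1f s into the ",
                        "available %.1f s; reduce n_events or event duration"),
                 n, min_gap, hi - lo), call. = FALSE)
  lo + sort(stats::runif(n, 0, slack)) + (seq_len(n) - 1) * min_gap
}

# Instantaneous-rise / exponential-decay transient train in dff units,
# sampled on t. Durations are the above-threshold widths.
.calcium_signal <- function(t, onsets, durations, amp, thr) {
  s <- numeric(length(t))
  if (length(onsets) == 0) return(s)
  tau <- durations / log(amp / thr)
  span <- durations * (1 + log(20) / log(amp / thr)) # decay to thr/20
  dt <- t[2] - t[1]
  for (k in seq_along(onsets)) {
    i0 <- max(1L, ceiling((onsets[k] - t[1]) / dt) + 1L)
    i1 <- min(length(t), floor((onsets[k] + span[k] - t[1]) / dt) + 1L)
    if (i0 > i1) next
    idx <- i0:i1
    s[idx] <- s[idx] + amp * exp(-(t[idx] - onsets[k]) / tau[k])
  }
  s
}

# Flat-top burst envelopes (negative) sampled on t: a sustained plateau
# at -amp with raised-cosine ramps, so the threshold crossing is steep
# and the burst edge does not fragment under recording noise. Durations
# are the widths at the thr (-0.3 mV) crossing; amp is the (negative)
# plateau level. Ramp length adapts to short bursts.
.lfp_envelope <- function(t, centers, durations, amp, thr) {
  e <- numeric(length(t))
  if (length(centers) == 0) return(e)
  dt <- t[2] - t[1]
  for (k in seq_along(centers)) {
    ramp <- min(0.1, durations[k] / 4)
    # distance from envelope start to the thr crossing on the cosine ramp
    u_cross <- ramp * acos(1 - 2 * thr / amp) / pi
    support <- durations[k] + 2 * u_cross
    t0 <- centers[k] - support / 2
    i0 <- max(1L, ceiling((t0 - t[1]) / dt) + 1L)
    i1 <- min(length(t), floor((t0 + support - t[1]) / dt) + 1L)
    if (i0 > i1) next
    idx <- i0:i1
    u <- t[idx] - t0
    prof <- rep(1, length(u))
    lo <- u < ramp
    hi <- u > support - ramp
    prof[lo] <- 0.5 * (1 - cos(pi * u[lo] / ramp))
    prof[hi] <- 0.5 * (1 - cos(pi * (support - u[hi]) / ramp))
    e[idx] <- e[idx] - amp * prof
  }
  e
}

.drift_curve <- function(t, model, mag, duration_s) {
  switch(model,
         none = numeric(length(t)),
         linear = mag * t / duration_s,
         exponential = mag * exp(-3 * t / duration_s))
}

.truth_windows <- function(t, s, above, rate_hz, merge_gap_s) {
  ev <- .detect_runs(t, s, above, rate_hz, merge_gap_s = merge_gap_s,
                     min_dur_s = 0, peak_fun = which.max)
  data.frame(onset_s = ev$onset_s, offset_s = ev$offset_s)
}

.ground_truth <- function(calcium_windows = NULL, lfp_windows = NULL,
                          pairs = NULL, puncta = NULL, cells = NULL) {
  structure(list(calcium_windows = calcium_windows,
                 lfp_windows = lfp_windows, pairs = pairs,
                 puncta = puncta, cells = cells),
            class = "GroundTruth")
}

#' Simulate a calcium fluorescence recording with planted seizure events
#'
#' Generates a ROI-mean fluorescence trace
#' `f = baseline * (1 + drift + transients + noise)` where each transient
#' has an instantaneous rise and exponential decay scaled so that its
#' above-threshold width equals the requested duration. Ground-truth event
#' windows are the contiguous supra-threshold runs of the noiseless
#' delta-F/F0 signal — the same definition the detector uses — so in the
#' noiseless limit detection recovers the truth exactly.
#'
#' @param cfg A [sim_config()].
#' @return List with `trace` (a `FluorescenceTrace`) and `truth` (a
#'   `GroundTruth` with `calcium_windows`).
#' @export
simulate_calcium_trace <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  t <- seq(0, cfg$duration_s - 1 / cfg$calcium_rate_hz,
           by = 1 / cfg$calcium_rate_hz)
  n <- cfg$n_events
  amp <- cfg$event_amplitude_dff; thr <- cfg$calcium_threshold_dff
  dur <- if (n > 0)
    cfg$event_duration_s +
      stats::runif(n, -cfg$event_duration_jitter_s, cfg$event_duration_jitter_s)
  else numeric(0)
  span_max <- max(c(0, dur)) * (1 + log(20) / log(amp / thr))
  onsets <- .place_onsets(n, lo = 5, hi = cfg$duration_s - span_max - 5,
                          min_gap = span_max + 2)
  s <- .calcium_signal(t, onsets, dur, amp, thr)
  drift <- .drift_curve(t, cfg$drift_model, cfg$drift_magnitude,
                        cfg$duration_s)
  noise <- stats::rnorm(length(t), 0, cfg$noise_sd)
  f <- cfg$baseline_f * (1 + drift + s + noise)
  truth <- .ground_truth(
    calcium_windows = .truth_windows(t, s, s > thr, cfg$calcium_rate_hz,
                                     merge_gap_s = 1))
  list(trace = fluorescence_trace(t, f, cfg$calcium_rate_hz), truth = truth)
}

#' Simulate an LFP recording with planted ictal-like bursts
#'
#' Bursts are rectified `lfp_spike_hz` oscillations under a negative
#' flat-top envelope (raised-cosine ramps) whose plateau is
#' `lfp_amplitude_mv` and whose width at the `lfp_threshold_mv` crossing
#' equals the requested duration. Ground-truth windows are the
#' sub-threshold runs of the noiseless envelope (gaps under 50 ms
#' bridged), matching the detector's merged-run definition.
#'
#' @param cfg A [sim_config()].
#' @return List with `trace` (an `LfpTrace`) and `truth`.
#' @export
simulate_lfp_trace <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  t <- seq(0, cfg$duration_s - 1 / cfg$lfp_rate_hz, by = 1 / cfg$lfp_rate_hz)
  n <- cfg$n_events
  amp <- abs(cfg$lfp_amplitude_mv); thr <- abs(cfg$lfp_threshold_mv)
  dur <- if (n > 0)
    cfg$event_duration_s +
      stats::runif(n, -cfg$event_duration_jitter_s, cfg$event_duration_jitter_s)
  else numeric(0)
  span_max <- max(c(0, dur)) + 0.25
  centers <- .place_onsets(n, lo = span_max / 2 + 0.3,
                           hi = cfg$duration_s - span_max / 2 - 0.3,
                           min_gap = span_max + 0.3)
  env <- .lfp_envelope(t, centers, dur, amp, thr)
  v <- env * abs(sin(2 * pi * cfg$lfp_spike_hz * t)) +
    stats::rnorm(length(t), 0, cfg$lfp_noise_sd_mv)
  truth <- .ground_truth(
    lfp_windows = .truth_windows(t, env, env < cfg$lfp_threshold_mv,
                                 cfg$lfp_rate_hz, merge_gap_s = 0.05))
  list(trace = lfp_trace(t, v, cfg$lfp_rate_hz), truth = truth)
}

#' Simulate a simultaneous calcium + LFP recording with coupled events
#'
#' Every planted seizure appears in both modalities: the LFP burst
#' duration `D` is drawn uniformly around `event_duration_s`, the calcium
#' event duration is `coupling_slope * D + coupling_intercept + e` with
#' `e ~ N(0, coupling_jitter_sd)`, and the calcium onset tracks the LFP
#' onset up to `onset_jitter_sd_s`. With `coupling_jitter_sd = 0` the
#' durations are exactly linear in each other.
#'
#' @param cfg A [sim_config()]; `coupling_slope` must be positive.
#' @return List with `calcium` (a `FluorescenceTrace`), `lfp` (an
#'   `LfpTrace`) and `truth` whose `pairs` element records the planted
#'   per-event windows in both modalities.
#' @export
simulate_coupled_recording <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  n <- cfg$n_events
  if (n == 1)
    warning("a single coupled event cannot support a duration correlation",
            call. = FALSE)
  amp <- cfg$event_amplitude_dff; thr <- cfg$calcium_threshold_dff
  lamp <- abs(cfg$lfp_amplitude_mv); lthr <- abs(cfg$lfp_threshold_mv)

  lfp_dur <- if (n > 0)
    cfg$event_duration_s +
      stats::runif(n, -cfg$event_duration_jitter_s, cfg$event_duration_jitter_s)
  else numeric(0)
  cal_dur <- pmax(2 / cfg$calcium_rate_hz,
                  cfg$coupling_slope * lfp_dur + cfg$coupling_intercept +
                    stats::rnorm(n, 0, cfg$coupling_jitter_sd))
  cal_span <- if (n > 0) max(cal_dur) * (1 + log(20) / log(amp / thr)) else 0
  lfp_span <- if (n > 0) max(lfp_dur) + 0.25 else 0
  span <- max(cal_span, lfp_span)
  onsets <- .place_onsets(n, lo = span / 2 + 5,
                          hi = cfg$duration_s - span - 5,
                          min_gap = span + 3)
  cal_onsets <- onsets + stats::rnorm(n, 0, cfg$onset_jitter_sd_s)

  tc <- seq(0, cfg$duration_s - 1 / cfg$calcium_rate_hz,
            by = 1 / cfg$calcium_rate_hz)
  tl <- seq(0, cfg$duration_s - 1 / cfg$lfp_rate_hz, by = 1 / cfg$lfp_rate_hz)

  s <- .calcium_signal(tc, cal_onsets, cal_dur, amp, thr)
  drift <- .drift_curve(tc, cfg$drift_model, cfg$drift_magnitude,
                        cfg$duration_s)
  f <- cfg$baseline_f *
    (1 + drift + s + stats::rnorm(length(tc), 0, cfg$noise_sd))

  # burst center so the envelope window starts at the shared onset
  centers <- onsets + lfp_dur / 2
  env <- .lfp_envelope(tl, centers, lfp_dur, lamp, lthr)
  v <- env * abs(sin(2 * pi * cfg$lfp_spike_hz * tl)) +
    stats::rnorm(length(tl), 0, cfg$lfp_noise_sd_mv)

  pairs <- data.frame(lfp_onset_s = onsets, lfp_duration_s = lfp_dur,
                      calcium_onset_s = cal_onsets,
                      calcium_duration_s = cal_dur)
  truth <- .ground_truth(
    calcium_windows = .truth_windows(tc, s, s > thr, cfg$calcium_rate_hz,
                                     merge_gap_s = 1),
    lfp_windows = .truth_windows(tl, env, env < cfg$lfp_threshold_mv,
                                 cfg$lfp_rate_hz, merge_gap_s = 0.05),
    pairs = pairs)
  list(calcium = fluorescence_trace(tc, f, cfg$calcium_rate_hz),
       lfp = lfp_trace(tl, v, cfg$lfp_rate_hz), truth = truth)
}

#' Coupling jitter that yields a target duration-duration R-squared
#'
#' In the coupled simulator the LFP durations are uniform with half-width
#' `event_duration_jitter_s`, so the signal variance of the calcium
#' duration is `slope^2 * jitter^2 / 3` and the expected coefficient of
#' determination is `R^2 = var_signal / (var_signal + sd_noise^2)`.
#' Inverting gives the Gaussian duration noise SD that produces a desired
#' expected R^2.
#'
#' @param r2 Target expected R-squared in (0, 1].
#' @param slope Coupling slope (default 1).
#' @param duration_jitter_s Uniform half-width of the LFP durations
#'   (default 3).
#' @return `coupling_jitter_sd` in seconds.
#' @export
coupling_jitter_for_r2 <- function(r2, slope = 1, duration_jitter_s = 3) {
  stopifnot(r2 > 0, r2 <= 1)
  sd_signal <- slope * duration_jitter_s / sqrt(3)
  sd_signal * sqrt((1 - r2) / r2)
}
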