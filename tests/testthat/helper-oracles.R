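# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (explicit loops, no shared helpers with the package)
# so they validate the implementation rather than mirror it.

# per-point sliding-window baseline: sort-based median, explicit
# accumulation of the sub-median mean
oracle_drift_correct <- function(x, rate_hz, window_s = 20) {
  n <- length(x)
  h <- max(1, round(window_s * rate_hz / 2))
  out <- numeric(n)
  for (i in 1:n) {
    w <- x[max(1, i - h):min(n, i + h)]
    sw <- sort(w)
    m <- length(sw)
    med <- if (m %% 2 == 1) sw[(m + 1) / 2] else (sw[m / 2] + sw[m / 2 + 1]) / 2
    tot <- 0; cnt <- 0
    for (v in w) if (v < med) { tot <- tot + v; cnt <- cnt + 1 }
    out[i] <- x[i] - (if (cnt > 0) tot / cnt else med)
  }
  out
}

# run-length event oracle: contiguous supra-threshold runs, no merging
oracle_runs <- function(t, x, above) {
  dt <- t[2] - t[1]
  on <- c(); off <- c()
  inside <- FALSE
  for (i in seq_along(x)) {
    if (above[i] && !inside) { on <- c(on, t[i]); inside <- TRUE }
    if (!above[i] && inside) { off <- c(off, t[i]); inside <- FALSE }
  }
  if (inside) off <- c(off, t[length(t)] + dt)
  data.frame(onset_s = on %||% numeric(0), offset_s = off %||% numeric(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# queue-based flood fill, 8-connectivity
oracle_flood_fill8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in 1:nc) for (i in 1:nr) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j))
      lab[i, j] <- cur
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          a <- p[1] + di; b <- p[2] + dj
          if (a >= 1 && a <= nr && b >= 1 && b <= nc &&
              mask[a, b] && lab[a, b] == 0L) {
            lab[a, b] <- cur
            queue[[length(queue) + 1]] <- c(a, b)
          }
        }
      }
    }
  }
  lab
}

# component pixel-count multiset from a labeling (labeling-order invariant)
component_sizes <- function(lab) sort(as.integer(table(lab[lab > 0])))

# study conditions for the coupled-recording analyses: large transients
# (steep decay at the 0.04 crossing), low trace noise and a wide LFP
# duration spread keep duration-measurement error small relative to the
# planted coupling jitter, which the closed-form R^2 oracle requires; the
# drift window is widened to 60 s so that multi-second events stay small
# relative to it.
coupled_cfg <- function(seed, r2 = NULL, n_events = 50, duration_s = 2600,
                        ...) {
  jitter <- if (is.null(r2)) 0 else
    coupling_jitter_for_r2(r2, slope = 1, duration_jitter_s = 4)
  args <- list(seed = seed, duration_s = duration_s, n_events = n_events,
               lfp_rate_hz = 250, event_amplitude_dff = 0.5,
               noise_sd = 0.002, event_duration_s = 6,
               event_duration_jitter_s = 4, coupling_slope = 1,
               coupling_intercept = 2, coupling_jitter_sd = jitter)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

run_coupled_pipeline <- function(cfg) {
  sim <- simulate_coupled_recording(cfg)
  dff <- correct_drift(compute_dff(sim$calcium), window_s = 60)
  cal_ev <- detect_calcium_events(dff)
  lfp_ev <- detect_lfp_events(sim$lfp)
  list(sim = sim, matches = match_events(cal_ev, lfp_ev),
       cal_ev = cal_ev, lfp_ev = lfp_ev)
}
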