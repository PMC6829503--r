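test_that("compute_dff normalizes against the grand mean", {
  t <- seq(0, 1.5, by = 0.5)
  tr <- fluorescence_trace(t, c(100, 100, 100, 140), rate_hz = 2)
  dff <- compute_dff(tr)
  expect_equal(dff$dff, c(-10, -10, -10, 30) / 110, tolerance = 1e-12)
  expect_equal(mean(dff$dff), 0, tolerance = 1e-12)
  expect_false(dff$baseline_corrected)

  const <- compute_dff(fluorescence_trace(t, rep(100, 4), 2))
  expect_equal(const$dff, rep(0, 4))

  set.seed(1)
  f <- 50 + runif(100, 0, 30)
  noisy <- compute_dff(fluorescence_trace(seq_len(100) / 2 - 0.5, f, 2))
  expect_equal(mean(noisy$dff), 0, tolerance = 1e-12)
})

test_that("compute_dff rejects non-positive mean fluorescence", {
  t <- c(0, 0.5, 1)
  expect_error(compute_dff(fluorescence_trace(t, c(-1, 0, 1), 2)),
               "positive")
})

test_that("correct_drift matches the brute-force sliding-window oracle", {
  set.seed(42)
  for (n in c(37, 200, 1000)) {
    x <- 0.02 * sin(seq_len(n) / 15) + rnorm(n, 0, 0.01)
    dff <- dff_trace(seq_len(n) / 2 - 0.5, x, 2)
    got <- correct_drift(dff, window_s = 20)
    expect_lt(max(abs(got$dff - oracle_drift_correct(x, 2, 20))), 1e-12)
    expect_true(got$baseline_corrected)
  }
})

test_that("correct_drift leaves a constant trace at zero and removes a ramp", {
  t <- seq(0, 499.5, by = 0.5)
  zero <- correct_drift(dff_trace(t, rep(0, length(t)), 2))
  expect_equal(zero$dff, rep(0, length(t)))

  t1 <- seq(0, 3599.5, by = 0.5)
  ramp <- correct_drift(dff_trace(t1, 0.02 * t1 / 3600, 2))
  expect_lt(abs(median(ramp$dff)), 0.005)
})

test_that("drift correction preserves event amplitude on a bleaching baseline", {
  cfg <- sim_config(seed = 21, duration_s = 1200, n_events = 6,
                    noise_sd = 0, drift_model = "exponential",
                    drift_magnitude = 0.05)
  sim <- simulate_calcium_trace(cfg)
  dff <- correct_drift(compute_dff(sim$trace))
  ev <- detect_calcium_events(dff)
  expect_equal(nrow(ev), 6)
  # planted peak is the transient amplitude; recovered within 10%
  expect_true(all(abs(ev$peak_value - 0.1) / 0.1 < 0.1))
})

test_that("correct_drift on drift-free noise leaves the spread unchanged", {
  set.seed(7)
  t <- seq(0, 899.5, by = 0.5)
  x <- rnorm(length(t), 0, 0.01)
  out <- correct_drift(dff_trace(t, x, 2))
  expect_lt(abs(sd(out$dff) / sd(x) - 1), 0.2)
})

test_that("correct_drift rejects windows spanning fewer than 3 samples", {
  expect_error(correct_drift(dff_trace(0:9, rnorm(10), 1), window_s = 2),
               "3 samples")
})

test_that("calcium event detection follows the run-length definition", {
  t <- seq(0, 99.5, by = 0.5)
  x <- rep(0, length(t))
  x[t >= 20 & t < 25] <- 0.1 # rectangular 5 s pulse
  dff <- dff_trace(t, x, 2, baseline_corrected = TRUE)
  ev <- detect_calcium_events(dff)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 5, tolerance = 0.5)
  expect_equal(ev$peak_value, 0.1)
  orc <- oracle_runs(t, x, x > 0.04)
  expect_equal(ev$onset_s, orc$onset_s)
  expect_equal(ev$offset_s, orc$offset_s)

  expect_equal(nrow(detect_calcium_events(
    dff_trace(t, rep(0.02, length(t)), 2, baseline_corrected = TRUE))), 0)
})

test_that("runs separated by a short gap merge into one event", {
  t <- seq(0, 49.5, by = 0.5)
  x <- rep(0, length(t))
  x[t >= 10 & t < 14] <- 0.1
  x[t >= 14.5 & t < 18] <- 0.1 # one sub-threshold sample between pulses
  dff <- dff_trace(t, x, 2, baseline_corrected = TRUE)
  ev <- detect_calcium_events(dff, merge_gap_s = 1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_s, 10)
  expect_equal(ev$offset_s, 18)
})

test_that("detection count is monotone non-increasing in threshold", {
  set.seed(5)
  sim <- simulate_calcium_trace(sim_config(seed = 5, duration_s = 1800,
                                           n_events = 20))
  dff <- correct_drift(compute_dff(sim$trace))
  counts <- vapply(c(0.02, 0.04, 0.06, 0.08, 0.12),
                   function(th) nrow(detect_calcium_events(dff, th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection warns on an uncorrected trace", {
  t <- seq(0, 9.5, by = 0.5)
  dff <- dff_trace(t, rep(0, 20), 2)
  expect_warning(detect_calcium_events(dff), "drift")
})

test_that("event_rate converts counts to events per hour", {
  ev0 <- detected_events()
  expect_equal(event_rate(ev0, 3600), 0)
  ev <- detected_events(onset_s = seq(0, 500, 100), offset_s = seq(5, 505, 100),
                        peak_value = rep(0.1, 6), peak_time_s = seq(1, 501, 100),
                        truncated = rep(FALSE, 6))
  expect_equal(event_rate(ev, 1800), 12)
  expect_error(event_rate(ev, 0), "> 0")
})
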