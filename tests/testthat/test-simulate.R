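test_that("simulators are bit-reproducible for a fixed config", {
  cfg <- sim_config(seed = 1, duration_s = 600, n_events = 5)
  a <- simulate_calcium_trace(cfg)
  b <- simulate_calcium_trace(cfg)
  expect_identical(a$trace$f, b$trace$f)
  expect_identical(a$truth$calcium_windows, b$truth$calcium_windows)

  cfgL <- sim_config(seed = 2, duration_s = 30, n_events = 3,
                     event_duration_s = 0.2, event_duration_jitter_s = 0)
  expect_identical(simulate_lfp_trace(cfgL)$trace$v,
                   simulate_lfp_trace(cfgL)$trace$v)

  cfgC <- coupled_cfg(seed = 3, n_events = 5, duration_s = 300)
  expect_identical(simulate_coupled_recording(cfgC)$lfp$v,
                   simulate_coupled_recording(cfgC)$lfp$v)
})

test_that("event-free noiseless configs give constant traces and empty truth", {
  cfg <- sim_config(seed = 1, duration_s = 300, n_events = 0, noise_sd = 0)
  sim <- simulate_calcium_trace(cfg)
  expect_equal(sim$trace$f, rep(100, length(sim$trace$t)))
  expect_equal(nrow(sim$truth$calcium_windows), 0)

  cfgL <- sim_config(seed = 1, duration_s = 10, n_events = 0,
                     lfp_noise_sd_mv = 0)
  simL <- simulate_lfp_trace(cfgL)
  expect_equal(simL$trace$v, rep(0, length(simL$trace$t)))
  expect_equal(nrow(simL$truth$lfp_windows), 0)
})

test_that("overcrowded recordings are rejected with an explicit message", {
  expect_error(
    simulate_calcium_trace(sim_config(seed = 1, duration_s = 120,
                                      n_events = 50)),
    "cannot fit")
})

test_that("planted truth windows have the requested durations", {
  cfgL <- sim_config(seed = 9, duration_s = 30, n_events = 1,
                     event_duration_s = 0.2, event_duration_jitter_s = 0,
                     lfp_noise_sd_mv = 0)
  simL <- simulate_lfp_trace(cfgL)
  w <- simL$truth$lfp_windows
  expect_equal(nrow(w), 1)
  expect_equal(w$offset_s - w$onset_s, 0.2, tolerance = 2 / 10000)

  cfg <- sim_config(seed = 10, duration_s = 600, n_events = 4,
                    event_duration_s = 6, event_duration_jitter_s = 0,
                    noise_sd = 0)
  sim <- simulate_calcium_trace(cfg)
  w2 <- sim$truth$calcium_windows
  expect_equal(nrow(w2), 4)
  expect_equal(w2$offset_s - w2$onset_s, rep(6, 4), tolerance = 1)
})

test_that("noiseless drift-free recovery is perfect in both modalities", {
  cfg <- sim_config(seed = 13, duration_s = 1200, n_events = 10,
                    noise_sd = 0)
  sim <- simulate_calcium_trace(cfg)
  ev <- detect_calcium_events(correct_drift(compute_dff(sim$trace)))
  perf <- detection_performance(ev, sim$truth$calcium_windows)
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$precision, 1)

  cfgL <- sim_config(seed = 14, duration_s = 30, n_events = 3,
                     event_duration_s = 0.2, event_duration_jitter_s = 0,
                     lfp_noise_sd_mv = 0)
  simL <- simulate_lfp_trace(cfgL)
  evL <- detect_lfp_events(simL$trace)
  perfL <- detection_performance(evL, simL$truth$lfp_windows)
  expect_equal(perfL$sensitivity, 1)
  expect_equal(perfL$precision, 1)
})

test_that("coupled durations are exactly linear in the noiseless limit", {
  cfg <- coupled_cfg(seed = 15, n_events = 8, duration_s = 400,
                     noise_sd = 0, lfp_noise_sd_mv = 0, onset_jitter_sd_s = 0)
  sim <- simulate_coupled_recording(cfg)
  p <- sim$truth$pairs
  expect_equal(p$calcium_duration_s, p$lfp_duration_s + 2, tolerance = 1e-12)
  expect_equal(p$calcium_onset_s, p$lfp_onset_s, tolerance = 1e-12)
})

test_that("a single coupled event is flagged as correlation-degenerate", {
  expect_warning(
    simulate_coupled_recording(coupled_cfg(seed = 16, n_events = 1,
                                           duration_s = 200)),
    "single")
})

test_that("puncta simulator plants exact area bands and rejects tiny fields", {
  sim <- simulate_puncta_image(n_in_range = 0, n_below = 0, n_above = 0,
                               seed = 1)
  expect_equal(max(sim$image$pixels), 0)
  expect_equal(nrow(sim$truth$puncta), 0)

  sim2 <- simulate_puncta_image(n_in_range = 4, n_below = 3, n_above = 1,
                                seed = 2)
  tr <- sim2$truth$puncta
  expect_equal(sum(tr$band == "below"), 3)
  # sub-threshold clusters are at most 4 px: below the 0.018 um^2 bound
  expect_true(all(tr$area_um2[tr$band == "below"] < 0.018))
  expect_true(all(tr$area_um2[tr$band == "in_range"] >= 0.018 &
                    tr$area_um2[tr$band == "in_range"] <= 3.14))
  expect_true(all(tr$area_um2[tr$band == "above"] > 3.14))

  expect_error(simulate_puncta_image(n_in_range = 0, n_above = 40,
                                     seed = 3, size_px = 128),
               "field too small")
})

test_that("cell-volume simulator respects separation and colocalization requests", {
  sim <- simulate_cell_volume(3, 4, 2, apoptotic_on = "excitatory", seed = 5)
  tr <- sim$truth$cells
  neurons <- tr[tr$class != "apoptotic", ]
  d <- as.matrix(dist(neurons[, c("x_um", "y_um", "z_um")]))
  expect_true(all(d[upper.tri(d)] >= 7))
  apo <- tr[tr$class == "apoptotic", c("x_um", "y_um", "z_um")]
  exc <- tr[tr$class == "excitatory", c("x_um", "y_um", "z_um")]
  for (i in seq_len(nrow(apo)))
    expect_true(any(sqrt(colSums((t(exc) - unlist(apo[i, ]))^2)) < 1e-9))

  expect_error(simulate_cell_volume(200, 200, 0, size_um = c(30, 30, 20),
                                    seed = 6),
               "crowded")
})
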