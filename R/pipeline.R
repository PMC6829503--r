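#' Default analysis parameters
#'
#' The constants every entry point defaults to: the 0.04 delta-F/F0
#' calcium event threshold, the 20 s drift-correction window, the
#' -0.3 mV / 0.1 s LFP event rule, the 0.1-1000 Hz acquisition band, the
#' 0.018-3.14 um^2 punctum area band at 0.063 um pixels, the 7 um cell
#' diameter, and alpha = 0.05 for the gated statistics.
#'
#' @return Named list of defaults.
#' @export
epiquant_defaults <- function() {
  list(calcium_threshold_dff = 0.04,
       drift_window_s = 20,
       lfp_amp_mv = -0.3,
       lfp_min_dur_s = 0.1,
       lfp_hp_hz = 0.1,
       lfp_lp_hz = 1000,
       min_area_um2 = 0.018,
       max_area_um2 = 3.14,
       pixel_size_um = 0.063,
       cell_diameter_um = 7,
       coloc_max_dist_um = 3.5,
       match_tolerance_s = 2.0,
       alpha = 0.05)
}

# canonical JSON serialization used for both results and config hashes:
# fixed precision so byte-identical reruns are guaranteed
.to_canonical_json <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(10), dataframe = "columns",
                   na = "null", pretty = TRUE)
}

.config_hash <- function(config) {
  config <- config[setdiff(names(config), c("out_dir", "verbose"))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(.to_canonical_json(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}

.pkg_version <- function() {
  as.character(utils::packageVersion("epiquant"))
}

#' Run a configured analysis task end-to-end
#'
#' Executes one named task with the package's functions and writes a
#' reproducible result bundle: a JSON summary (serialized at fixed
#' precision, so identical config + inputs give byte-identical output),
#' CSV tables where applicable, and the config hash and package version
#' stamped into every summary.
#'
#' Tasks: `"simulate_calcium"`, `"simulate_lfp"`, `"simulate_coupled"`
#' (config field `sim` holds [sim_config()] arguments),
#' `"detect_calcium"` / `"detect_lfp"` (field `input`: trace CSV),
#' `"couple"` (fields `calcium_input`, `lfp_input`), `"compare"` (fields
#' `group_a`, `group_b`: single-column CSVs), and `"demo"` (simulate a
#' coupled recording, detect in both modalities, match, correlate, and
#' gate-compare the matched durations).
#'
#' @param config Named list (or path to a YAML file) with at least
#'   `task`, optional `seed` (default 1) and `out_dir` (default a temp
#'   directory).
#' @return The summary list, invisibly; side effect: files under
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (is.null(config$task))
    stop("config$task is required (see ?run_pipeline)", call. = FALSE)
  task <- config$task
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- if (is.null(config$out_dir)) tempfile("epiquant_")
             else config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  def <- epiquant_defaults()
  p <- utils::modifyList(def, config[intersect(names(config), names(def))])

  summary <- switch(
    task,
    simulate_calcium = {
      cfg <- do.call(sim_config, c(list(seed = seed),
                                   config$sim %||% list()))
      sim <- simulate_calcium_trace(cfg)
      write_trace_csv(sim$trace, file.path(out_dir, "calcium_trace.csv"))
      write_ground_truth_json(sim$truth, file.path(out_dir, "truth.json"))
      list(n_planted = nrow(sim$truth$calcium_windows))
    },
    simulate_lfp = {
      cfg <- do.call(sim_config, c(list(seed = seed),
                                   config$sim %||% list()))
      sim <- simulate_lfp_trace(cfg)
      write_trace_csv(sim$trace, file.path(out_dir, "lfp_trace.csv"))
      write_ground_truth_json(sim$truth, file.path(out_dir, "truth.json"))
      list(n_planted = nrow(sim$truth$lfp_windows))
    },
    simulate_coupled = {
      cfg <- do.call(sim_config, c(list(seed = seed),
                                   config$sim %||% list()))
      sim <- simulate_coupled_recording(cfg)
      write_trace_csv(sim$calcium, file.path(out_dir, "calcium_trace.csv"))
      write_trace_csv(sim$lfp, file.path(out_dir, "lfp_trace.csv"))
      write_ground_truth_json(sim$truth, file.path(out_dir, "truth.json"))
      list(n_planted = nrow(sim$truth$pairs))
    },
    detect_calcium = {
      trace <- read_trace_csv(.require_input(config$input), "fluorescence")
      dff <- correct_drift(compute_dff(trace), p$drift_window_s)
      ev <- detect_calcium_events(dff, p$calcium_threshold_dff)
      utils::write.csv(ev, file.path(out_dir, "calcium_events.csv"),
                       row.names = FALSE)
      dur <- trace$t[length(trace$t)] - trace$t[1] + 1 / trace$rate_hz
      list(n_events = nrow(ev), events_per_hour = event_rate(ev, dur))
    },
    detect_lfp = {
      trace <- read_trace_csv(.require_input(config$input), "lfp")
      if (isTRUE(config$bandpass))
        trace <- bandpass_lfp(trace, p$lfp_hp_hz, p$lfp_lp_hz)
      ev <- detect_lfp_events(trace, p$lfp_amp_mv, p$lfp_min_dur_s)
      utils::write.csv(ev, file.path(out_dir, "lfp_events.csv"),
                       row.names = FALSE)
      dur <- trace$t[length(trace$t)] - trace$t[1] + 1 / trace$rate_hz
      list(n_events = nrow(ev), events_per_hour = event_rate(ev, dur))
    },
    couple = {
      cal <- read_trace_csv(.require_input(config$calcium_input),
                            "fluorescence")
      lfp <- read_trace_csv(.require_input(config$lfp_input), "lfp")
      dff <- correct_drift(compute_dff(cal), p$drift_window_s)
      cal_ev <- detect_calcium_events(dff, p$calcium_threshold_dff)
      lfp_ev <- detect_lfp_events(lfp, p$lfp_amp_mv, p$lfp_min_dur_s)
      mt <- match_events(cal_ev, lfp_ev, p$match_tolerance_s)
      utils::write.csv(mt$matches, file.path(out_dir, "matches.csv"),
                       row.names = FALSE)
      corr <- duration_correlation(mt)
      list(n_calcium = nrow(cal_ev), n_lfp = nrow(lfp_ev),
           n_pairs = corr$n_pairs, slope = corr$slope,
           intercept = corr$intercept, r_squared = corr$r_squared)
    },
    compare = {
      a <- utils::read.csv(.require_input(config$group_a))[[1]]
      b <- utils::read.csv(.require_input(config$group_b))[[1]]
      cmp <- compare_groups(a, b, p$alpha)
      unclass(cmp)
    },
    puncta = {
      img <- read_puncta_tiff(.require_input(config$input),
                              p$pixel_size_um)
      seg <- if (is.null(config$threshold))
        segment_puncta(img) else
        segment_puncta(img, "fixed", config$threshold)
      pts <- filter_puncta(seg, min_area_um2 = p$min_area_um2,
                           max_area_um2 = p$max_area_um2)
      utils::write.csv(pts, file.path(out_dir, "puncta.csv"),
                       row.names = FALSE)
      roi <- config$roi_area_um2 %||%
        (prod(dim(img$pixels)) * img$pixel_size_um^2)
      dens <- puncta_density(pts, roi)
      list(n_components = nrow(seg$components), n_puncta = dens$n_puncta,
           roi_area_um2 = dens$roi_area_um2,
           density_per_um2 = dens$density_per_um2)
    },
    cells = {
      vol <- read_volume_tiff(.require_input(config$input),
                              n_channels = config$n_channels %||% 1,
                              voxel_size_um = unlist(config$voxel_size_um
                                                     %||% c(0.8, 0.8, 2.0)),
                              channels = config$channels)
      det <- detect_cells(vol, channel = config$channel %||% 1,
                          diameter_um = p$cell_diameter_um)
      det <- classify_cells(det, vol)
      utils::write.csv(det, file.path(out_dir, "cells.csv"),
                       row.names = FALSE)
      as.list(c(n_cells = nrow(det),
                table(factor(det$class, levels = vol$channels))))
    },
    movement = {
      planes <- tiff::readTIFF(.require_input(config$input), all = TRUE)
      if (!is.list(planes)) planes <- list(planes)
      mv <- quantify_movement(planes,
                              config$intensity_change_threshold %||% 0.1)
      list(n_frames = length(planes), acting_units = mv$total)
    },
    demo = {
      cfg <- do.call(sim_config, c(list(seed = seed),
                                   config$sim %||% list()))
      sim <- simulate_coupled_recording(cfg)
      dff <- correct_drift(compute_dff(sim$calcium), p$drift_window_s)
      cal_ev <- detect_calcium_events(dff, p$calcium_threshold_dff)
      lfp_ev <- detect_lfp_events(sim$lfp, p$lfp_amp_mv, p$lfp_min_dur_s)
      mt <- match_events(cal_ev, lfp_ev, p$match_tolerance_s)
      utils::write.csv(mt$matches, file.path(out_dir, "matches.csv"),
                       row.names = FALSE)
      corr <- duration_correlation(mt)
      cmp <- compare_groups(mt$matches$calcium_duration_s,
                            mt$matches$lfp_duration_s, p$alpha)
      list(n_planted = nrow(sim$truth$pairs),
           n_calcium = nrow(cal_ev), n_lfp = nrow(lfp_ev),
           n_pairs = corr$n_pairs, slope = corr$slope,
           intercept = corr$intercept, r_squared = corr$r_squared,
           duration_test = cmp$test_used, duration_p = cmp$p_value)
    },
    stop("unknown task: ", task, call. = FALSE))

  summary <- c(list(task = task, seed = seed,
                    config_hash = .config_hash(config),
                    package_version = .pkg_version()),
               summary)
  writeLines(.to_canonical_json(summary),
             file.path(out_dir, "summary.json"))
  invisible(summary)
}

.require_input <- function(path) {
  if (is.null(path) || !file.exists(path))
    stop("input file not found: ",
         if (is.null(path)) "(missing)" else path, call. = FALSE)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
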