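# End-to-end orchestration: simulate -> train -> track -> thickness -> spm
# on synthetic phantom data, with a single declarative configuration, one
# root seed, and a config hash stamped into the run manifest.

#' Declarative pipeline configuration
#'
#' All module defaults in one validated document.  Unknown keys are
#' rejected.  Defaults follow the tracked imaging protocol: 19 landmarks
#' per boundary at 32 px (~2.75 mm) spacing, 98.5% PDM variance retention,
#' +/-3 SD shape constraint, 4 resolution levels for tracking and 5 for
#' first-frame initialisation, 20 thickness sites + mean, 4 strides
#' normalised to 200 nodes, alpha 0.05.
#'
#' @param ... overrides of the defaults listed in the function definition.
#' @return a validated `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    # phantom imaging
    image_height = 300L, image_width = 608L, pixel_pitch = 2.75 / 32,
    frame_rate = 25, band_brightness = 0.8, band_halfwidth = 3,
    background = 0.15, speckle_var = 0.005, gaussian_sd = 0.02,
    n_landmarks = 19L, landmark_spacing = 32L,
    # training
    train_frames = 60L, label_stride = 5L, variance_target = 0.985,
    # ASM search
    search_range = 5L, max_iterations = 10L, convergence_fraction = 0.9,
    n_levels_track = 4L, n_levels_init = 5L, sd_limit = 3, k = 2L,
    # gait / GRF
    stride_period = 1.0, duty_factor = 0.35, n_strides = 4L,
    grf_rate = 2000, peak_force = 1600, grf_noise_sd = 0,
    force_threshold = 20, debounce = 0.05,
    # thickness + SPM
    n_sites = 20L, n_nodes = 200L, alpha = 0.05,
    muscles = c("LG", "SO"), standing_frames = 10L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, over)
  if (!is_count(cfg$n_strides)) stopf("n_strides must be >= 1")
  if (!is_count(cfg$n_nodes, 2L)) stopf("n_nodes must be >= 2")
  if (cfg$variance_target <= 0 || cfg$variance_target > 1) {
    stopf("variance_target must lie in (0, 1]")
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stopf("alpha must lie in (0, 1)")
  if (cfg$n_levels_init < cfg$n_levels_track) {
    stopf("n_levels_init must be >= n_levels_track")
  }
  structure(cfg, class = "run_config")
}

#' MD5 hash of a configuration (provenance stamp)
#' @param config a [run_config()].
#' @return 32-character hash string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

# Phantom boundary set used by the pipeline; `motion` scales the temporal
# amplitudes, `period` is the motion period in frames, `phase` shifts all
# three boundaries (distinguishes the two training trials).
pipeline_boundaries <- function(cfg, motion = 1, period = 25, phase = 0) {
  list(
    boundary_curve(0.2 * cfg$image_height, amp_x = 4, wavelength_x = 480,
                   motion_amp = 3 * motion, motion_period = period,
                   motion_phase = phase),
    boundary_curve(0.5 * cfg$image_height, amp_x = 5, wavelength_x = 400,
                   phase_x = 1.2, motion_amp = 5 * motion,
                   motion_period = period, motion_phase = 0.8 + phase),
    boundary_curve(0.82 * cfg$image_height, amp_x = 3, wavelength_x = 520,
                   phase_x = 2.1, motion_amp = 4 * motion,
                   motion_period = period, motion_phase = 1.9 + phase))
}

pipeline_phantom <- function(cfg, n_frames, boundaries, seed) {
  phantom_config(
    image_height = cfg$image_height, image_width = cfg$image_width,
    n_frames = n_frames, pixel_pitch = cfg$pixel_pitch,
    boundaries = boundaries, band_brightness = cfg$band_brightness,
    band_halfwidth = cfg$band_halfwidth, background = cfg$background,
    noise = list(speckle_var = cfg$speckle_var,
                 gaussian_sd = cfg$gaussian_sd),
    n_landmarks = cfg$n_landmarks,
    landmark_spacing = cfg$landmark_spacing, seed = seed)
}

mean_shape_of <- function(shapes) {
  apo_shape(Reduce(`+`, lapply(shapes, unclass)) / length(shapes),
            n_boundaries = n_boundaries(shapes[[1L]]))
}

#' Run the full synthetic pipeline
#'
#' Simulates two hand-labelled training trials and one analysis trial with
#' a matched GRF trace, trains the PDM and profile models from subsampled
#' truth labels (emulating every n-th frame being hand labelled), tracks
#' the analysis and quiet-standing sequences, extracts stride-normalised
#' baseline-subtracted thickness for each muscle, and runs a 1D SPM
#' region-effect ANOVA (strides as the repeated blocks) on the result.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory; when given, fits, thickness
#'   table, GRF, SPM results, model archive and a manifest with the config
#'   hash are written there.
#' @return list with `fits`, `thickness` (per muscle), `stride_thickness`,
#'   `long` (data.table), `spm` (per muscle), `standing`, `grf`, `pdm`,
#'   `models`, `config`, `config_md5`, `flags`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  hash <- config_hash(cfg)
  seeds <- cfg$seed + c(train1 = 101L, train2 = 202L, trial = 303L,
                        grf = 404L, standing = 505L)
  message(sprintf("[apotrack] run %s (seed %d)", hash, cfg$seed))

  # --- simulate ---------------------------------------------------------
  period_frames <- cfg$stride_period * cfg$frame_rate
  n_frames <- as.integer(ceiling(
    (cfg$n_strides + 1) * cfg$stride_period * cfg$frame_rate)) + 1L
  train_a <- generate_phantom_sequence(pipeline_phantom(
    cfg, cfg$train_frames, pipeline_boundaries(cfg, motion = 1),
    seeds[["train1"]]))
  train_b <- generate_phantom_sequence(pipeline_phantom(
    cfg, cfg$train_frames,
    pipeline_boundaries(cfg, motion = 1.6, phase = pi / 2),
    seeds[["train2"]]))
  trial <- generate_phantom_sequence(pipeline_phantom(
    cfg, n_frames, pipeline_boundaries(cfg, motion = 1.3,
                                       period = period_frames),
    seeds[["trial"]]))
  standing <- generate_phantom_sequence(pipeline_phantom(
    cfg, cfg$standing_frames, pipeline_boundaries(cfg, motion = 0),
    seeds[["standing"]]))
  grf <- generate_grf(cfg$stride_period, cfg$duty_factor,
                      cfg$n_strides + 1L, cfg$grf_rate, cfg$peak_force,
                      cfg$grf_noise_sd, seeds[["grf"]])
  message(sprintf("[apotrack] simulated %d training + %d trial frames",
                  2L * cfg$train_frames, n_frames))

  # --- train ------------------------------------------------------------
  lab_idx <- seq(1L, cfg$train_frames, by = cfg$label_stride)
  labels_a <- train_a$truth_shapes[lab_idx]
  labels_b <- train_b$truth_shapes[lab_idx]
  pdm <- build_pdm(c(labels_a, labels_b), cfg$variance_target)
  scfg <- search_config(cfg$search_range, cfg$max_iterations,
                        cfg$convergence_fraction, cfg$n_levels_track,
                        cfg$n_levels_init, cfg$sd_limit, cfg$k)
  pyramids <- lapply(c(train_a$frames[lab_idx], train_b$frames[lab_idx]),
                     build_pyramid, n_levels = cfg$n_levels_init)
  models <- train_profile_models(pyramids, c(labels_a, labels_b),
                                 k = cfg$k, n_levels = cfg$n_levels_init)
  trial_means <- list(mean_shape_of(labels_a), mean_shape_of(labels_b))
  message(sprintf("[apotrack] PDM: %d modes (%.2f%% variance), %d labels",
                  ncol(pdm$modes), 100 * pdm$variance_retained,
                  2L * length(lab_idx)))

  # --- track ------------------------------------------------------------
  fits <- track_sequence(trial$frames, pdm, models, scfg, trial_means)
  stand_fits <- track_sequence(standing$frames, pdm, models, scfg,
                               trial_means)
  n_unconv <- sum(!vapply(fits, `[[`, logical(1), "converged"))
  message(sprintf("[apotrack] tracked %d frames (%d unconverged)",
                  length(fits), n_unconv))

  # --- thickness --------------------------------------------------------
  frame_times <- (seq_len(n_frames) - 1L) / cfg$frame_rate
  thick <- list()
  stride_th <- list()
  spm <- list()
  long <- list()
  flags <- list(unconverged_frames = n_unconv, crossings = 0L)
  for (m in cfg$muscles) {
    ts <- compute_thickness_series(fits, m, n_sites = cfg$n_sites,
                                   pixel_pitch = cfg$pixel_pitch,
                                   frame_times = frame_times)
    stand_ts <- compute_thickness_series(stand_fits, m,
                                         n_sites = cfg$n_sites,
                                         pixel_pitch = cfg$pixel_pitch)
    flags$crossings <- flags$crossings + sum(ts$crossing)
    st <- stride_normalized_thickness(ts, grf, standing_baseline(stand_ts),
                                      cfg$n_strides, cfg$n_nodes,
                                      cfg$force_threshold, cfg$debounce)
    # SPM demo design: region = site (1..n_sites + mean), strides as the
    # repeated blocks
    n_series <- dim(st$change)[3L]
    Y <- do.call(rbind, lapply(seq_len(n_series), function(sI) {
      st$change[, , sI]
    }))
    design <- field_design(Y,
                           subject = rep(seq_len(cfg$n_strides), n_series),
                           region = rep(seq_len(n_series),
                                        each = cfg$n_strides))
    spm[[m]] <- spm_inference(pointwise_rm_anova(design, "region"),
                              alpha = cfg$alpha)
    thick[[m]] <- ts
    stride_th[[m]] <- st
    long[[m]] <- thickness_long(st, trial = "trial1")
  }
  long <- data.table::rbindlist(long)

  # --- write ------------------------------------------------------------
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fits_json(fits, file.path(out_dir, "fits.json"))
    write_thickness_csv(long, file.path(out_dir, "thickness.csv"))
    write_grf_csv(grf, file.path(out_dir, "grf.csv"))
    write_model_archive(pdm, models, file.path(out_dir, "model.json"))
    for (m in names(spm)) {
      write_spm_json(spm[[m]], file.path(out_dir,
                                         sprintf("spm_%s.json", m)))
    }
    files <- c("fits.json", "thickness.csv", "grf.csv", "model.json",
               sprintf("spm_%s.json", names(spm)))
    manifest <- list(schema = "apotrack-run/1", config_md5 = hash,
                     config = unclass(cfg),
                     files = as.list(stats::setNames(
                       unname(tools::md5sum(file.path(out_dir, files))),
                       files)),
                     flags = flags)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  invisible(list(fits = fits, thickness = thick,
                 stride_thickness = stride_th, long = long, spm = spm,
                 standing = stand_fits, grf = grf, pdm = pdm,
                 models = models, truth = trial$truth_shapes,
                 config = cfg, config_md5 = hash, flags = flags))
}
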