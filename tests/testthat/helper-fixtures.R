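# Shared fixtures, built once per test run.  The "small" phantom (120 x 320
# px, 19 landmarks at 16 px spacing) keeps unit tests fast; acceptance tests
# build the full-size stated configuration themselves.

.fixtures <- new.env(parent = emptyenv())

small_boundaries <- function(motion = 1, phase = 0) {
  list(
    boundary_curve(25, amp_x = 2, wavelength_x = 240,
                   motion_amp = 1.5 * motion, motion_period = 12,
                   motion_phase = phase),
    boundary_curve(60, amp_x = 3, wavelength_x = 200, phase_x = 1.2,
                   motion_amp = 2.5 * motion, motion_period = 12,
                   motion_phase = 0.8 + phase),
    boundary_curve(95, amp_x = 2, wavelength_x = 260, phase_x = 2.1,
                   motion_amp = 2 * motion, motion_period = 12,
                   motion_phase = 1.9 + phase))
}

small_phantom_config <- function(n_frames = 12L, motion = 1, phase = 0,
                                 noise = list(speckle_var = 0,
                                              gaussian_sd = 0),
                                 seed = 1L) {
  phantom_config(image_height = 120L, image_width = 320L,
                 n_frames = n_frames,
                 boundaries = small_boundaries(motion, phase),
                 noise = noise, n_landmarks = 19L, landmark_spacing = 16L,
                 seed = seed)
}

# Trained PDM + profile models + trial mean shapes on the small phantom.
small_setup <- function(key = "noiseless",
                        noise = list(speckle_var = 0, gaussian_sd = 0)) {
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  cfg_a <- small_phantom_config(24L, motion = 1, noise = noise, seed = 11L)
  cfg_b <- small_phantom_config(24L, motion = 1.6, phase = pi / 2,
                                noise = noise, seed = 12L)
  seq_a <- generate_phantom_sequence(cfg_a)
  seq_b <- generate_phantom_sequence(cfg_b)
  idx <- seq(1L, 24L, by = 3L)
  labels <- c(seq_a$truth_shapes[idx], seq_b$truth_shapes[idx])
  pdm <- build_pdm(labels)
  pyramids <- lapply(c(seq_a$frames[idx], seq_b$frames[idx]),
                     build_pyramid, n_levels = 5L)
  models <- train_profile_models(pyramids, labels, n_levels = 5L)
  mean_of <- function(shapes) {
    apo_shape(Reduce(`+`, lapply(shapes, unclass)) / length(shapes))
  }
  out <- list(pdm = pdm, models = models,
              means = list(mean_of(seq_a$truth_shapes[idx]),
                           mean_of(seq_b$truth_shapes[idx])),
              labels = labels, seq_a = seq_a, seq_b = seq_b, idx = idx,
              noise = noise)
  .fixtures[[key]] <- out
  out
}

# Random valid 3-boundary shape with strictly increasing x per boundary.
random_shape <- function(n_per = 19L, jitter = 2) {
  x <- seq(10, 10 + 16 * (n_per - 1L), by = 16)
  m <- do.call(rbind, lapply(c(30, 60, 90), function(d) {
    cbind(x + stats::runif(n_per, -4, 4) * 0,
          d + stats::rnorm(n_per, sd = jitter))
  }))
  apo_shape(m)
}

# Full-size training setup matching the tracked phantom's stated world
# (300 x 608 px, 19 landmarks at 32 px); used by the acceptance suite.
fullsize_setup <- function(key, noise) {
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  mk <- function(motion, phase, seed) {
    phantom_config(n_frames = 30L,
                   boundaries = list(
                     boundary_curve(60, amp_x = 4, wavelength_x = 480,
                                    motion_amp = 3 * motion,
                                    motion_period = 25,
                                    motion_phase = phase),
                     boundary_curve(150, amp_x = 5, wavelength_x = 400,
                                    phase_x = 1.2, motion_amp = 5 * motion,
                                    motion_period = 25,
                                    motion_phase = 0.8 + phase),
                     boundary_curve(245, amp_x = 3, wavelength_x = 520,
                                    phase_x = 2.1, motion_amp = 4 * motion,
                                    motion_period = 25,
                                    motion_phase = 1.9 + phase)),
                   noise = noise, seed = seed)
  }
  seq_a <- generate_phantom_sequence(mk(1, 0, 21L))
  seq_b <- generate_phantom_sequence(mk(1.6, pi / 2, 22L))
  idx <- seq(1L, 30L, by = 3L)
  labels <- c(seq_a$truth_shapes[idx], seq_b$truth_shapes[idx])
  pdm <- build_pdm(labels)
  pyramids <- lapply(c(seq_a$frames[idx], seq_b$frames[idx]),
                     build_pyramid, n_levels = 5L)
  models <- train_profile_models(pyramids, labels, n_levels = 5L)
  mean_of <- function(shapes) {
    apo_shape(Reduce(`+`, lapply(shapes, unclass)) / length(shapes))
  }
  out <- list(pdm = pdm, models = models,
              means = list(mean_of(seq_a$truth_shapes[idx]),
                           mean_of(seq_b$truth_shapes[idx])))
  .fixtures[[key]] <- out
  out
}

# RMS landmark error of a fit against the truth shape, px.
fit_rms <- function(fit, truth) {
  sqrt(mean((unclass(fit$shape) - unclass(truth))^2))
}

# Reduced pipeline configuration for end-to-end and determinism tests
# (scaled down from the full stated world to keep runtimes in budget).
tiny_config <- function(seed = 1L) {
  run_config(seed = seed, image_height = 160L, image_width = 320L,
             landmark_spacing = 16L, frame_rate = 10, stride_period = 1.0,
             n_strides = 2L, train_frames = 15L, label_stride = 3L,
             standing_frames = 4L, n_nodes = 50L, muscles = "SO",
             grf_rate = 500)
}
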