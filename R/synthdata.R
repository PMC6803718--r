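# Synthetic phantom data: ultrasound-like image sequences with known
# aponeurosis geometry, stride-periodic vertical ground-reaction-force
# traces, and smooth Gaussian 1D random fields.  Everything downstream
# (shape model, ASM search, thickness pipeline, SPM) is validated against
# the analytic truth these generators carry.

#' Parametric aponeurosis boundary curve
#'
#' Depth (row coordinate, pixels) as a function of lateral position `x`
#' (pixels, 0-based) and frame index `t` (0-based):
#' \deqn{d(x,t) = depth + slope\,x + A_x \sin(2\pi x/\lambda_x + \phi_x)
#'              + A_t \sin(2\pi t/T_t + \phi_t)}
#' Spatial undulation models gentle aponeurosis curvature; the temporal term
#' models periodic whole-boundary motion over the stride.
#'
#' @param depth baseline depth, pixels.
#' @param slope linear depth change per pixel of x.
#' @param amp_x,wavelength_x,phase_x spatial sinusoid: amplitude (px),
#'   wavelength (px), phase (rad).
#' @param motion_amp,motion_period,motion_phase temporal sinusoid: amplitude
#'   (px), period (frames), phase (rad).
#' @return a `boundary_curve` list usable in [phantom_config()].
#' @export
boundary_curve <- function(depth, slope = 0, amp_x = 0, wavelength_x = 256,
                           phase_x = 0, motion_amp = 0, motion_period = 25,
                           motion_phase = 0) {
  stopifnot(is_number(depth), is_number(slope), is_number(amp_x),
            is_number(wavelength_x), wavelength_x > 0,
            is_number(motion_amp), is_number(motion_period),
            motion_period > 0)
  structure(list(depth = depth, slope = slope, amp_x = amp_x,
                 wavelength_x = wavelength_x, phase_x = phase_x,
                 motion_amp = motion_amp, motion_period = motion_period,
                 motion_phase = motion_phase),
            class = "boundary_curve")
}

# Evaluate a boundary curve at lateral positions x for frame t (both 0-based).
boundary_depth <- function(b, x, t) {
  b$depth + b$slope * x +
    b$amp_x * sin(2 * pi * x / b$wavelength_x + b$phase_x) +
    b$motion_amp * sin(2 * pi * t / b$motion_period + b$motion_phase)
}

#' Noise preset giving band signal-to-noise ratio of about 10
#'
#' Multiplicative speckle variance 0.005 (sd ~ 0.07 of local intensity) plus
#' additive Gaussian sd 0.02; against the default band brightness of 0.8 the
#' ridge-to-noise ratio is ~10.
#' @export
noise_snr10 <- function() list(speckle_var = 0.005, gaussian_sd = 0.02)

#' Configuration of a synthetic ultrasound phantom
#'
#' Describes a grayscale image sequence containing three bright, gently
#' curved, possibly moving aponeurosis bands (superficial, middle, deep, in
#' order of increasing depth) over a speckled background.  Truth landmarks
#' are placed at `n_landmarks` x-positions separated by `landmark_spacing`
#' pixels, centred laterally.
#'
#' @param image_height,image_width image dimensions, pixels.
#' @param n_frames number of frames in the sequence.
#' @param pixel_pitch mm per pixel (default 2.75/32, i.e. 32 px ~ 2.75 mm).
#' @param boundaries list of exactly three [boundary_curve()] objects ordered
#'   superficial, middle, deep.
#' @param band_brightness peak added intensity of each band (0-1).
#' @param band_halfwidth Gaussian sigma of the rendered ridge profile, px.
#' @param background background intensity level (0-1).
#' @param noise list with `speckle_var` (variance of the unit-mean
#'   multiplicative gamma speckle) and `gaussian_sd` (additive noise sd).
#'   Both 0 gives a noiseless phantom.
#' @param n_landmarks truth landmarks per boundary (default 19).
#' @param landmark_spacing lateral spacing between landmarks, px (default 32).
#' @param seed integer seed controlling all noise draws.
#' @return a validated `phantom_config` object.
#' @export
phantom_config <- function(image_height = 300L, image_width = 608L,
                           n_frames = 50L, pixel_pitch = 2.75 / 32,
                           boundaries = list(
                             boundary_curve(60, amp_x = 4, wavelength_x = 480,
                                            motion_amp = 3, motion_period = 25),
                             boundary_curve(150, amp_x = 5, wavelength_x = 400,
                                            phase_x = 1.2, motion_amp = 5,
                                            motion_period = 25,
                                            motion_phase = 0.8),
                             boundary_curve(245, amp_x = 3, wavelength_x = 520,
                                            phase_x = 2.1, motion_amp = 4,
                                            motion_period = 25,
                                            motion_phase = 1.9)),
                           band_brightness = 0.8, band_halfwidth = 3,
                           background = 0.15,
                           noise = list(speckle_var = 0, gaussian_sd = 0),
                           n_landmarks = 19L, landmark_spacing = 32L,
                           seed = 1L) {
  if (!is_count(image_height) || !is_count(image_width)) {
    stopf("image dimensions must be positive integers")
  }
  if (!is_count(n_frames)) stopf("n_frames must be a positive integer")
  if (!is_number(pixel_pitch) || pixel_pitch <= 0) {
    stopf("pixel_pitch must be > 0")
  }
  if (length(boundaries) != 3L ||
      !all(vapply(boundaries, inherits, logical(1), "boundary_curve"))) {
    stopf("boundaries must be a list of three boundary_curve objects")
  }
  cfg <- structure(list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    n_frames = as.integer(n_frames), pixel_pitch = pixel_pitch,
    boundaries = boundaries, band_brightness = band_brightness,
    band_halfwidth = band_halfwidth, background = background,
    noise = list(speckle_var = noise$speckle_var %||% 0,
                 gaussian_sd = noise$gaussian_sd %||% 0),
    n_landmarks = as.integer(n_landmarks),
    landmark_spacing = as.integer(landmark_spacing),
    seed = as.integer(seed)), class = "phantom_config")
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  x <- seq(0L, cfg$image_width - 1L)
  for (t in seq(0L, cfg$n_frames - 1L)) {
    d1 <- boundary_depth(cfg$boundaries[[1]], x, t)
    d2 <- boundary_depth(cfg$boundaries[[2]], x, t)
    d3 <- boundary_depth(cfg$boundaries[[3]], x, t)
    if (any(d2 <= d1) || any(d3 <= d2)) {
      stopf(paste("boundary curves cross at frame %d: boundaries must be",
                  "ordered superficial < middle < deep at every x"), t)
    }
    if (min(d1) < 0 || max(d3) > cfg$image_height - 1L) {
      stopf("boundary curves leave the image at frame %d", t)
    }
  }
  span <- (cfg$n_landmarks - 1L) * cfg$landmark_spacing
  if (span > cfg$image_width - 1L) {
    stopf("landmark span (%d px) exceeds image width", span)
  }
  invisible(cfg)
}

# x-positions of the truth landmarks (0-based, centred laterally).
phantom_landmark_x <- function(cfg) {
  span <- (cfg$n_landmarks - 1L) * cfg$landmark_spacing
  x0 <- floor((cfg$image_width - 1L - span) / 2)
  x0 + seq(0L, span, by = cfg$landmark_spacing)
}

# Truth shape (57 landmarks) for one frame.
phantom_truth_shape <- function(cfg, frame) {
  x <- phantom_landmark_x(cfg)
  lm <- do.call(rbind, lapply(cfg$boundaries, function(b) {
    cbind(x = x, y = boundary_depth(b, x, frame))
  }))
  apo_shape(lm, frame_index = frame, n_boundaries = 3L)
}

#' Generate a phantom ultrasound sequence
#'
#' Renders each boundary as a Gaussian-profiled bright ridge centred on the
#' true curve, adds multiplicative gamma speckle and additive Gaussian noise,
#' and clamps intensities to \[0, 1\].  Deterministic given `config$seed`.
#'
#' @param config a [phantom_config()].
#' @return `phantom_sequence`: list with `frames` (list of H x W matrices),
#'   `truth_shapes` (one [apo_shape()] per frame) and `config`.
#' @export
generate_phantom_sequence <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  validate_phantom_config(config)
  h <- config$image_height
  w <- config$image_width
  y <- seq(0L, h - 1L)
  x <- seq(0L, w - 1L)
  s2 <- 2 * config$band_halfwidth^2
  sv <- config$noise$speckle_var
  gs <- config$noise$gaussian_sd
  frames <- with_seed(config$seed, {
    lapply(seq(0L, config$n_frames - 1L), function(t) {
      img <- matrix(config$background, h, w)
      for (b in config$boundaries) {
        d <- boundary_depth(b, x, t)
        img <- img + config$band_brightness *
          exp(-(outer(y, d, "-"))^2 / s2)
      }
      if (sv > 0) {
        img <- img * matrix(stats::rgamma(h * w, shape = 1 / sv,
                                          rate = 1 / sv), h, w)
      }
      if (gs > 0) {
        img <- img + matrix(stats::rnorm(h * w, sd = gs), h, w)
      }
      pmin(pmax(img, 0), 1)
    })
  })
  truth <- lapply(seq(0L, config$n_frames - 1L), function(t) {
    phantom_truth_shape(config, t)
  })
  structure(list(frames = frames, truth_shapes = truth, config = config),
            class = "phantom_sequence")
}

#' @export
print.phantom_sequence <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("phantom_sequence: %d frames of %d x %d px (pitch %.5f mm/px)\n",
              cfg$n_frames, cfg$image_height, cfg$image_width,
              cfg$pixel_pitch))
  invisible(x)
}

#' Generate a synthetic vertical ground-reaction-force trace
#'
#' Stance phases are positive half-sine bumps of duration
#' `duty_factor * stride_period`; swing phases are zero force.  Foot-strike
#' (stance onset) truth times are recorded on the sampling grid.
#'
#' @param stride_period stride duration, s.
#' @param duty_factor fraction of the stride spent in stance, in (0, 1).
#' @param n_strides number of stance phases generated.
#' @param sampling_rate Hz (default 2000).
#' @param peak_force stance peak, N.
#' @param noise_sd additive Gaussian noise sd, N (force clamped at 0).
#' @param seed integer seed.
#' @return `grf_trace`: list with `time`, `vertical_force`, `sampling_rate`,
#'   `true_event_times`.
#' @export
generate_grf <- function(stride_period = 1.0, duty_factor = 0.35,
                         n_strides = 5L, sampling_rate = 2000,
                         peak_force = 1600, noise_sd = 0, seed = 1L) {
  if (!is_number(stride_period) || stride_period <= 0) {
    stopf("stride_period must be positive")
  }
  if (!is_number(duty_factor) || duty_factor <= 0 || duty_factor >= 1) {
    stopf("duty_factor must lie strictly between 0 and 1")
  }
  if (!is_count(n_strides)) stopf("n_strides must be >= 1")
  n <- as.integer(ceiling(n_strides * stride_period * sampling_rate)) + 1L
  time <- seq(0L, n - 1L) / sampling_rate
  onsets <- (seq_len(n_strides) - 1L) * stride_period
  # snap truth events onto the sampling grid (first sample at/after onset)
  events <- ceiling(onsets * sampling_rate - 1e-9) / sampling_rate
  stance_dur <- duty_factor * stride_period
  phase <- time %% stride_period
  force <- ifelse(phase < stance_dur,
                  peak_force * sin(pi * phase / stance_dur), 0)
  force[time >= n_strides * stride_period] <- 0
  if (noise_sd > 0) {
    force <- force + with_seed(seed, stats::rnorm(n, sd = noise_sd))
  }
  force <- pmax(force, 0)
  structure(list(time = time, vertical_force = force,
                 sampling_rate = sampling_rate, true_event_times = events),
            class = "grf_trace")
}

#' Generate smooth zero-mean Gaussian null fields
#'
#' White Gaussian noise convolved with a Gaussian kernel of the requested
#' full-width-at-half-maximum, rescaled to unit pointwise variance and
#' multiplied by `sd`.  The kernel FWHM equals the random-field smoothness
#' recovered by [estimate_fwhm()].
#'
#' @param n_fields number of fields (rows).
#' @param n_nodes nodes per field (columns), >= 2.
#' @param fwhm smoothness, nodes, > 0.
#' @param sd pointwise standard deviation.
#' @param seed integer seed.
#' @return numeric matrix `n_fields x n_nodes`.
#' @export
generate_smooth_null_fields <- function(n_fields, n_nodes = 200L, fwhm = 20,
                                        sd = 1, seed = 1L) {
  if (!is_count(n_fields)) stopf("n_fields must be >= 1")
  if (!is_count(n_nodes, 2L)) stopf("n_nodes must be >= 2")
  if (!is_number(fwhm) || fwhm <= 0) stopf("fwhm must be > 0")
  sigma <- fwhm / sqrt(8 * log(2))
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  wobble <- with_seed(seed, {
    matrix(stats::rnorm(n_fields * (n_nodes + 2L * r)), n_fields)
  })
  out <- matrix(0, n_fields, n_nodes)
  for (i in seq_along(k)) {
    out <- out + k[i] * wobble[, i:(i + n_nodes - 1L), drop = FALSE]
  }
  out * (sd / sqrt(sum(k^2)))
}

#' Generate labelled fields with injected region/condition effects
#'
#' Simulates a balanced within-subject factorial: each observation is
#' subject intercept + region effect curve + condition effect curve + smooth
#' Gaussian noise, fully crossed over subject x region x condition x stride.
#' Used for parameter-recovery and power checks of the SPM stage.
#'
#' @param region_offsets matrix (regions x nodes) of region effect curves.
#' @param condition_offsets matrix (conditions x nodes) of condition curves.
#' @param n_subjects,n_strides design sizes.
#' @param subject_sd sd of the random subject intercepts.
#' @param noise_fwhm,noise_sd smooth-noise parameters (see
#'   [generate_smooth_null_fields()]); `noise_sd = 0` gives noiseless data.
#' @param seed integer seed.
#' @return list with `fields` (observations x nodes) and `labels`
#'   (data.frame: subject, region, condition, stride).
#' @export
generate_effect_fields <- function(region_offsets, condition_offsets,
                                   n_subjects = 10L, n_strides = 4L,
                                   subject_sd = 1, noise_fwhm = 20,
                                   noise_sd = 1, seed = 1L) {
  region_offsets <- as.matrix(region_offsets)
  condition_offsets <- as.matrix(condition_offsets)
  if (ncol(region_offsets) != ncol(condition_offsets)) {
    stopf("region and condition offset curves must share one node grid")
  }
  n_nodes <- ncol(region_offsets)
  n_reg <- nrow(region_offsets)
  n_con <- nrow(condition_offsets)
  labels <- expand.grid(stride = seq_len(n_strides),
                        condition = seq_len(n_con),
                        region = seq_len(n_reg),
                        subject = seq_len(n_subjects))
  labels <- labels[, c("subject", "region", "condition", "stride")]
  n_obs <- nrow(labels)
  with_seed(seed, {
    intercepts <- stats::rnorm(n_subjects, sd = subject_sd)
    noise <- if (noise_sd > 0) {
      generate_smooth_null_fields(n_obs, n_nodes, fwhm = noise_fwhm,
                                  sd = noise_sd, seed = NULL)
    } else {
      matrix(0, n_obs, n_nodes)
    }
    fields <- noise + intercepts[labels$subject] +
      region_offsets[labels$region, , drop = FALSE] +
      condition_offsets[labels$condition, , drop = FALSE]
    list(fields = fields, labels = labels,
         subject_intercepts = intercepts)
  })
}
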