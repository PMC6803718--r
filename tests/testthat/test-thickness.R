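# Thickness extraction, stride segmentation, time normalisation, baseline.

test_that("boundary interpolation is exact at landmarks and accurate on curves", {
  x <- seq(0, 576, by = 32)
  # exact at landmarks, linear reproduction for collinear points
  lin <- cbind(x, 100 + 0.05 * x)
  expect_equal(interpolate_boundary(lin, x), lin[, 2L])
  q <- seq(0, 576, by = 1)
  expect_lt(max(abs(interpolate_boundary(lin, q) - (100 + 0.05 * q))),
            1e-9)
  # gently curved boundary (amplitude 5 px at 32 px spacing) within 0.1 px
  f <- function(x) 150 + 5 * sin(2 * pi * x / 384 + 0.7)
  sine <- cbind(x, f(x))
  expect_equal(interpolate_boundary(sine, x), f(x))
  expect_lt(max(abs(interpolate_boundary(sine, q) - f(q))), 0.1)
  expect_error(interpolate_boundary(lin, -5), "extrapolation")
})

test_that("site thickness matches flat and wedge closed forms", {
  x <- seq(15, 15 + 18 * 32, by = 32)
  pitch <- 2.75 / 32
  flat <- apo_shape(rbind(cbind(x, 50), cbind(x, 150), cbind(x, 250)))
  th <- compute_thickness(flat, "SO", n_sites = 20L, pixel_pitch = pitch)
  expect_equal(th$site_thickness, rep(100 * pitch, 20L))
  expect_equal(th$mean_thickness, 8.59375)
  expect_false(th$crossing)
  # gastrocnemius view uses boundaries 1-2
  thg <- compute_thickness(flat, "LG", n_sites = 20L, pixel_pitch = pitch)
  expect_equal(thg$mean_thickness, 8.59375)
  # wedge: thickness linear in site index, mean = midspan value
  wedge <- apo_shape(rbind(cbind(x, 50), cbind(x, 150),
                           cbind(x, 200 + 0.1 * (x - 15))))
  thw <- compute_thickness(wedge, "SO", n_sites = 20L, pixel_pitch = pitch)
  expect_lt(max(abs(diff(diff(thw$site_thickness)))), 1e-9)
  expect_equal(thw$mean_thickness,
               (50 + 0.1 * 288) * pitch, tolerance = 1e-9)
  # mean_thickness consistency invariant
  expect_equal(thw$mean_thickness, mean(thw$site_thickness),
               tolerance = 1e-10)
  expect_error(compute_thickness(flat, "VL"), "unknown muscle")
})

test_that("thickness agrees with analytic truth on phantom shapes", {
  cfg <- small_phantom_config(5L)
  seq <- generate_phantom_sequence(cfg)
  ts <- compute_thickness_series(seq$truth_shapes, "SO", n_sites = 20L,
                                 pixel_pitch = cfg$pixel_pitch)
  curve_depth <- function(b, x, t) {
    b$depth + b$slope * x +
      b$amp_x * sin(2 * pi * x / b$wavelength_x + b$phase_x) +
      b$motion_amp * sin(2 * pi * t / b$motion_period + b$motion_phase)
  }
  for (f in 1:5) {
    truth_mm <- (curve_depth(cfg$boundaries[[3L]], ts$site_x, f - 1) -
                   curve_depth(cfg$boundaries[[2L]], ts$site_x, f - 1)) *
      cfg$pixel_pitch
    expect_lt(max(abs(ts$site_thickness[f, ] - truth_mm)),
              0.5 * cfg$pixel_pitch)
  }
  expect_equal(ts$mean_thickness, rowMeans(ts$site_thickness),
               tolerance = 1e-10)
})

test_that("stride detection finds generator truth and rejects degenerate traces", {
  g <- generate_grf(stride_period = 0.8, duty_factor = 0.4, n_strides = 6L)
  w <- detect_strides(g, 20, 4L)
  strikes <- attr(w, "strikes")
  # crossing of a 20 N threshold on a half-sine bump lags stance onset by
  # (stance/pi)*asin(thr/peak); detection is within one sample of that
  lag <- (0.4 * 0.8 / pi) * asin(20 / 1600)
  for (i in seq_len(min(length(strikes), length(g$true_event_times)))) {
    expect_lt(abs(strikes[i] - g$true_event_times[i]),
              lag + 2 / g$sampling_rate)
  }
  # windows disjoint, contiguous, half-open
  expect_equal(w$start[-1L], w$end[-nrow(w)])
  expect_true(all(w$end > w$start))
  zero <- list(time = seq(0, 5, by = 5e-4), vertical_force = rep(0, 10001))
  expect_error(detect_strides(zero, 20, 4L), "insufficient strikes")
  expect_error(detect_strides(g, 1e5, 4L), "insufficient strikes")
})

test_that("stride normalisation reproduces constants, ramps and sinusoids", {
  win <- list(start = 1, end = 2)
  times <- seq(0, 3, by = 1 / 80)
  expect_equal(normalize_stride(rep(10, length(times)), times, win),
               rep(10, 200L))
  ramp <- 2 * times
  out <- normalize_stride(ramp, times, win, 200L)
  expect_lt(max(abs(diff(diff(out)))), 1e-9)
  expect_equal(out[1L], 2, tolerance = 1e-9)
  sine <- 5 * sin(2 * pi * times)
  outs <- normalize_stride(sine, times, win, 200L)
  nodes <- 1 + (0:199) / 200
  expect_lt(max(abs(outs - 5 * sin(2 * pi * nodes))), 0.05)  # < 1% of amplitude
  expect_error(normalize_stride(rep(1, 4), c(0, 1, 2, 3),
                                list(start = 2.4, end = 2.6)),
               "fewer than 2")
})

test_that("baseline subtraction is exact and linear", {
  m <- matrix(17, 200L, 21L)
  out <- subtract_baseline(m, rep(15, 21L))
  expect_equal(out, matrix(2, 200L, 21L))
  expect_equal(subtract_baseline(matrix(15, 5L, 3L), rep(15, 3L)),
               matrix(0, 5L, 3L))
  expect_error(subtract_baseline(m, rep(15, 20L)), "mismatch")
  # mean-site change equals mean of per-site changes
  set.seed(2)
  trial <- matrix(rnorm(200 * 20, mean = 17), 200L)
  trial <- cbind(trial, rowMeans(trial))
  standing <- c(rnorm(20, 15), 0)
  standing[21L] <- mean(standing[1:20])
  ch <- subtract_baseline(trial, standing)
  expect_equal(ch[, 21L], rowMeans(ch[, 1:20]), tolerance = 1e-10)
})

test_that("stride_normalized_thickness chains the stages coherently", {
  cfg <- small_phantom_config(33L)
  seq <- generate_phantom_sequence(cfg)
  g <- generate_grf(stride_period = 1.0, duty_factor = 0.4, n_strides = 3L)
  ts <- compute_thickness_series(seq$truth_shapes, "SO",
                                 pixel_pitch = cfg$pixel_pitch,
                                 frame_times = (0:32) / 16)
  standing <- standing_baseline(ts)
  st <- stride_normalized_thickness(ts, g, standing, n_strides = 2L,
                                    n_nodes = 100L)
  expect_equal(dim(st$change), c(2L, 100L, 21L))
  expect_equal(st$change, st$thickness - rep(standing,
                                             each = 2L * 100L),
               tolerance = 1e-10)
  # mean consistency survives normalisation and subtraction
  expect_equal(st$change[, , 21L],
               apply(st$change[, , 1:20], c(1L, 2L), mean),
               tolerance = 1e-10)
})
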