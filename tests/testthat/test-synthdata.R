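# Phantom, GRF and random-field generators: analytic truth, determinism,
# and statistical calibration.

test_that("phantom sequences honour flat geometry, determinism and closed-form curves", {
  flat <- phantom_config(
    image_height = 300L, image_width = 320L, n_frames = 3L,
    boundaries = list(boundary_curve(50), boundary_curve(150),
                      boundary_curve(250)),
    n_landmarks = 19L, landmark_spacing = 16L, seed = 5L)
  seq <- generate_phantom_sequence(flat)
  for (s in seq$truth_shapes) {
    th <- boundary_landmarks(s, 3L)[, 2L] - boundary_landmarks(s, 1L)[, 2L]
    expect_equal(th, rep(200, 19))
    th2 <- boundary_landmarks(s, 2L)[, 2L] - boundary_landmarks(s, 1L)[, 2L]
    expect_equal(th2, rep(100, 19))
  }
  seq2 <- generate_phantom_sequence(flat)
  expect_identical(seq$frames, seq2$frames)

  sine <- phantom_config(
    image_height = 300L, image_width = 320L, n_frames = 6L,
    boundaries = list(boundary_curve(50),
                      boundary_curve(150, amp_x = 5, wavelength_x = 200,
                                     phase_x = 0.4, motion_amp = 3,
                                     motion_period = 6),
                      boundary_curve(250)),
    n_landmarks = 19L, landmark_spacing = 16L, seed = 5L)
  sseq <- generate_phantom_sequence(sine)
  x <- boundary_landmarks(sseq$truth_shapes[[1L]], 2L)[, 1L]
  for (t in 0:5) {
    expected <- 150 + 5 * sin(2 * pi * x / 200 + 0.4) +
      3 * sin(2 * pi * t / 6)
    got <- boundary_landmarks(sseq$truth_shapes[[t + 1L]], 2L)[, 2L]
    expect_lt(max(abs(got - expected)), 1e-9)
  }
})

test_that("crossing or out-of-image boundary configurations are rejected", {
  expect_error(
    phantom_config(boundaries = list(boundary_curve(150),
                                     boundary_curve(60),
                                     boundary_curve(245))),
    "cross")
  expect_error(
    phantom_config(boundaries = list(boundary_curve(100),
                                     boundary_curve(102, motion_amp = 5),
                                     boundary_curve(245))),
    "cross")
})

test_that("GRF generator produces half-sine stance phases with exact truth events", {
  g <- generate_grf(stride_period = 1.0, duty_factor = 0.6, n_strides = 4L,
                    sampling_rate = 2000, noise_sd = 0)
  expect_length(g$true_event_times, 4L)
  expect_true(all(diff(g$true_event_times) > 0))
  # consecutive events differ by the period to within one sample
  expect_true(all(abs(diff(g$true_event_times) - 1.0) <= 1 / 2000 + 1e-12))
  # swing phase exactly zero without noise
  phase <- g$time %% 1.0
  expect_true(all(g$vertical_force[phase >= 0.6] == 0))
  expect_true(all(g$vertical_force >= 0))
  # determinism with noise
  g1 <- generate_grf(noise_sd = 10, seed = 3L)
  g2 <- generate_grf(noise_sd = 10, seed = 3L)
  expect_identical(g1$vertical_force, g2$vertical_force)
  expect_error(generate_grf(stride_period = 0), "positive")
  expect_error(generate_grf(duty_factor = 1), "duty_factor")
})

test_that("smooth null fields are unit-calibrated, deterministic and smooth", {
  expect_identical(generate_smooth_null_fields(5L, 40L, 10, sd = 0,
                                               seed = 2L),
                   matrix(0, 5L, 40L))
  Y <- generate_smooth_null_fields(10000L, 50L, fwhm = 10, sd = 2,
                                   seed = 7L)
  v <- colMeans(sweep(Y, 2L, colMeans(Y))^2)
  expect_true(all(abs(v / 4 - 1) < 0.05))   # pointwise variance within 5%
  # near-constant fields in the huge-FWHM limit.  For a unit-variance
  # Gaussian field the increment sd over a span L is ~ L*sqrt(8 ln 2)/fwhm,
  # so a pointwise range below 0.05 needs fwhm >> 40 * L; fwhm = 200 *
  # n_nodes comfortably satisfies the bound, fwhm = 10 * n_nodes does not.
  Yc <- generate_smooth_null_fields(200L, 40L, fwhm = 200 * 40, sd = 1,
                                    seed = 8L)
  rng <- apply(Yc, 1L, function(r) diff(range(r)))
  expect_gte(mean(rng < 0.05), 0.95)
  # generator FWHM is recovered by the smoothness estimator within 10%
  R <- generate_smooth_null_fields(1000L, 200L, fwhm = 20, seed = 9L)
  expect_lt(abs(estimate_fwhm(R) / 20 - 1), 0.1)
})

test_that("effect-field generator injects exactly the stated cell sums", {
  n_nodes <- 30L
  reg <- rbind(rep(0, n_nodes), c(rep(0, 10), rep(2, 10), rep(0, 10)))
  con <- rbind(rep(0, n_nodes), rep(0.5, n_nodes))
  ef <- generate_effect_fields(reg, con, n_subjects = 3L, n_strides = 2L,
                               subject_sd = 1, noise_sd = 0, seed = 4L)
  expect_equal(nrow(ef$fields), 3L * 2L * 2L * 2L)
  expected <- ef$subject_intercepts[ef$labels$subject] +
    reg[ef$labels$region, ] + con[ef$labels$condition, ]
  expect_equal(ef$fields, expected)
  # zero offsets reduce to null fields plus subject intercepts
  zero <- matrix(0, 1L, n_nodes)
  ef0 <- generate_effect_fields(zero, zero, n_subjects = 3L,
                                n_strides = 2L, subject_sd = 1,
                                noise_fwhm = 8, noise_sd = 1, seed = 4L)
  set.seed(4L)
  ints <- rnorm(3L, sd = 1)
  noise <- generate_smooth_null_fields(nrow(ef0$fields), n_nodes, fwhm = 8,
                                       sd = 1, seed = NULL)
  expect_equal(ef0$fields, noise + ints[ef0$labels$subject])
  expect_error(generate_effect_fields(matrix(0, 1, 10), matrix(0, 1, 9)),
               "node grid")
})
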