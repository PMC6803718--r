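# 1D SPM: pointwise RM-ANOVA and paired-t fields against 0D oracles,
# smoothness estimation, RFT thresholds and cluster extraction.

test_that("RM-ANOVA F fields match an aov() oracle node by node", {
  set.seed(13)
  s <- 4L; a <- 3L; b <- 2L
  lab <- expand.grid(condition = seq_len(b), region = seq_len(a),
                     subject = seq_len(s))
  n_nodes <- 5L
  Y <- matrix(rnorm(nrow(lab) * n_nodes), nrow(lab))
  design <- field_design(Y, lab$subject, lab$region, lab$condition)
  fr <- pointwise_rm_anova(design, "region")
  fc <- pointwise_rm_anova(design, "condition")
  fi <- pointwise_rm_anova(design, "interaction")
  expect_equal(fr$df, c(a - 1L, (a - 1L) * (s - 1L)))
  expect_equal(fc$df, c(b - 1L, (b - 1L) * (s - 1L)))
  expect_equal(fi$df, c((a - 1L) * (b - 1L),
                        (a - 1L) * (b - 1L) * (s - 1L)))
  for (node in seq_len(n_nodes)) {
    d <- data.frame(y = Y[, node], subject = factor(lab$subject),
                    region = factor(lab$region),
                    condition = factor(lab$condition))
    fit <- stats::aov(y ~ region * condition +
                        Error(subject / (region * condition)), data = d)
    sm <- summary(fit)
    f_reg <- sm[["Error: subject:region"]][[1L]]["region", "F value"]
    f_con <- sm[["Error: subject:condition"]][[1L]]["condition", "F value"]
    f_int <- sm[["Error: subject:region:condition"]][[1L]][
      "region:condition", "F value"]
    expect_equal(fr$z[node], f_reg, tolerance = 1e-6)
    expect_equal(fc$z[node], f_con, tolerance = 1e-6)
    expect_equal(fi$z[node], f_int, tolerance = 1e-6)
  }
})

test_that("ANOVA degenerate limits: null identity and noiseless infinity", {
  s <- 3L; a <- 4L; b <- 2L
  lab <- expand.grid(condition = seq_len(b), region = seq_len(a),
                     subject = seq_len(s))
  # data constant across the tested factor -> F = 0
  base <- 2 * lab$subject + 0.5 * lab$condition
  Y0 <- matrix(rep(base, 3L), ncol = 3L)
  d0 <- field_design(Y0, lab$subject, lab$region, lab$condition)
  expect_equal(pointwise_rm_anova(d0, "region")$z, rep(0, 3L))
  # injected noiseless region effect -> infinite F exactly at hit nodes
  reg <- rbind(c(0, 0, 0), c(0, 3, 0))
  con <- matrix(0, 2L, 3L)
  ef <- generate_effect_fields(reg, con, n_subjects = 4L, n_strides = 1L,
                               subject_sd = 1, noise_sd = 0, seed = 2L)
  de <- field_design(ef$fields, ef$labels$subject, ef$labels$region,
                     ef$labels$condition, ef$labels$stride)
  z <- pointwise_rm_anova(de, "region")$z
  expect_identical(z[2L], Inf)
  expect_equal(z[c(1L, 3L)], c(0, 0))
  # unbalanced designs are rejected
  expect_error(field_design(Y0[-1L, ], lab$subject[-1L], lab$region[-1L],
                            lab$condition[-1L]),
               "unbalanced")
  expect_error(pointwise_rm_anova(d0, "nope"))
})

test_that("paired-t fields match the closed form and flag degeneracies", {
  set.seed(4)
  n <- 9L
  y1 <- matrix(rnorm(n * 6L), n)
  y2 <- matrix(rnorm(n * 6L), n)
  f <- pointwise_paired_t(y1, y2)
  d <- y1 - y2
  for (node in 1:6) {
    tt <- mean(d[, node]) / (stats::sd(d[, node]) / sqrt(n))
    expect_equal(f$z[node], tt, tolerance = 1e-10)
  }
  expect_equal(f$df, c(1L, n - 1L))
  # identical sets -> 0; constant nonzero difference -> signed Inf, flagged
  f0 <- pointwise_paired_t(y1, y1)
  expect_equal(f0$z, rep(0, 6L))
  fc <- pointwise_paired_t(matrix(2, n, 6L), matrix(0, n, 6L))
  expect_true(all(fc$z == Inf))
  expect_true(all(fc$flags))
  expect_error(pointwise_paired_t(y1[1L, , drop = FALSE],
                                  y2[1L, , drop = FALSE]), "n >= 2")
})

test_that("smoothness estimation hits generator truth and known limits", {
  # white noise: fwhm = sqrt(4 log 2) / sqrt(2) ~ 1.18, below 2
  set.seed(6)
  W <- matrix(rnorm(500 * 101), 500L)
  fw <- estimate_fwhm(W)
  expect_gt(fw, 1.06)
  expect_lt(fw, 1.25)
  R <- generate_smooth_null_fields(1000L, 200L, fwhm = 20, seed = 3L)
  expect_lt(abs(estimate_fwhm(R) / 20 - 1), 0.1)
  expect_warning(fwc <- estimate_fwhm(matrix(rep(c(1, 2), each = 5L), 2L,
                                             5L, byrow = TRUE)),
                 "constant")
  expect_identical(fwc, Inf)
  expect_error(estimate_fwhm(matrix(0, 3L, 4L)), "all-zero")
})

test_that("RFT thresholds reduce to 0D quantiles and grow as smoothness falls", {
  expect_equal(rft_critical_threshold("t", 12L, 200L, Inf, 0.05,
                                      two_sided = FALSE),
               stats::qt(0.95, 12L), tolerance = 1e-4)
  expect_equal(rft_critical_threshold("t", 12L, 200L, Inf, 0.05,
                                      two_sided = TRUE),
               stats::qt(0.975, 12L), tolerance = 1e-4)
  expect_equal(rft_critical_threshold("F", c(3L, 24L), 200L, Inf, 0.05),
               stats::qf(0.95, 3L, 24L), tolerance = 1e-4)
  for (kind in c("t", "F")) {
    u <- vapply(c(50, 20, 10, 5), function(fw) {
      rft_critical_threshold(kind, c(2L, 16L), 200L, fw, 0.05)
    }, numeric(1))
    expect_true(all(diff(u) > 0))
  }
  expect_error(rft_critical_threshold("t", 10L, 200L, 10, 1.5), "alpha")
})

test_that("RFT threshold is calibrated against Monte-Carlo field maxima", {
  u <- rft_critical_threshold("t", 1e6, 200L, 10, 0.05, two_sided = FALSE)
  Y <- generate_smooth_null_fields(10000L, 200L, fwhm = 10, seed = 42L)
  rate <- mean(apply(Y, 1L, max) > u)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("cluster extraction is exact and involutive", {
  z <- rep(0, 200L)
  expect_identical(nrow(suprathreshold_clusters(z, 1)), 0L)
  z[65:123] <- 5   # 0-based nodes 64-122
  cl <- suprathreshold_clusters(z, 1)
  expect_equal(cl$node_start, 64L)
  expect_equal(cl$node_end, 122L)
  expect_equal(cl$start_pct, 32)
  expect_equal(cl$end_pct, 61.5)
  expect_identical(suprathreshold_clusters(-(-z), 1), cl)
  expect_error(suprathreshold_clusters(z, Inf), "finite")
})

test_that("post-hoc families apply Bonferroni correction", {
  set.seed(8)
  mk <- function() matrix(rnorm(8 * 50), 8L) +
    generate_smooth_null_fields(8L, 50L, 8, seed = sample.int(1e6, 1))
  cmp <- list(a = list(mk(), mk()), b = list(mk(), mk()),
              c = list(mk(), mk()), d = list(mk(), mk()))
  res <- posthoc_paired_t_family(cmp, alpha_family = 0.05)
  expect_equal(attr(res, "alpha_per_comparison"), 0.0125)
  expect_equal(res$a$alpha, 0.0125)
  # per-comparison threshold strictly exceeds the single-test threshold
  single <- spm_inference(pointwise_paired_t(cmp$a[[1L]], cmp$a[[2L]]),
                          alpha = 0.05)
  expect_gt(res$a$critical_threshold, single$critical_threshold)
  # self-comparison: zero field, no clusters
  self <- posthoc_paired_t_family(list(s = list(cmp$a[[1L]], cmp$a[[1L]])))
  expect_equal(self$s$z, rep(0, 50L))
  expect_identical(nrow(self$s$clusters), 0L)
  expect_error(posthoc_paired_t_family(list()), "non-empty")
})
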