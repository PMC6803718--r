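# One-dimensional statistical parametric mapping over stride-cycle nodes:
# pointwise repeated-measures ANOVA and paired-t statistic fields,
# residual-based smoothness (FWHM) estimation, random-field-theory critical
# thresholds via the expected Euler characteristic, suprathreshold cluster
# reporting, and Bonferroni-corrected post-hoc families.

#' Balanced within-subject field design
#'
#' Holds a matrix of 1D observations (rows) over stride-cycle nodes
#' (columns) with per-observation factor labels.  Strides are within-cell
#' replicates; the design must be balanced (equal strides in every
#' subject x region x condition cell).
#'
#' @param fields observations x nodes matrix.
#' @param subject,region,condition,stride label vectors (length = rows);
#'   `region`/`condition`/`stride` may be omitted (single level).
#' @return a `field_design` object.
#' @export
field_design <- function(fields, subject, region = NULL, condition = NULL,
                         stride = NULL) {
  fields <- as.matrix(fields)
  n <- nrow(fields)
  one <- rep(1L, n)
  labels <- data.frame(subject = factor(subject),
                       region = factor(region %||% one),
                       condition = factor(condition %||% one),
                       stride = factor(stride %||% one))
  if (any(vapply(labels, length, integer(1)) != n)) {
    stopf("label lengths must equal the number of observation rows")
  }
  counts <- table(labels$subject, labels$region, labels$condition)
  if (length(unique(as.vector(counts))) != 1L || any(counts == 0)) {
    stopf("unbalanced design: every subject x region x condition cell must %s",
          "contain the same number of strides")
  }
  structure(list(fields = fields, labels = labels,
                 n_replicates = as.vector(counts)[1L]),
            class = "field_design")
}

# Group means of matrix rows by integer group code g in 1..ng; returns an
# ng x ncol matrix ordered by group code.
group_mean <- function(M, g, ng) {
  r <- rowsum(M, g)
  idx <- as.integer(rownames(r))
  out <- matrix(0, ng, ncol(M))
  out[idx, ] <- r / tabulate(g, ng)[idx]
  out
}

#' Pointwise two-way repeated-measures ANOVA field
#'
#' At every node independently, the within-subject F statistic for the
#' requested effect (region main effect, condition main effect, or their
#' interaction), with subject as the random blocking factor.  Strides are
#' first averaged into subject x region x condition cell means; each
#' effect's error term is its interaction with subject.  Where both effect
#' and error mean squares are exactly zero the F value is reported as 0;
#' zero error with a nonzero effect gives +Inf (noiseless limit).
#'
#' @param design a [field_design()].
#' @param effect `"region"`, `"condition"` or `"interaction"`.
#' @return `spm_field`: `stat = "F"`, `z` (F per node), `df` (effect,
#'   error), `residuals` (for smoothness estimation), `effect`.
#' @export
pointwise_rm_anova <- function(design,
                               effect = c("region", "condition",
                                          "interaction")) {
  effect <- match.arg(effect)
  lab <- design$labels
  Y <- design$fields
  si <- as.integer(lab$subject)
  ai <- as.integer(lab$region)
  bi <- as.integer(lab$condition)
  s <- nlevels(lab$subject)
  a <- nlevels(lab$region)
  b <- nlevels(lab$condition)
  if (s < 2L) stopf("at least 2 subjects are required")
  if (effect == "region" && a < 2L) stopf("region has a single level")
  if (effect == "condition" && b < 2L) stopf("condition has a single level")
  if (effect == "interaction" && (a < 2L || b < 2L)) {
    stopf("interaction requires >= 2 levels of both factors")
  }
  # average strides into cell means
  cell <- (si - 1L) * a * b + (ai - 1L) * b + bi
  C <- group_mean(Y, cell, s * a * b)
  cells <- seq_len(s * a * b)
  cs <- (cells - 1L) %/% (a * b) + 1L
  ca <- ((cells - 1L) %/% b) %% a + 1L
  cb <- (cells - 1L) %% b + 1L
  N <- ncol(Y)
  grand <- colMeans(C)
  mS <- group_mean(C, cs, s)
  mA <- group_mean(C, ca, a)
  mB <- group_mean(C, cb, b)
  mAS <- group_mean(C, (cs - 1L) * a + ca, s * a)
  mBS <- group_mean(C, (cs - 1L) * b + cb, s * b)
  mAB <- group_mean(C, (ca - 1L) * b + cb, a * b)
  G <- matrix(grand, 1L)[rep(1L, s * a * b), , drop = FALSE]
  rA <- mA[ca, , drop = FALSE]
  rB <- mB[cb, , drop = FALSE]
  rS <- mS[cs, , drop = FALSE]
  rAS <- mAS[(cs - 1L) * a + ca, , drop = FALSE]
  rBS <- mBS[(cs - 1L) * b + cb, , drop = FALSE]
  rAB <- mAB[(ca - 1L) * b + cb, , drop = FALSE]
  if (effect == "region") {
    ss_eff <- b * s * colSums(sweep(mA, 2L, grand)^2)
    ss_err <- b * colSums((mAS - mA[rep(seq_len(a), s), , drop = FALSE] -
                             mS[rep(seq_len(s), each = a), , drop = FALSE] +
                             matrix(grand, 1L)[rep(1L, s * a), ,
                                               drop = FALSE])^2)
    df <- c(a - 1L, (a - 1L) * (s - 1L))
  } else if (effect == "condition") {
    ss_eff <- a * s * colSums(sweep(mB, 2L, grand)^2)
    ss_err <- a * colSums((mBS - mB[rep(seq_len(b), s), , drop = FALSE] -
                             mS[rep(seq_len(s), each = b), , drop = FALSE] +
                             matrix(grand, 1L)[rep(1L, s * b), ,
                                               drop = FALSE])^2)
    df <- c(b - 1L, (b - 1L) * (s - 1L))
  } else {
    ss_eff <- s * colSums((mAB -
                             mA[rep(seq_len(a), each = b), , drop = FALSE] -
                             mB[rep(seq_len(b), a), , drop = FALSE] +
                             matrix(grand, 1L)[rep(1L, a * b), ,
                                               drop = FALSE])^2)
    ss_err <- colSums((C - rAB - rAS - rBS + rA + rB + rS - G)^2)
    df <- c((a - 1L) * (b - 1L), (a - 1L) * (b - 1L) * (s - 1L))
  }
  ms_eff <- ss_eff / df[1L]
  ms_err <- ss_err / df[2L]
  tiny <- 1e-12 * (mean(C^2) + 1e-300)
  z <- ms_eff / ms_err
  z[ms_err <= tiny & ms_eff <= tiny] <- 0
  z[ms_err <= tiny & ms_eff > tiny] <- Inf
  # residuals defining the error process, for smoothness estimation
  if (design$n_replicates > 1L) {
    R <- Y - C[cell, , drop = FALSE]
  } else if (a > 1L && b > 1L) {
    R <- C - rAB - rAS - rBS + rA + rB + rS - G
  } else if (b > 1L) {
    R <- C - rB - rS + G
  } else if (a > 1L) {
    R <- C - rA - rS + G
  } else {
    stopf("design has no within-subject variation to estimate error from")
  }
  structure(list(stat = "F", z = z, df = df, residuals = R,
                 effect = effect, flags = !is.finite(z)),
            class = "spm_field")
}

#' Pointwise paired-t field
#'
#' Per node, `t = mean(d) / (sd(d) / sqrt(n))` for matched differences
#' `d = y1 - y2`.  Nodes with zero difference variance are reported as
#' signed infinity (0 when the mean difference is also 0) and flagged.
#'
#' @param y1,y2 matched observation matrices (equal dimensions, rows paired
#'   by subject/stride).
#' @return `spm_field` with `stat = "t"`, `df = n - 1`.
#' @export
pointwise_paired_t <- function(y1, y2) {
  y1 <- as.matrix(y1)
  y2 <- as.matrix(y2)
  if (!all(dim(y1) == dim(y2))) stopf("paired sets must have equal dimensions")
  n <- nrow(y1)
  if (n < 2L) stopf("paired t requires n >= 2")
  d <- y1 - y2
  mu <- colMeans(d)
  R <- sweep(d, 2L, mu)
  sdd <- sqrt(colSums(R^2) / (n - 1L))
  se <- sdd / sqrt(n)
  z <- ifelse(se > 0, mu / se, ifelse(mu == 0, 0, sign(mu) * Inf))
  structure(list(stat = "t", z = z, df = c(1L, n - 1L), residuals = R,
                 effect = "paired", flags = se == 0),
            class = "spm_field")
}

#' Field smoothness (FWHM) from residuals
#'
#' Residuals are normalised to unit pointwise variance, differentiated along
#' the node axis by forward differences, and pooled:
#' `FWHM = sqrt(4 log 2) / RMS(gradient)`.  Residuals constant along the
#' node axis give `Inf` (with a warning); all-zero residuals are an error.
#'
#' @param residuals observations x nodes matrix.
#' @return smoothness in nodes.
#' @export
estimate_fwhm <- function(residuals) {
  R <- as.matrix(residuals)
  if (nrow(R) < 2L) stopf("at least 2 residual rows are required")
  v <- colMeans(R^2)
  if (all(v == 0)) stopf("all-zero residuals")
  sdv <- sqrt(v)
  sdv[sdv == 0] <- 1
  Rn <- sweep(R, 2L, sdv, "/")
  D <- Rn[, -1L, drop = FALSE] - Rn[, -ncol(Rn), drop = FALSE]
  rms <- sqrt(mean(D^2))
  if (rms == 0) {
    warning("residuals constant along nodes; FWHM is infinite")
    return(Inf)
  }
  sqrt(4 * log(2)) / rms
}

# 1D Euler-characteristic densities per resel (Worsley), for unit-variance
# t and F random fields.
ec1_density <- function(stat_kind, u, df) {
  if (stat_kind == "t") {
    sqrt(4 * log(2)) / (2 * pi) * (1 + u^2 / df[length(df)])^
      (-(df[length(df)] - 1) / 2)
  } else {
    # Worsley's 1D F density; at k = 1 it equals 2 * rho1_t(sqrt(u)),
    # i.e. F(1, v) excursions match two-sided t(v) excursions exactly
    k <- df[1L]
    v <- df[2L]
    sqrt(4 * log(2)) / sqrt(2 * pi) *
      exp(lgamma((v + k - 1) / 2) - lgamma(v / 2) - lgamma(k / 2)) *
      sqrt(2) * (k * u / v)^((k - 1) / 2) *
      (1 + k * u / v)^(-(v + k - 2) / 2)
  }
}

stat_p0 <- function(stat_kind, u, df) {
  if (stat_kind == "t") {
    stats::pt(u, df[length(df)], lower.tail = FALSE)
  } else {
    stats::pf(u, df[1L], df[2L], lower.tail = FALSE)
  }
}

#' Random-field-theory critical threshold for a 1D statistic field
#'
#' Smallest `u` at which the expected Euler characteristic of the excursion
#' set, `P0(stat > u) + resels * EC1(u)` with
#' `resels = (n_nodes - 1) / fwhm`, equals `alpha` (doubled for two-sided t
#' fields).  Solved by bisection to 1e-6.  As `fwhm -> Inf` the threshold
#' reduces to the ordinary 0D t/F critical value.
#'
#' @param stat_kind `"t"` or `"F"`.
#' @param df degrees of freedom: `(k, v)` for F, `v` (or `(1, v)`) for t.
#' @param n_nodes field length in nodes.
#' @param fwhm field smoothness, nodes.
#' @param alpha family-wise error rate, in (0, 1).
#' @param two_sided double the excursion probability (default TRUE for t,
#'   FALSE for F).
#' @return critical threshold in statistic units.
#' @export
rft_critical_threshold <- function(stat_kind = c("t", "F"), df, n_nodes,
                                   fwhm, alpha = 0.05,
                                   two_sided = (stat_kind[1L] == "t")) {
  stat_kind <- match.arg(stat_kind)
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) {
    stopf("alpha must lie in (0, 1)")
  }
  if (!(length(fwhm) == 1L && (is.infinite(fwhm) || fwhm > 0))) {
    stopf("fwhm must be > 0")
  }
  resels <- if (is.infinite(fwhm)) 0 else (n_nodes - 1) / fwhm
  mult <- if (two_sided) 2 else 1
  target <- function(u) {
    mult * (stat_p0(stat_kind, u, df) + resels * ec1_density(stat_kind, u, df))
  }
  lo <- if (stat_kind == "t") {
    stats::qt(1 - alpha / mult, df[length(df)])
  } else {
    stats::qf(1 - alpha, df[1L], df[2L])
  }
  if (target(lo) <= alpha) return(lo)
  hi <- lo + 1
  iter <- 0L
  while (target(hi) > alpha) {
    hi <- lo + 2 * (hi - lo)
    iter <- iter + 1L
    if (iter > 200L) stopf("threshold search did not converge")
  }
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (target(mid) > alpha) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Suprathreshold clusters of a statistic field
#'
#' Maximal runs of consecutive nodes with statistic strictly above the
#' threshold, reported as half-open intervals in percent stride
#' (`node * 100 / n_nodes`; at 200 nodes, node/2).
#'
#' @param field numeric statistic vector over nodes.
#' @param threshold finite critical value.
#' @return data.frame: `node_start`, `node_end` (0-based, inclusive),
#'   `start_pct`, `end_pct` (half-open).
#' @export
suprathreshold_clusters <- function(field, threshold) {
  if (!is.finite(threshold)) stopf("threshold must be finite")
  exc <- !is.na(field) & field > threshold
  r <- rle(exc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  n <- length(field)
  data.frame(node_start = starts[keep] - 1L,
             node_end = ends[keep] - 1L,
             start_pct = (starts[keep] - 1L) * 100 / n,
             end_pct = ends[keep] * 100 / n)
}

#' Full SPM inference on a statistic field
#'
#' Estimates the smoothness from the field's residuals, computes the RFT
#' critical threshold at `alpha`, and extracts suprathreshold clusters
#' (of `|t|` for two-sided t fields).
#'
#' @param field an `spm_field` from [pointwise_rm_anova()] or
#'   [pointwise_paired_t()].
#' @param alpha significance level (default 0.05).
#' @param two_sided default TRUE for t fields.
#' @return `spm_result`: `stat`, `z`, `df`, `fwhm`, `resels`,
#'   `critical_threshold`, `clusters`, `alpha`, `flags`.
#' @export
spm_inference <- function(field, alpha = 0.05,
                          two_sided = (field$stat == "t")) {
  # all-zero residuals (e.g. a level compared with itself) carry no
  # smoothness information: treat the field as maximally smooth so the
  # threshold falls back to the 0D quantile
  fwhm <- if (all(field$residuals == 0)) Inf else
    estimate_fwhm(field$residuals)
  n_nodes <- length(field$z)
  u <- rft_critical_threshold(field$stat, field$df, n_nodes, fwhm, alpha,
                              two_sided)
  z_cl <- if (two_sided) abs(field$z) else field$z
  structure(list(stat = field$stat, z = field$z, df = field$df,
                 effect = field$effect, fwhm = fwhm,
                 resels = if (is.infinite(fwhm)) 0 else (n_nodes - 1) / fwhm,
                 critical_threshold = u,
                 clusters = suprathreshold_clusters(z_cl, u),
                 alpha = alpha, two_sided = two_sided,
                 flags = field$flags),
            class = "spm_result")
}

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf("spm_result: %s field (%s), df = (%s), fwhm = %.2f nodes\n",
              x$stat, x$effect, paste(x$df, collapse = ", "), x$fwhm))
  cat(sprintf("  critical %s = %.3f at alpha = %g%s\n", x$stat,
              x$critical_threshold, x$alpha,
              if (x$two_sided) " (two-sided)" else ""))
  if (nrow(x$clusters)) {
    for (i in seq_len(nrow(x$clusters))) {
      cat(sprintf("  cluster: %.1f-%.1f%% stride\n",
                  x$clusters$start_pct[i], x$clusters$end_pct[i]))
    }
  } else {
    cat("  no suprathreshold clusters\n")
  }
  invisible(x)
}

#' Bonferroni-corrected family of paired-t comparisons
#'
#' Each comparison is tested with [pointwise_paired_t()] and
#' [spm_inference()] at per-comparison level
#' `alpha_family / n_comparisons`.
#'
#' @param comparisons named list; each element a list of two matched
#'   observation matrices `(y1, y2)`.
#' @param alpha_family family-wise error rate (default 0.05).
#' @return named list of `spm_result`, with attribute `alpha_per_comparison`.
#' @export
posthoc_paired_t_family <- function(comparisons, alpha_family = 0.05) {
  if (!length(comparisons)) stopf("comparisons must be non-empty")
  alpha_c <- alpha_family / length(comparisons)
  out <- lapply(comparisons, function(cmp) {
    spm_inference(pointwise_paired_t(cmp[[1L]], cmp[[2L]]), alpha = alpha_c)
  })
  attr(out, "alpha_per_comparison") <- alpha_c
  out
}
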