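# Per-landmark appearance models: normalised intensity-gradient profiles
# sampled perpendicular to the boundary, modelled as Gaussians per landmark
# per resolution level, scored by Mahalanobis distance.

#' Multiresolution image pyramid
#'
#' Level 1 is the input image; every further level is Gaussian-smoothed
#' (sigma 1 px) and decimated by 2 per axis (rows/columns 0, 2, 4, ...), so
#' a full-resolution coordinate c maps to c / 2^(L-1) at level L.
#'
#' @param image grayscale matrix.
#' @param n_levels number of levels (>= 1).
#' @return `image_pyramid`: list with `levels` (list of matrices) and
#'   `n_levels`.
#' @export
build_pyramid <- function(image, n_levels) {
  if (!is_count(n_levels)) stopf("n_levels must be >= 1")
  n_levels <- as.integer(n_levels)
  if (!is.matrix(image) || !nrow(image) || !ncol(image)) {
    stopf("image must be a non-empty matrix")
  }
  if (min(dim(image)) < 2^(n_levels - 1L)) {
    stopf("image of %d x %d px cannot support %d pyramid levels",
          nrow(image), ncol(image), n_levels)
  }
  levels <- vector("list", n_levels)
  levels[[1L]] <- image
  for (l in seq_len(n_levels - 1L)) {
    sm <- smooth_image(levels[[l]], sigma = 1)
    levels[[l + 1L]] <- sm[seq(1L, nrow(sm), by = 2L),
                           seq(1L, ncol(sm), by = 2L), drop = FALSE]
  }
  structure(list(levels = levels, n_levels = n_levels),
            class = "image_pyramid")
}

#' Unit normals at every landmark of a shape
#'
#' The normal at landmark i is perpendicular to the segment joining its
#' neighbours i-1 and i+1 on the same boundary (endpoints use their single
#' neighbour), with the sign chosen so the y (depth) component is
#' non-negative.
#'
#' @param shape an [apo_shape()].
#' @return `n x 2` matrix of unit normal vectors.
#' @export
shape_normals <- function(shape) {
  m <- unclass(shape)
  per <- points_per_boundary(shape)
  nb <- n_boundaries(shape)
  out <- matrix(0, nrow(m), 2L)
  for (b in seq_len(nb)) {
    idx <- (b - 1L) * per + seq_len(per)
    p <- m[idx, , drop = FALSE]
    lo <- pmax(seq_len(per) - 1L, 1L)
    hi <- pmin(seq_len(per) + 1L, per)
    tx <- p[hi, 1L] - p[lo, 1L]
    ty <- p[hi, 2L] - p[lo, 2L]
    nx <- -ty
    ny <- tx
    len <- sqrt(nx^2 + ny^2)
    if (any(len == 0)) stopf("degenerate (zero-length) tangent in boundary %d", b)
    nx <- nx / len
    ny <- ny / len
    flip <- ny < 0 | (ny == 0 & nx < 0)
    nx[flip] <- -nx[flip]
    ny[flip] <- -ny[flip]
    out[idx, ] <- cbind(nx, ny)
  }
  out
}

#' Normalised intensity-gradient profile at a point
#'
#' Samples image intensity by bilinear interpolation at `2k+3` unit-spaced
#' positions along the normal through `point`, takes central finite
#' differences to obtain `2k+1` gradient values, and normalises by the L1
#' norm of the gradient vector (an all-zero gradient stays all zero).
#'
#' @param image grayscale matrix.
#' @param point length-2 numeric `(x, y)`, 0-based pixels.
#' @param normal length-2 direction vector (normalised internally).
#' @param k half-length of the profile (default 2, giving 5 values).
#' @return numeric vector of length `2k+1`.
#' @export
sample_profile <- function(image, point, normal, k = 2L) {
  len <- sqrt(sum(normal^2))
  if (len == 0) stopf("normal vector must be nonzero")
  n <- normal / len
  j <- seq(-(k + 1L), k + 1L)
  s <- bilinear_sample(image, point[1L] + j * n[1L], point[2L] + j * n[2L])
  g <- (s[seq(3L, 2L * k + 3L)] - s[seq(1L, 2L * k + 1L)]) / 2
  l1 <- sum(abs(g))
  if (l1 > 0) g / l1 else g
}

# All candidate profiles for one landmark at integer offsets along its
# normal, as a matrix (length(offsets) x (2k+1)).  Vectorised inner loop of
# the ASM search.
profiles_at_offsets <- function(image, point, normal, k, offsets) {
  n <- normal / sqrt(sum(normal^2))
  j <- seq(-(k + 1L), k + 1L)
  d <- outer(offsets, j, "+")           # candidates x samples
  s <- bilinear_sample(image, point[1L] + d * n[1L], point[2L] + d * n[2L])
  s <- matrix(s, nrow = length(offsets))
  m <- 2L * k + 3L
  g <- (s[, seq(3L, m), drop = FALSE] - s[, seq(1L, m - 2L), drop = FALSE]) / 2
  l1 <- rowSums(abs(g))
  l1[l1 == 0] <- 1
  g / l1
}

#' Train Gaussian profile models for every landmark and level
#'
#' For each pyramid level and landmark, collects the normalised gradient
#' profiles over all training frames (landmark coordinates divided by
#' 2^(L-1) at level L; normal directions taken from the full-resolution
#' shape) and fits mean and sample covariance (n-1 denominator).  The
#' covariance is regularised by adding `reg_scale * mean(diag(cov))` (at
#' least 1e-10) to the diagonal so it is always positive definite.
#'
#' @param pyramids list of [build_pyramid()] objects, one per training frame,
#'   each with at least `n_levels` levels.
#' @param shapes list of [apo_shape()] truth/hand labels matching `pyramids`.
#' @param k profile half-length (default 2).
#' @param n_levels number of resolution levels to model.
#' @param reg_scale diagonal regularisation factor (default 1e-6).
#' @return `profile_models`: `levels[[L]][[i]]` holds `mean`, `cov`, `inv`
#'   and `eps` for landmark i at level L; plus `k`, `n_levels`, `n_points`.
#' @export
train_profile_models <- function(pyramids, shapes, k = 2L, n_levels = 4L,
                                 reg_scale = 1e-6) {
  if (length(pyramids) < 2L) stopf("at least 2 training frames are required")
  if (length(pyramids) != length(shapes)) {
    stopf("pyramids and shapes must have equal length")
  }
  if (any(vapply(pyramids, function(p) p$n_levels, integer(1)) < n_levels)) {
    stopf("every training pyramid needs at least %d levels", n_levels)
  }
  n_pts <- nrow(shapes[[1L]])
  d <- 2L * k + 1L
  levels <- vector("list", n_levels)
  for (lv in seq_len(n_levels)) {
    scale <- 2^(lv - 1L)
    # profiles[[i]]: training frames x d
    prof <- lapply(seq_len(n_pts), function(i) {
      matrix(0, length(pyramids), d)
    })
    for (f in seq_along(pyramids)) {
      img <- pyramids[[f]]$levels[[lv]]
      normals <- shape_normals(shapes[[f]])
      pts <- unclass(shapes[[f]]) / scale
      for (i in seq_len(n_pts)) {
        prof[[i]][f, ] <- sample_profile(img, pts[i, ], normals[i, ], k)
      }
    }
    levels[[lv]] <- lapply(prof, function(P) {
      mu <- colMeans(P)
      S <- stats::cov(P)
      eps <- max(reg_scale * mean(diag(S)), 1e-10)
      S <- S + diag(eps, d)
      inv <- tryCatch(chol2inv(chol(S)),
                      error = function(e) stopf(
                        "profile covariance not positive definite: %s",
                        conditionMessage(e)))
      list(mean = mu, cov = S, inv = inv, eps = eps)
    })
  }
  structure(list(levels = levels, k = as.integer(k),
                 n_levels = as.integer(n_levels), n_points = n_pts),
            class = "profile_models")
}

#' Squared Mahalanobis distance of a profile from a Gaussian model
#'
#' `d^2 = (g - mean)' Sigma^-1 (g - mean)`, proportional (up to constants)
#' to the negative log-likelihood under the Gaussian profile model.  A
#' non-positive-definite covariance is an error, never silently
#' pseudo-inverted.
#'
#' @param profile numeric vector.
#' @param mean model mean, same length.
#' @param cov model covariance matrix.
#' @return non-negative scalar.
#' @export
mahalanobis_d2 <- function(profile, mean, cov) {
  if (length(profile) != length(mean)) {
    stopf("profile and model dimensions disagree")
  }
  d <- profile - mean
  ch <- tryCatch(chol(cov), error = function(e) {
    stopf("covariance matrix is singular or not positive definite")
  })
  z <- backsolve(ch, d, transpose = TRUE)
  sum(z^2)
}
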