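# Point distribution model: PCA of landmark configurations in raw image
# coordinates (the transducer is fixed to the limb, so absolute position is
# informative and no Procrustes alignment is applied by default), plus
# projection into the plausible shape space with an SD limit on each mode
# coefficient.

#' Ordered aponeurosis landmark set for one frame
#'
#' Landmarks are stored as an `n x 2` matrix (columns `x`, `y`, 0-based
#' pixels) holding `n_boundaries` consecutive runs of equal length, ordered
#' superficial, middle, deep.  Within each boundary x must be strictly
#' increasing.
#'
#' @param landmarks numeric matrix `n x 2` (or object coercible to one).
#' @param frame_index 0-based frame index the labels belong to (optional).
#' @param n_boundaries number of boundaries (default 3).
#' @param check validate invariants (disable only for transient internal
#'   shapes mid-optimisation).
#' @return an `apo_shape` object.
#' @export
apo_shape <- function(landmarks, frame_index = NA_integer_,
                      n_boundaries = 3L, check = TRUE) {
  m <- as.matrix(landmarks)
  if (ncol(m) != 2L) stopf("landmarks must be an n x 2 matrix")
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y")
  if (nrow(m) %% n_boundaries != 0L) {
    stopf("landmark count %d is not a multiple of %d boundaries",
          nrow(m), n_boundaries)
  }
  per <- nrow(m) %/% n_boundaries
  if (check) {
    if (any(!is.finite(m))) stopf("landmarks must be finite")
    for (b in seq_len(n_boundaries)) {
      xs <- m[(b - 1L) * per + seq_len(per), 1L]
      if (any(diff(xs) <= 0)) {
        stopf("x must be strictly increasing within boundary %d", b)
      }
    }
  }
  structure(m, frame_index = frame_index, n_boundaries = n_boundaries,
            class = c("apo_shape", "matrix", "array"))
}

n_boundaries <- function(shape) attr(shape, "n_boundaries") %||% 3L

points_per_boundary <- function(shape) nrow(shape) %/% n_boundaries(shape)

#' Extract the landmarks of one boundary
#' @param shape an [apo_shape()].
#' @param id boundary index: 1 superficial, 2 middle, 3 deep.
#' @return matrix of that boundary's landmarks.
#' @export
boundary_landmarks <- function(shape, id) {
  per <- points_per_boundary(shape)
  unclass(shape)[(id - 1L) * per + seq_len(per), , drop = FALSE]
}

# Shape <-> vector packing: all x coordinates, then all y coordinates.
shape_to_vec <- function(shape) as.vector(unclass(shape))

vec_to_shape <- function(v, template, check = FALSE) {
  apo_shape(matrix(v, ncol = 2L),
            frame_index = attr(template, "frame_index"),
            n_boundaries = n_boundaries(template), check = check)
}

#' Build a point distribution model from training shapes
#'
#' Computes the mean shape and the eigendecomposition of the sample
#' covariance (n-1 denominator) of the stacked shape vectors, retaining the
#' minimal number of leading modes whose cumulative eigenvalue fraction
#' reaches `variance_target`.
#'
#' @param training_shapes list of [apo_shape()] objects with identical
#'   landmark counts (>= 2 shapes).
#' @param variance_target fraction of total variance to retain
#'   (default 0.985).
#' @return a `pdm` object: `mean_shape` (vector), `modes` (matrix, columns =
#'   orthonormal eigenvectors), `mode_variances` (eigenvalues, px^2),
#'   `variance_retained` (achieved fraction), `n_training`.
#' @export
build_pdm <- function(training_shapes, variance_target = 0.985) {
  if (length(training_shapes) < 2L) {
    stopf("at least 2 training shapes are required")
  }
  if (!is_number(variance_target) || variance_target <= 0 ||
      variance_target > 1) {
    stopf("variance_target must lie in (0, 1]")
  }
  sizes <- vapply(training_shapes, nrow, integer(1))
  if (length(unique(sizes)) != 1L) {
    stopf("training shapes have inconsistent landmark counts")
  }
  X <- t(vapply(training_shapes, shape_to_vec,
                numeric(2L * sizes[1L])))
  mu <- colMeans(X)
  S <- stats::cov(X)
  eig <- eigen(S, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  total <- sum(lam)
  if (total <= 1e-12 * length(lam)) {
    n_modes <- 0L
    achieved <- 0
  } else {
    frac <- cumsum(lam) / total
    n_modes <- which(frac >= variance_target - 1e-12)[1L]
    achieved <- frac[n_modes]
  }
  structure(list(
    mean_shape = mu,
    modes = eig$vectors[, seq_len(n_modes), drop = FALSE],
    mode_variances = lam[seq_len(n_modes)],
    variance_retained = achieved,
    variance_target = variance_target,
    n_training = nrow(X),
    n_points = sizes[1L],
    n_boundaries = n_boundaries(training_shapes[[1L]])),
    class = "pdm")
}

#' @export
print.pdm <- function(x, ...) {
  cat(sprintf(
    "pdm: %d landmarks, %d modes retaining %.2f%% variance (%d shapes)\n",
    x$n_points, ncol(x$modes), 100 * x$variance_retained, x$n_training))
  invisible(x)
}

pdm_template <- function(pdm) {
  apo_shape(matrix(pdm$mean_shape, ncol = 2L),
            n_boundaries = pdm$n_boundaries, check = FALSE)
}

#' Mode coefficients of a shape
#'
#' Projects `shape - mean` onto the retained modes:
#' `b = t(modes) %*% (s - mean)`.
#' @param shape an [apo_shape()] with the model's landmark count.
#' @param pdm a [build_pdm()] model.
#' @return numeric coefficient vector, one entry per retained mode.
#' @export
params_from_shape <- function(shape, pdm) {
  v <- shape_to_vec(shape)
  if (length(v) != length(pdm$mean_shape)) {
    stopf("shape has %d coordinates but the model expects %d",
          length(v), length(pdm$mean_shape))
  }
  as.numeric(crossprod(pdm$modes, v - pdm$mean_shape))
}

#' Reconstruct a shape from mode coefficients
#' @param b coefficient vector (one per retained mode).
#' @param pdm a [build_pdm()] model.
#' @return an [apo_shape()].
#' @export
shape_from_params <- function(b, pdm) {
  if (length(b) != ncol(pdm$modes)) {
    stopf("expected %d coefficients, got %d", ncol(pdm$modes), length(b))
  }
  v <- pdm$mean_shape + as.numeric(pdm$modes %*% b)
  vec_to_shape(v, pdm_template(pdm))
}

#' Nearest plausible shape under the SD limit
#'
#' Projects the shape into the retained subspace and clips every mode
#' coefficient to `[-sd_limit * sqrt(lambda_i), +sd_limit * sqrt(lambda_i)]`.
#' Idempotent; never increases any coefficient magnitude.
#'
#' @param shape an [apo_shape()].
#' @param pdm a [build_pdm()] model.
#' @param sd_limit allowed multiple of each mode's standard deviation
#'   (default 3).
#' @return the constrained [apo_shape()].
#' @export
project_to_plausible <- function(shape, pdm, sd_limit = 3) {
  if (!is_number(sd_limit) || sd_limit <= 0) stopf("sd_limit must be > 0")
  if (ncol(pdm$modes) == 0L) {
    return(vec_to_shape(pdm$mean_shape, pdm_template(pdm)))
  }
  b <- params_from_shape(shape, pdm)
  lim <- sd_limit * sqrt(pdm$mode_variances)
  shape_from_params(pmin(pmax(b, -lim), lim), pdm)
}
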