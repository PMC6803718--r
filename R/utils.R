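# Shared internal helpers: seeded evaluation, separable Gaussian smoothing,
# bilinear image sampling.  All image code uses 0-based pixel coordinates,
# x = column, y = row (depth, increasing downward), origin at the top-left
# pixel centre; an image is a numeric matrix [height x width] in [0, 1].

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generators do not
#' perturb an enclosing simulation.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Normalised Gaussian kernel with radius 3*sigma (minimum 1 sample each side).
gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# 1D convolution along the row index with replicate (clamp-to-edge) padding.
conv_rows <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  idx <- c(rep(1L, r), seq_len(n), rep(n, r))
  p <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (i in seq_along(k)) {
    out <- out + k[i] * p[i:(i + n - 1L), , drop = FALSE]
  }
  out
}

# Separable Gaussian smoothing of an image matrix.
smooth_image <- function(img, sigma = 1) {
  k <- gaussian_kernel(sigma)
  t(conv_rows(t(conv_rows(img, k)), k))
}

#' Bilinear interpolation of image intensities
#'
#' Samples a grayscale image at fractional pixel positions.  Coordinates are
#' 0-based (x = column, y = row); positions outside the image are clamped to
#' the nearest edge pixel.
#' @param img numeric matrix, rows = depth (y), columns = lateral position (x).
#' @param x,y coordinate vectors of equal length.
#' @return numeric vector of interpolated intensities.
#' @export
bilinear_sample <- function(img, x, y) {
  h <- nrow(img)
  w <- ncol(img)
  x <- pmin(pmax(as.vector(x), 0), w - 1)
  y <- pmin(pmax(as.vector(y), 0), h - 1)
  x0 <- pmin(floor(x), max(w - 2L, 0L))
  y0 <- pmin(floor(y), max(h - 2L, 0L))
  fx <- x - x0
  fy <- y - y0
  x1 <- pmin(x0 + 1L, w - 1L)
  y1 <- pmin(y0 + 1L, h - 1L)
  i00 <- img[cbind(y0 + 1L, x0 + 1L)]
  i01 <- img[cbind(y0 + 1L, x1 + 1L)]
  i10 <- img[cbind(y1 + 1L, x0 + 1L)]
  i11 <- img[cbind(y1 + 1L, x1 + 1L)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= min
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)
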