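# Multiresolution active-shape-model search: per-landmark Mahalanobis
# minimisation along the boundary normal, alternated with projection into
# the plausible shape space, coarse to fine; frame-to-frame propagation and
# the two-start initialisation of the first frame.

#' ASM search configuration
#'
#' @param search_range candidate offsets per iteration, +/- pixels along the
#'   normal at the current level (default 5).
#' @param max_iterations iteration cap per resolution level (default 10).
#' @param convergence_fraction stop a level once this fraction of landmarks
#'   moved less than 1 level-pixel (default 0.9).
#' @param n_levels_track pyramid levels used when tracking from the previous
#'   frame (default 4: full resolution plus three lower).
#' @param n_levels_init levels for the first-frame search (default 5; two
#'   extra coarse levels permit large initial adjustments).
#' @param sd_limit plausibility limit, SD multiples per mode (default 3).
#' @param k profile half-length (must match the trained models).
#' @return a `search_config` object.
#' @export
search_config <- function(search_range = 5L, max_iterations = 10L,
                          convergence_fraction = 0.9, n_levels_track = 4L,
                          n_levels_init = 5L, sd_limit = 3, k = 2L) {
  stopifnot(is_count(search_range), is_count(max_iterations),
            is_number(convergence_fraction), convergence_fraction > 0,
            convergence_fraction <= 1, is_count(n_levels_track),
            is_count(n_levels_init), is_number(sd_limit), sd_limit > 0,
            is_count(k))
  if (n_levels_init < n_levels_track) {
    stopf("n_levels_init must be >= n_levels_track")
  }
  structure(list(search_range = as.integer(search_range),
                 max_iterations = as.integer(max_iterations),
                 convergence_fraction = convergence_fraction,
                 n_levels_track = as.integer(n_levels_track),
                 n_levels_init = as.integer(n_levels_init),
                 sd_limit = sd_limit, k = as.integer(k)),
            class = "search_config")
}

#' Best landmark position along its normal
#'
#' Evaluates the normalised gradient profile at every integer offset in
#' `-search_range ... +search_range` along the (unit) normal and returns the
#' candidate minimising the squared Mahalanobis distance under the landmark's
#' profile model.  Ties break toward smaller |offset|, then toward the
#' negative offset.  A start point outside the image is left unmoved and
#' flagged.
#'
#' @param image image matrix at the current pyramid level.
#' @param point length-2 `(x, y)` at the current level, 0-based px.
#' @param normal length-2 direction vector.
#' @param model profile model (`mean`, `inv`) for this landmark and level.
#' @param search_range max |offset| in level pixels.
#' @param k profile half-length.
#' @return list: `point` (updated), `offset`, `d2` (score at the chosen
#'   offset), `flag` (TRUE if the landmark could not be searched).
#' @export
search_landmark <- function(image, point, normal, model, search_range = 5L,
                            k = 2L) {
  h <- nrow(image)
  w <- ncol(image)
  if (point[1L] < 0 || point[1L] > w - 1L ||
      point[2L] < 0 || point[2L] > h - 1L) {
    return(list(point = point, offset = 0L, d2 = NA_real_, flag = TRUE))
  }
  offs <- seq(-search_range, search_range)
  G <- profiles_at_offsets(image, point, normal, k, offs)
  D <- sweep(G, 2L, model$mean)
  d2 <- rowSums((D %*% model$inv) * D)
  best <- order(d2, abs(offs), offs)[1L]
  n <- normal / sqrt(sum(normal^2))
  list(point = point + offs[best] * n, offset = offs[best],
       d2 = d2[best], flag = FALSE)
}

#' Fit one frame with the multiresolution ASM
#'
#' For each resolution level, coarsest first: repeatedly move every landmark
#' to its Mahalanobis-optimal position along the normal
#' ([search_landmark()]), then constrain the whole 57-landmark configuration
#' with [project_to_plausible()]; a level stops when `convergence_fraction`
#' of the landmarks moved by less than one level-pixel, or after
#' `max_iterations`.  Poor fits are reported through the quality fields,
#' never as errors.
#'
#' @param pyramid an [build_pyramid()] of the frame with at least `n_levels`
#'   levels.
#' @param init_shape starting [apo_shape()] in full-resolution coordinates.
#' @param models trained [train_profile_models()] covering `n_levels`.
#' @param pdm the [build_pdm()] shape model.
#' @param config a [search_config()].
#' @param n_levels levels to use (default `config$n_levels_track`).
#' @return `frame_fit`: `shape`, `total_mahalanobis` (finest level),
#'   `level_scores` (summed d2 per level, index 1 = finest),
#'   `n_iterations`, `converged`, `n_flagged`.
#' @export
fit_frame <- function(pyramid, init_shape, models, pdm, config = search_config(),
                      n_levels = NULL) {
  n_levels <- n_levels %||% config$n_levels_track
  if (pyramid$n_levels < n_levels || models$n_levels < n_levels) {
    stopf("pyramid/models provide fewer than %d levels", n_levels)
  }
  shape <- apo_shape(unclass(init_shape), n_boundaries = n_boundaries(init_shape),
                     check = FALSE)
  n_pts <- nrow(shape)
  level_scores <- numeric(n_levels)
  total_iter <- 0L
  n_flagged <- 0L
  converged <- TRUE
  for (lv in seq(n_levels, 1L)) {
    scale <- 2^(lv - 1L)
    img <- pyramid$levels[[lv]]
    lv_models <- models$levels[[lv]]
    lv_converged <- FALSE
    d2 <- numeric(n_pts)
    for (it in seq_len(config$max_iterations)) {
      total_iter <- total_iter + 1L
      normals <- shape_normals(shape)
      pts <- unclass(shape) / scale
      new_pts <- pts
      for (i in seq_len(n_pts)) {
        res <- search_landmark(img, pts[i, ], normals[i, ], lv_models[[i]],
                               config$search_range, config$k)
        new_pts[i, ] <- res$point
        d2[i] <- if (is.na(res$d2)) 0 else res$d2
        if (res$flag) n_flagged <- n_flagged + 1L
      }
      cand <- apo_shape(new_pts * scale, n_boundaries = n_boundaries(shape),
                        check = FALSE)
      proj <- project_to_plausible(cand, pdm, config$sd_limit)
      moved <- sqrt(rowSums((unclass(proj) / scale - pts)^2))
      shape <- proj
      if (mean(moved < 1) >= config$convergence_fraction) {
        lv_converged <- TRUE
        break
      }
    }
    if (!lv_converged) converged <- FALSE
    level_scores[lv] <- sum(d2)
  }
  structure(list(shape = shape, total_mahalanobis = level_scores[1L],
                 level_scores = level_scores, n_iterations = total_iter,
                 converged = converged, n_flagged = n_flagged),
            class = "frame_fit")
}

#' @export
print.frame_fit <- function(x, ...) {
  cat(sprintf(
    "frame_fit: d2 = %.3f at full resolution, %d iterations, converged = %s\n",
    x$total_mahalanobis, x$n_iterations, x$converged))
  invisible(x)
}

#' First-frame initialisation by two-start search
#'
#' Runs [fit_frame()] over `config$n_levels_init` levels from each of the
#' two supplied trial mean shapes and keeps the result with the lowest
#' Mahalanobis distance accumulated over all landmarks and all resolution
#' levels (ties go to the first candidate).
#'
#' @param pyramid frame pyramid with `n_levels_init` levels.
#' @param pdm the shape model.
#' @param trial_mean_shapes list of exactly two candidate mean shapes, one
#'   per hand-labelled training trial.
#' @param models trained profile models covering `n_levels_init` levels.
#' @param config a [search_config()].
#' @return the selected `frame_fit`, with attributes `candidate_scores`
#'   (accumulated d2 per start) and `selected` (index of the winner).
#' @export
initialize_first_frame <- function(pyramid, pdm, trial_mean_shapes, models,
                                   config = search_config()) {
  if (length(trial_mean_shapes) != 2L) {
    stopf("exactly two trial mean shapes are required")
  }
  fits <- lapply(trial_mean_shapes, function(s) {
    fit_frame(pyramid, s, models, pdm, config,
              n_levels = config$n_levels_init)
  })
  scores <- vapply(fits, function(f) sum(f$level_scores), numeric(1))
  sel <- which.min(scores)   # ties -> first
  out <- fits[[sel]]
  attr(out, "candidate_scores") <- scores
  attr(out, "selected") <- sel
  out
}

#' Track a full image sequence
#'
#' Frame 1 is segmented by [initialize_first_frame()] (5 levels by default);
#' every later frame is segmented by [fit_frame()] initialised with the
#' previous frame's fit (identity motion prior) over `n_levels_track`
#' levels.  Unconverged frames are flagged in their `frame_fit`, never
#' fatal.
#'
#' @param frames list of image matrices (one sequence).
#' @param pdm shape model.
#' @param models profile models (must cover `n_levels_init` levels).
#' @param config a [search_config()].
#' @param trial_mean_shapes two starting shapes for the first frame.
#' @return list of `frame_fit`, one per frame.
#' @export
track_sequence <- function(frames, pdm, models, config = search_config(),
                           trial_mean_shapes = NULL) {
  if (!length(frames)) stopf("at least one frame is required")
  if (is.null(trial_mean_shapes)) {
    m <- vec_to_shape(pdm$mean_shape, pdm_template(pdm))
    trial_mean_shapes <- list(m, m)
  }
  fits <- vector("list", length(frames))
  pyr <- build_pyramid(frames[[1L]], config$n_levels_init)
  fits[[1L]] <- initialize_first_frame(pyr, pdm, trial_mean_shapes, models,
                                       config)
  for (f in seq_along(frames)[-1L]) {
    pyr <- build_pyramid(frames[[f]], config$n_levels_track)
    fits[[f]] <- fit_frame(pyr, fits[[f - 1L]]$shape, models, pdm, config)
  }
  fits
}
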