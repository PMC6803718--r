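# Thickness pipeline: boundary interpolation, 20-site vertical thickness,
# stride segmentation from vertical GRF, 200-node time normalisation, and
# quiet-standing baseline subtraction.  "Vertical" thickness is measured
# along the image depth axis, not perpendicular to the boundary.

#' Muscle to boundary-pair lookup
#'
#' In the gastrocnemius view the muscle lies between the superficial (1) and
#' middle (2) boundaries; soleus lies between the middle (2) and deep (3)
#' boundaries.  MG and LG use the same pair in their respective views.
#' @return named list muscle -> c(superficial id, deep id).
#' @export
default_boundary_map <- function() {
  list(MG = c(1L, 2L), LG = c(1L, 2L), SO = c(2L, 3L))
}

#' Monotone piecewise-cubic interpolation of a boundary
#'
#' Depth as a function of lateral position through the fitted landmarks
#' (Fritsch-Carlson monotone Hermite cubic); passes exactly through every
#' landmark.  Extrapolation beyond the landmark span is refused.
#'
#' @param landmarks `n x 2` matrix (x, depth) with strictly increasing x.
#' @param query_x positions at which to evaluate, px.
#' @return depth values at `query_x`, px.
#' @export
interpolate_boundary <- function(landmarks, query_x) {
  landmarks <- as.matrix(landmarks)
  x <- landmarks[, 1L]
  if (any(query_x < min(x) - 1e-9) || any(query_x > max(x) + 1e-9)) {
    stopf("query_x outside the landmark span [%g, %g]; extrapolation refused",
          min(x), max(x))
  }
  f <- stats::splinefun(x, landmarks[, 2L], method = "monoH.FC")
  f(pmin(pmax(query_x, min(x)), max(x)))
}

#' Muscle thickness at equally spaced sites
#'
#' Places `n_sites` x-positions equally over the common lateral span of the
#' muscle's two bounding aponeuroses and returns the vertical distance
#' between the interpolated deep and superficial boundaries at each site,
#' in mm, with their arithmetic mean appended.  Negative thickness (boundary
#' crossing) is flagged, with the values retained for inspection.
#'
#' @param shape a fitted [apo_shape()].
#' @param muscle one of the names in `boundary_map` (e.g. "SO", "MG", "LG").
#' @param boundary_map see [default_boundary_map()].
#' @param n_sites number of evaluation sites (default 20).
#' @param pixel_pitch mm per pixel.
#' @return list: `site_x` (px), `site_thickness` (mm, length `n_sites`),
#'   `mean_thickness` (mm), `crossing` (flag).
#' @export
compute_thickness <- function(shape, muscle,
                              boundary_map = default_boundary_map(),
                              n_sites = 20L, pixel_pitch = 2.75 / 32) {
  ids <- boundary_map[[muscle]]
  if (is.null(ids)) stopf("unknown muscle '%s'", muscle)
  sup <- boundary_landmarks(shape, ids[1L])
  deep <- boundary_landmarks(shape, ids[2L])
  lo <- max(min(sup[, 1L]), min(deep[, 1L]))
  hi <- min(max(sup[, 1L]), max(deep[, 1L]))
  sites <- seq(lo, hi, length.out = n_sites)
  th_px <- interpolate_boundary(deep, sites) - interpolate_boundary(sup, sites)
  th_mm <- th_px * pixel_pitch
  list(site_x = sites, site_thickness = th_mm,
       mean_thickness = mean(th_mm), crossing = any(th_px < 0))
}

#' Per-frame thickness series for one muscle
#'
#' Applies [compute_thickness()] to every frame fit of a tracked sequence.
#'
#' @param fits list of `frame_fit` (or of [apo_shape()]).
#' @param muscle,boundary_map,n_sites,pixel_pitch see [compute_thickness()].
#' @param frame_times frame timestamps, s.
#' @return `thickness_series`: `muscle`, `site_thickness` (frames x sites,
#'   mm), `mean_thickness` (per frame), `site_x`, `pixel_pitch`,
#'   `frame_times`, `crossing` (per-frame flags).
#' @export
compute_thickness_series <- function(fits, muscle,
                                     boundary_map = default_boundary_map(),
                                     n_sites = 20L, pixel_pitch = 2.75 / 32,
                                     frame_times = NULL) {
  shapes <- lapply(fits, function(f) if (inherits(f, "frame_fit")) f$shape else f)
  per <- lapply(shapes, compute_thickness, muscle = muscle,
                boundary_map = boundary_map, n_sites = n_sites,
                pixel_pitch = pixel_pitch)
  st <- do.call(rbind, lapply(per, `[[`, "site_thickness"))
  structure(list(
    muscle = muscle, site_thickness = st,
    mean_thickness = rowMeans(st),
    site_x = per[[1L]]$site_x, pixel_pitch = pixel_pitch,
    frame_times = frame_times %||% (seq_along(shapes) - 1),
    crossing = vapply(per, `[[`, logical(1), "crossing")),
    class = "thickness_series")
}

#' @export
print.thickness_series <- function(x, ...) {
  cat(sprintf("thickness_series: %s, %d frames x %d sites, mean %.2f mm\n",
              x$muscle, nrow(x$site_thickness), ncol(x$site_thickness),
              mean(x$mean_thickness)))
  invisible(x)
}

#' Detect stride windows from a vertical GRF trace
#'
#' A foot strike is an upward crossing of `force_threshold` preceded by at
#' least `debounce` seconds below threshold; a stride is the half-open
#' interval between consecutive strikes.  The first `n_strides` consecutive
#' strides are returned.
#'
#' @param grf a `grf_trace` (see [generate_grf()]) or list with `time` and
#'   `vertical_force`.
#' @param force_threshold N (default 20).
#' @param n_strides number of strides wanted (default 4).
#' @param debounce minimum off-ground time before a new strike, s
#'   (default 0.05).
#' @return data.frame with `start` and `end` times (s), one row per stride;
#'   attribute `strikes` holds all detected strike times.
#' @export
detect_strides <- function(grf, force_threshold = 20, n_strides = 4L,
                           debounce = 0.05) {
  f <- grf$vertical_force
  t <- grf$time
  n <- length(f)
  above <- f >= force_threshold
  cross <- which(above & !c(FALSE, above[-n]))
  if (length(cross)) {
    # index of the most recent above-threshold sample before each position
    last_above <- cummax(ifelse(above, seq_len(n), 0L))
    keep <- vapply(cross, function(i) {
      la <- if (i > 1L) last_above[i - 1L] else 0L
      la == 0L || (t[i] - t[la]) >= debounce
    }, logical(1))
    cross <- cross[keep]
  }
  strikes <- t[cross]
  if (length(strikes) < n_strides + 1L) {
    stopf("insufficient strikes: found %d, need %d for %d strides",
          length(strikes), n_strides + 1L, n_strides)
  }
  out <- data.frame(start = strikes[seq_len(n_strides)],
                    end = strikes[seq_len(n_strides) + 1L])
  attr(out, "strikes") <- strikes
  out
}

#' Time-normalise a thickness series to one stride
#'
#' Linearly interpolates frame-wise values onto `n_nodes` equally spaced
#' time points spanning the half-open stride window: node i sits at
#' `start + i * (end - start) / n_nodes`, i = 0 ... n_nodes-1, so node 0 is
#' the strike and the last node stops one step short of the next strike.
#'
#' @param values per-frame vector, or matrix frames x series (e.g. sites).
#' @param times frame timestamps, s.
#' @param window list/row with `start` and `end` (s).
#' @param n_nodes nodes per stride (default 200; node i = i/2 % stride).
#' @return vector (or matrix `n_nodes` x series) of interpolated values.
#' @export
normalize_stride <- function(values, times, window, n_nodes = 200L) {
  v <- if (is.matrix(values)) values else matrix(values, ncol = 1L)
  if (window$end <= window$start) stopf("empty stride window")
  inside <- sum(times >= window$start & times < window$end)
  if (inside < 2L) stopf("fewer than 2 frames fall inside the stride window")
  xout <- window$start +
    (seq_len(n_nodes) - 1L) * (window$end - window$start) / n_nodes
  out <- apply(v, 2L, function(col) {
    stats::approx(times, col, xout = xout, rule = 2)$y
  })
  if (is.matrix(values)) out else drop(out)
}

#' Subtract the quiet-standing baseline
#'
#' @param normalized nodes x sites matrix (or vector) of trial thickness, mm.
#' @param standing_thickness per-site standing thickness, mm (one value per
#'   column of `normalized`).
#' @return thickness change, same shape as `normalized`.
#' @export
subtract_baseline <- function(normalized, standing_thickness) {
  m <- if (is.matrix(normalized)) normalized else matrix(normalized, ncol = 1L)
  if (ncol(m) != length(standing_thickness)) {
    stopf("site count mismatch: %d columns vs %d standing values",
          ncol(m), length(standing_thickness))
  }
  out <- sweep(m, 2L, standing_thickness)
  if (is.matrix(normalized)) out else drop(out)
}

#' Per-site standing thickness from a quiet-standing trial
#'
#' Mean over the standing trial's frames, per site, with the mean-site value
#' appended last.
#' @param series a [compute_thickness_series()] of the standing trial.
#' @return numeric vector of length `n_sites + 1`.
#' @export
standing_baseline <- function(series) {
  c(colMeans(series$site_thickness), mean = mean(series$mean_thickness))
}

#' Stride-normalised thickness change for one trial and muscle
#'
#' Chains [detect_strides()], [normalize_stride()] and [subtract_baseline()]
#' over the 20 sites plus the mean.
#'
#' @param series trial [compute_thickness_series()].
#' @param grf the trial's `grf_trace`.
#' @param standing per-site + mean standing thickness
#'   ([standing_baseline()]).
#' @param n_strides,n_nodes defaults 4 strides, 200 nodes.
#' @param force_threshold,debounce see [detect_strides()].
#' @return `stride_thickness`: `change` (array strides x nodes x
#'   (sites+mean)), `thickness` (same, before subtraction), `windows`,
#'   `muscle`, `site_labels`.
#' @export
stride_normalized_thickness <- function(series, grf, standing,
                                        n_strides = 4L, n_nodes = 200L,
                                        force_threshold = 20,
                                        debounce = 0.05) {
  windows <- detect_strides(grf, force_threshold, n_strides, debounce)
  vals <- cbind(series$site_thickness, mean = series$mean_thickness)
  if (ncol(vals) != length(standing)) {
    stopf("standing baseline has %d sites, trial has %d",
          length(standing), ncol(vals))
  }
  n_series <- ncol(vals)
  th <- array(NA_real_, c(n_strides, n_nodes, n_series))
  ch <- th
  for (s in seq_len(n_strides)) {
    norm <- normalize_stride(vals, series$frame_times, windows[s, ], n_nodes)
    th[s, , ] <- norm
    ch[s, , ] <- subtract_baseline(norm, standing)
  }
  site_labels <- c(as.character(seq_len(n_series - 1L)), "mean")
  structure(list(change = ch, thickness = th, windows = windows,
                 muscle = series$muscle, site_labels = site_labels,
                 n_nodes = n_nodes),
            class = "stride_thickness")
}
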