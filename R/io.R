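# Readers and writers: PGM image stacks with a JSON sidecar, GRF CSV,
# landmark label JSON, model archives (PDM + profile models) as JSON,
# long-format thickness CSV, and SPM result JSON.  All round-trip tested.

#' Write a grayscale image as PGM
#'
#' Intensities in \[0, 1\] are scaled to the requested bit depth.  P5
#' (binary) by default; P2 writes plain ASCII.
#' @param img matrix in \[0, 1\].
#' @param path output file.
#' @param bits 8 or 16.
#' @param ascii write plain-text P2 instead of binary P5.
#' @export
write_pgm <- function(img, path, bits = 16L, ascii = FALSE) {
  if (!bits %in% c(8L, 16L)) stopf("bits must be 8 or 16")
  maxval <- 2L^bits - 1L
  q <- round(pmin(pmax(img, 0), 1) * maxval)
  # PGM raster order: rows top to bottom, columns left to right
  vals <- as.integer(t(q))
  header <- sprintf("%s\n%d %d\n%d\n", if (ascii) "P2" else "P5",
                    ncol(img), nrow(img), maxval)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sub("\n$", "", header), con)
    writeLines(paste(vals, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(header, con, eos = NULL)
    if (bits == 8L) {
      writeBin(as.raw(vals), con)
    } else {
      writeBin(as.integer(vals), con, size = 2L, endian = "big")
    }
  }
  invisible(path)
}

#' Read a PGM image
#'
#' Supports P2 (ASCII) and P5 (binary), 8- and 16-bit; returns intensities
#' normalised to \[0, 1\] so physical content is bit-depth independent.
#' @param path PGM file.
#' @return numeric matrix in \[0, 1\].
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch) || ch == "") stopf("truncated PGM header")
      if (ch == "#") {               # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (!length(ch) || ch %in% c("\n", "")) break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok)
      } else {
        tok <- paste0(tok, ch)
      }
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) stopf("not a PGM file: %s", path)
  w <- as.integer(read_token())
  h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  n <- w * h
  vals <- if (magic == "P2") {
    scan(con, what = integer(), n = n, quiet = TRUE)
  } else if (maxval < 256L) {
    as.integer(readBin(con, "raw", n = n))
  } else {
    readBin(con, "integer", n = n, size = 2L, signed = FALSE,
            endian = "big")
  }
  if (length(vals) != n) stopf("truncated PGM raster in %s", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxval
}

#' Write an image sequence as a PGM stack with a JSON sidecar
#'
#' @param seq a `phantom_sequence`, or a list of image matrices.
#' @param dir output directory (created).
#' @param bits PGM bit depth (default 16, lossless to ~1.5e-5 intensity).
#' @param pixel_pitch mm/px recorded in the sidecar (taken from a phantom's
#'   config when available).
#' @export
write_image_sequence <- function(seq, dir, bits = 16L, pixel_pitch = NULL) {
  frames <- if (inherits(seq, "phantom_sequence")) seq$frames else seq
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(frames)) {
    write_pgm(frames[[i]], file.path(dir, sprintf("frame_%04d.pgm", i - 1L)),
              bits = bits)
  }
  meta <- list(n_frames = length(frames),
               pixel_pitch = pixel_pitch %||%
                 (if (inherits(seq, "phantom_sequence"))
                    seq$config$pixel_pitch else NULL))
  if (inherits(seq, "phantom_sequence")) {
    meta$truth <- lapply(seq$truth_shapes, function(s) {
      unname(as.matrix(unclass(s)))
    })
    cfg <- seq$config
    cfg$boundaries <- lapply(cfg$boundaries, unclass)
    meta$config <- unclass(cfg)
  }
  jsonlite::write_json(meta, file.path(dir, "sequence.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an image sequence from a PGM directory
#'
#' @param path directory of `*.pgm` frames (read in lexicographic order)
#'   with optional `sequence.json` sidecar.
#' @param pixel_pitch override/provide mm per pixel.
#' @return list: `frames`, `pixel_pitch`, `truth` (list of [apo_shape()] or
#'   NULL), `meta`.
#' @export
read_image_sequence <- function(path, pixel_pitch = NULL) {
  if (!dir.exists(path)) stopf("no such directory: %s", path)
  files <- sort(list.files(path, pattern = "\\.pgm$", full.names = TRUE))
  if (!length(files)) stopf("no PGM frames found in %s", path)
  frames <- lapply(files, read_pgm)
  meta <- NULL
  sidecar <- file.path(path, "sequence.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  truth <- NULL
  if (!is.null(meta$truth)) {
    tr <- meta$truth
    truth <- if (is.array(tr) && length(dim(tr)) == 3L) {
      lapply(seq_len(dim(tr)[1L]), function(i) {
        apo_shape(tr[i, , ], frame_index = i - 1L)
      })
    } else {
      lapply(seq_along(tr), function(i) {
        apo_shape(tr[[i]], frame_index = i - 1L)
      })
    }
  }
  list(frames = frames,
       pixel_pitch = pixel_pitch %||% meta$pixel_pitch,
       truth = truth, meta = meta)
}

#' Write/read a GRF trace as two-column CSV (time_s, force_N)
#' @param grf a `grf_trace`.
#' @param path CSV file.
#' @export
write_grf_csv <- function(grf, path) {
  utils::write.csv(data.frame(time_s = grf$time,
                              force_N = grf$vertical_force),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grf_csv
#' @param sampling_rate Hz; inferred from the time column when omitted.
#' @export
read_grf_csv <- function(path, sampling_rate = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "force_N") %in% names(d))) {
    stopf("GRF CSV must have columns time_s, force_N")
  }
  structure(list(time = d$time_s, vertical_force = d$force_N,
                 sampling_rate = sampling_rate %||%
                   (1 / stats::median(diff(d$time_s))),
                 true_event_times = NULL),
            class = "grf_trace")
}

#' Write/read landmark labels as JSON (frame index -> n x 2 array)
#' @param shapes named or indexed list of [apo_shape()]; names default to
#'   0-based frame indices.
#' @param path JSON file.
#' @export
write_labels_json <- function(shapes, path) {
  obj <- lapply(shapes, function(s) unname(as.matrix(unclass(s))))
  names(obj) <- names(shapes) %||%
    vapply(shapes, function(s) {
      as.character(attr(s, "frame_index") %||% NA_integer_)
    }, character(1))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_labels_json
#' @export
read_labels_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(stats::setNames(seq_along(obj), names(obj)), function(i) {
    apo_shape(obj[[i]], frame_index = suppressWarnings(
      as.integer(names(obj)[i])))
  })
}

#' Serialize PDM + profile models to one JSON archive
#' @param pdm a [build_pdm()] model.
#' @param models a [train_profile_models()] set.
#' @param path output `.json` file.
#' @export
write_model_archive <- function(pdm, models, path) {
  obj <- list(
    schema = "apotrack-model/1",
    pdm = list(mean_shape = pdm$mean_shape, modes = pdm$modes,
               mode_variances = pdm$mode_variances,
               variance_retained = pdm$variance_retained,
               variance_target = pdm$variance_target,
               n_training = pdm$n_training, n_points = pdm$n_points,
               n_boundaries = pdm$n_boundaries),
    profiles = list(k = models$k, n_levels = models$n_levels,
                    n_points = models$n_points,
                    levels = lapply(models$levels, function(lv) {
                      lapply(lv, function(m) {
                        list(mean = m$mean, cov = m$cov, eps = m$eps)
                      })
                    })))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_archive
#' @return list with elements `pdm` and `models`.
#' @export
read_model_archive <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  p <- obj$pdm
  mean_shape <- unlist(p$mean_shape)
  # matrices were written row-major (array of rows)
  modes <- do.call(rbind, lapply(p$modes, unlist))
  if (is.null(modes)) modes <- matrix(0, length(mean_shape), 0L)
  pdm <- structure(list(
    mean_shape = mean_shape,
    modes = modes,
    mode_variances = as.numeric(unlist(p$mode_variances)),
    variance_retained = p$variance_retained,
    variance_target = p$variance_target,
    n_training = p$n_training, n_points = p$n_points,
    n_boundaries = p$n_boundaries), class = "pdm")
  q <- obj$profiles
  levels <- lapply(q$levels, function(lv) {
    lapply(lv, function(m) {
      cov <- do.call(rbind, lapply(m$cov, unlist))
      list(mean = as.numeric(unlist(m$mean)), cov = cov,
           inv = chol2inv(chol(cov)), eps = m$eps)
    })
  })
  models <- structure(list(levels = levels, k = as.integer(q$k),
                           n_levels = as.integer(q$n_levels),
                           n_points = as.integer(q$n_points)),
                      class = "profile_models")
  list(pdm = pdm, models = models)
}

#' Write fitted frame shapes and quality metrics as JSON
#' @param fits list of `frame_fit`.
#' @param path JSON file.
#' @export
write_fits_json <- function(fits, path) {
  obj <- list(schema = "apotrack-fits/1",
              frames = lapply(fits, function(f) {
                list(landmarks = unname(as.matrix(unclass(f$shape))),
                     total_mahalanobis = f$total_mahalanobis,
                     level_scores = f$level_scores,
                     n_iterations = f$n_iterations,
                     converged = f$converged, n_flagged = f$n_flagged)
              }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fits_json
#' @export
read_fits_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_along(obj$frames$converged %||% obj$frames), function(i) {
    fr <- if (is.data.frame(obj$frames)) {
      lapply(obj$frames, `[[`, i)
    } else {
      obj$frames[[i]]
    }
    structure(list(shape = apo_shape(fr$landmarks, frame_index = i - 1L,
                                     check = FALSE),
                   total_mahalanobis = fr$total_mahalanobis,
                   level_scores = unlist(fr$level_scores),
                   n_iterations = fr$n_iterations,
                   converged = fr$converged, n_flagged = fr$n_flagged),
              class = "frame_fit")
  })
}

#' Long-format thickness table
#'
#' One row per (trial, muscle, stride, site, node):
#' `trial, muscle, stride, site, node, thickness_mm, change_mm` with
#' `site` in 1..n_sites plus `"mean"` and `node` in 0..n_nodes-1.
#'
#' @param stride_th a `stride_thickness` (see
#'   [stride_normalized_thickness()]).
#' @param trial trial label.
#' @return a `data.table`.
#' @export
thickness_long <- function(stride_th, trial = "trial1") {
  dims <- dim(stride_th$change)   # strides x nodes x sites
  # as.vector order: stride fastest, then node, then site
  dt <- data.table::data.table(
    trial = trial, muscle = stride_th$muscle,
    stride = rep(seq_len(dims[1L]), times = dims[2L] * dims[3L]),
    site = rep(stride_th$site_labels, each = dims[1L] * dims[2L]),
    node = rep(rep(seq_len(dims[2L]) - 1L, each = dims[1L]),
               times = dims[3L]),
    thickness_mm = as.vector(stride_th$thickness),
    change_mm = as.vector(stride_th$change))
  data.table::setcolorder(dt, c("trial", "muscle", "stride", "site", "node",
                                "thickness_mm", "change_mm"))
  dt[]
}

#' Write/read the long-format thickness CSV
#' @param dt table from [thickness_long()] (or several rbind-ed).
#' @param path CSV file.
#' @export
write_thickness_csv <- function(dt, path) {
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_thickness_csv
#' @export
read_thickness_csv <- function(path) {
  data.table::fread(path)
}

#' Write/read an SPM result as JSON
#' @param result an `spm_result`.
#' @param path JSON file.
#' @export
write_spm_json <- function(result, path) {
  obj <- list(schema = "apotrack-spm/1",
              stat = result$stat, effect = result$effect,
              z = result$z, df = result$df, fwhm = result$fwhm,
              resels = result$resels,
              critical_threshold = result$critical_threshold,
              alpha = result$alpha, two_sided = result$two_sided,
              clusters = result$clusters)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_spm_json
#' @export
read_spm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cl <- as.data.frame(obj$clusters)
  if (!nrow(cl)) {
    cl <- data.frame(node_start = integer(), node_end = integer(),
                     start_pct = numeric(), end_pct = numeric())
  }
  structure(list(stat = obj$stat, z = obj$z, df = obj$df,
                 effect = obj$effect, fwhm = obj$fwhm,
                 resels = obj$resels,
                 critical_threshold = obj$critical_threshold,
                 clusters = cl, alpha = obj$alpha,
                 two_sided = obj$two_sided),
            class = "spm_result")
}
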