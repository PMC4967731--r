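#' Scene configuration for the synthetic flicker-movie simulator
#'
#' Describes a field of organelles inside a traced cell, their flicker
#' statistics (organelle-wide stochastic depolarizations), motility
#' (Brownian jitter plus directed runs along the cell axis), and the
#' imaging model (baseline brightness, photon shot noise, Gaussian read
#' noise, exponential photobleaching, whole-field drift, optional
#' Gaussian PSF blur). All stochastic draws are governed by `rng_seed`;
#' identical configs produce bit-identical scenes.
#'
#' @param nx,ny image size, pixels.
#' @param pixel_size_nm,frame_interval_s,duration_s calibration; defaults
#'   225 nm, 0.5 s/frame, 120 s.
#' @param organelles data frame with columns `shape` ("rod", "disc" or
#'   "blob"), `len_px`, `wid_px`, `x`, `y` (0-based centre),
#'   `orientation` (degrees, 0 = along x), `motile` (logical).
#' @param cell integer vector `c(x0, y0, x1, y1)` (0-based, inclusive)
#'   tracing the cell rectangle, or `NULL` for the full image.
#' @param flicker list: `rate_per_min` (Poisson event rate per
#'   organelle), `depth` (fractional dip, in (0, 1]), `duration_s`
#'   (depolarized plateau), `tau_on_s`, `tau_off_s` (mono-exponential
#'   de/repolarization time constants).
#' @param motility list: `brownian_sigma_nm` (per sqrt-second step of
#'   motile organelles), `speed_range_nm_s` and `distance_range_um` for
#'   the single directed run each mover performs, along +/- x (the cell
#'   axis), direction chosen to stay inside the cell.
#' @param noise list: `f0` (organelle baseline, counts), `background`
#'   (counts), `shot` (logical, Poisson noise), `read_sigma` (counts).
#' @param bleach_rate_per_min exponential photobleaching rate.
#' @param drift_px_per_frame length-2 whole-field drift per frame.
#' @param psf_sigma_px Gaussian PSF sigma in pixels (0 disables blur;
#'   disabled by default so simulator footprints stay exact for oracle
#'   tests).
#' @param rng_seed integer seed.
#' @return validated list of class `scene_config`.
#' @export
scene_config <- function(nx, ny, pixel_size_nm = 225,
                         frame_interval_s = 0.5, duration_s = 120,
                         organelles = NULL, cell = NULL,
                         flicker = list(), motility = list(),
                         noise = list(), bleach_rate_per_min = 0.01,
                         drift_px_per_frame = c(0, 0), psf_sigma_px = 0,
                         rng_seed = 1L) {
  flick <- utils::modifyList(
    list(rate_per_min = 3, depth = 0.8, duration_s = 5,
         tau_on_s = 0.5, tau_off_s = 1),
    flicker)
  mot <- utils::modifyList(
    list(brownian_sigma_nm = 15, speed_range_nm_s = c(40, 95),
         distance_range_um = c(0.8, 12)),
    motility)
  noi <- utils::modifyList(
    list(f0 = 400, background = 40, shot = TRUE, read_sigma = 3),
    noise)
  if (is.null(cell)) cell <- c(0L, 0L, nx - 1L, ny - 1L)
  cfg <- list(nx = as.integer(nx), ny = as.integer(ny),
              pixel_size_nm = pixel_size_nm,
              frame_interval_s = frame_interval_s,
              duration_s = duration_s,
              organelles = organelles, cell = as.integer(cell),
              flicker = flick, motility = mot, noise = noi,
              bleach_rate_per_min = bleach_rate_per_min,
              drift_px_per_frame = as.numeric(drift_px_per_frame),
              psf_sigma_px = psf_sigma_px,
              rng_seed = as.integer(rng_seed))
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  with(cfg, {
    stopifnot(nx >= 1, ny >= 1, pixel_size_nm > 0, frame_interval_s > 0,
              duration_s > 0, flicker$rate_per_min >= 0,
              flicker$duration_s > 0, flicker$tau_on_s > 0,
              flicker$tau_off_s > 0, noise$f0 > 0, noise$background >= 0,
              noise$read_sigma >= 0, bleach_rate_per_min >= 0,
              psf_sigma_px >= 0, length(drift_px_per_frame) == 2)
    if (flicker$depth <= 0 || flicker$depth > 1) {
      stop("flicker depth must be in (0, 1]")
    }
    if (cell[1] < 0 || cell[2] < 0 || cell[3] >= nx || cell[4] >= ny ||
        cell[1] > cell[3] || cell[2] > cell[4]) {
      stop("cell rectangle outside the image")
    }
  })
  invisible(cfg)
}

# 0-based pixel offsets of a footprint centred near (0, 0)
footprint_offsets <- function(shape, len_px, wid_px, orientation = 0) {
  off <- switch(as.character(shape),
    rod = {
      xs <- seq_len(len_px) - 1L - (len_px %/% 2L)
      ys <- seq_len(wid_px) - 1L - (wid_px %/% 2L)
      as.matrix(expand.grid(x = xs, y = ys))
    },
    disc = {
      r <- len_px / 2
      g <- expand.grid(x = -ceiling(r):ceiling(r), y = -ceiling(r):ceiling(r))
      as.matrix(g[g$x^2 + g$y^2 <= r^2, ])
    },
    blob = {
      # 4x4 square minus two opposite corners: a compact 14-px blob
      g <- as.matrix(expand.grid(x = 0:3, y = 0:3))
      g <- g[!(g[, 1] == 0 & g[, 2] == 0) & !(g[, 1] == 3 & g[, 2] == 3), ]
      sweep(g, 2L, c(1L, 1L))
    },
    stop("unknown shape: ", shape))
  if (orientation %% 180 == 90) off <- off[, c(2L, 1L), drop = FALSE]
  colnames(off) <- c("x", "y")
  off
}

# organelle-wide flicker intensity factor series: 1 when polarized,
# 1 - depth at the trough, mono-exponential on/off kinetics
flicker_factor <- function(onsets_s, t_s, flick) {
  g <- numeric(length(t_s))
  for (o in onsets_s) {
    s <- t_s - o
    gi <- numeric(length(t_s))
    on <- s >= 0 & s <= flick$duration_s
    gi[on] <- 1 - exp(-s[on] / flick$tau_on_s)
    post <- s > flick$duration_s
    g_end <- 1 - exp(-flick$duration_s / flick$tau_on_s)
    gi[post] <- g_end * exp(-(s[post] - flick$duration_s) / flick$tau_off_s)
    g <- pmax(g, gi)
  }
  1 - flick$depth * pmin(g, 1)
}

#' Build the ground truth of a scene
#'
#' Draws every stochastic element of the scene (flicker schedules,
#' Brownian paths, directed runs) from the config's seed and assembles
#' the ground truth: per-organelle footprints, flicker factor series,
#' motion paths, the cell mask, and the planted population summary
#' (occupancy, motile fraction, shape records computed from the true
#' footprints).
#'
#' @param config a [scene_config()].
#' @return list of class `scene_truth`.
#' @export
build_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  org <- config$organelles
  n <- as.integer(round(config$duration_s / config$frame_interval_s))
  t_s <- (seq_len(n) - 1L) * config$frame_interval_s
  cell_mask <- matrix(FALSE, config$nx, config$ny)
  cl <- config$cell
  cell_mask[(cl[1]:cl[3]) + 1L, (cl[2]:cl[4]) + 1L] <- TRUE

  if (is.null(org) || nrow(org) == 0L) {
    return(structure(list(config = config, n_frames = n, t_s = t_s,
                          footprints = list(), factors = NULL,
                          paths = list(), cell_mask = cell_mask,
                          organelles = org,
                          planted = list(occupancy = 0, n_motile = 0L,
                                         fraction_motile = 0)),
                     class = "scene_truth"))
  }

  set.seed(config$rng_seed)
  nk <- nrow(org)
  px_nm <- config$pixel_size_nm
  footprints <- vector("list", nk)
  paths <- vector("list", nk)
  factors <- matrix(1, n, nk)
  n_events <- integer(nk)
  for (i in seq_len(nk)) {
    off <- footprint_offsets(org$shape[i], org$len_px[i], org$wid_px[i],
                             if ("orientation" %in% names(org))
                               org$orientation[i] else 0)
    fp <- cbind(x = off[, 1L] + org$x[i], y = off[, 2L] + org$y[i])
    if (any(fp[, 1L] < 0 | fp[, 1L] >= config$nx |
            fp[, 2L] < 0 | fp[, 2L] >= config$ny)) {
      stop(sprintf("organelle %d does not fit inside the image", i))
    }
    footprints[[i]] <- fp
    if (config$flicker$rate_per_min > 0) {
      n_ev <- rpois(1L, config$flicker$rate_per_min * config$duration_s / 60)
      onsets <- sort(runif(n_ev, 0, config$duration_s))
      factors[, i] <- flicker_factor(onsets, t_s, config$flicker)
      n_events[i] <- n_ev
    }
    if (isTRUE(org$motile[i])) {
      sig_px <- config$motility$brownian_sigma_nm *
        sqrt(config$frame_interval_s) / px_nm
      steps <- matrix(rnorm(2L * n, 0, sig_px), n, 2L)
      steps[1L, ] <- 0
      path <- apply(steps, 2L, cumsum)
      # one directed run along the cell axis, direction keeping the run
      # inside the cell
      dist_um <- runif(1L, config$motility$distance_range_um[1L],
                       config$motility$distance_range_um[2L])
      speed <- runif(1L, config$motility$speed_range_nm_s[1L],
                     config$motility$speed_range_nm_s[2L])
      run_s <- dist_um * 1000 / speed
      t0 <- runif(1L, 0, max(0, config$duration_s - run_s))
      dist_px <- dist_um * 1000 / px_nm
      margin <- max(org$len_px[i], 4L)
      room_pos <- cl[3] - margin - org$x[i]
      room_neg <- org$x[i] - cl[1] - margin
      dir <- if (room_pos >= dist_px) 1 else if (room_neg >= dist_px) -1
             else if (room_pos >= room_neg) 1 else -1
      reach <- pmin(pmax(t_s - t0, 0), run_s) * speed / 1000  # um
      reach <- pmin(reach, max(if (dir > 0) room_pos else room_neg, 0) *
                             px_nm / 1000)
      path[, 1L] <- path[, 1L] + dir * reach * 1000 / px_nm
      paths[[i]] <- path
    }
  }

  motile <- if ("motile" %in% names(org)) isTRUE_vec(org$motile) else
    rep(FALSE, nk)
  truth_masks <- lapply(footprints, mito_mask)
  records <- lapply(truth_masks, shape_record, pixel_size_nm = px_nm)
  occ <- suppressWarnings(occupancy(cell_mask, truth_masks))
  summ <- summarize_population(records, px_nm)
  structure(list(
    config = config, n_frames = n, t_s = t_s,
    footprints = footprints, factors = factors, paths = paths,
    n_flicker_events = n_events,
    cell_mask = cell_mask, organelles = org,
    shape_records = records,
    planted = list(
      occupancy = occ$fraction,
      n_motile = sum(motile), fraction_motile = mean(motile),
      fraction_long = summ$fraction_long,
      fraction_elongated = summ$fraction_elongated,
      mode_area_um2 = summ$mode_area)
  ), class = "scene_truth")
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

# separable Gaussian blur with edge renormalization; intended for the
# small oracle scenes where the PSF is switched on
gaussian_blur <- function(frame, sigma) {
  r <- ceiling(3 * sigma)
  band <- function(nn) {
    B <- outer(seq_len(nn), seq_len(nn),
               function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
    B[abs(row(B) - col(B)) > r] <- 0
    B / rowSums(B)
  }
  band(nrow(frame)) %*% frame %*% t(band(ncol(frame)))
}

#' Render a scene to a fluorescence stack
#'
#' Composes the movie from the ground truth: each organelle contributes
#' its baseline brightness scaled by its flicker factor (the whole,
#' electrically contiguous organelle dims together), movers and
#' whole-field drift shift footprints by the rounded cumulative offset,
#' photobleaching decays the signal exponentially, the optional Gaussian
#' PSF blurs each frame, and background plus photon shot noise and read
#' noise are applied. Output intensities are integer camera counts
#' (clamped to the 16-bit range), so written movies round-trip exactly.
#'
#' @param truth a [build_scene()] result.
#' @return a [fluorescence_stack()].
#' @export
render_stack <- function(truth) {
  stopifnot(inherits(truth, "scene_truth"))
  cfg <- truth$config
  n <- truth$n_frames
  npix <- cfg$nx * cfg$ny
  mat <- matrix(0, npix, n)
  drift_cum <- apply(matrix(cfg$drift_px_per_frame, n, 2L, byrow = TRUE),
                     2L, cumsum) - matrix(cfg$drift_px_per_frame, n, 2L,
                                          byrow = TRUE)
  has_drift <- any(cfg$drift_px_per_frame != 0)
  for (i in seq_along(truth$footprints)) {
    fp <- truth$footprints[[i]]
    fac <- cfg$noise$f0 * truth$factors[, i]
    path <- truth$paths[[i]]
    if (is.null(path) && !has_drift) {
      lin <- fp[, 1L] + 1L + fp[, 2L] * cfg$nx
      mat[lin, ] <- mat[lin, ] + rep(fac, each = nrow(fp))
    } else {
      for (t in seq_len(n)) {
        o <- round(drift_cum[t, ] +
                     if (is.null(path)) c(0, 0) else path[t, ])
        xs <- fp[, 1L] + o[1L]; ys <- fp[, 2L] + o[2L]
        keep <- xs >= 0L & xs < cfg$nx & ys >= 0L & ys < cfg$ny
        lin <- xs[keep] + 1L + ys[keep] * cfg$nx
        mat[lin, t] <- mat[lin, t] + fac[t]
      }
    }
  }
  if (cfg$bleach_rate_per_min > 0) {
    bleach <- exp(-cfg$bleach_rate_per_min / 60 * truth$t_s)
    mat <- mat * rep(bleach, each = npix)
  }
  if (cfg$psf_sigma_px > 0) {
    for (t in seq_len(n)) {
      mat[, t] <- gaussian_blur(matrix(mat[, t], cfg$nx, cfg$ny),
                                cfg$psf_sigma_px)
    }
  }
  mat <- mat + cfg$noise$background
  set.seed(cfg$rng_seed + 1L)
  if (isTRUE(cfg$noise$shot)) {
    mat[] <- rpois(length(mat), lambda = mat)
  }
  if (cfg$noise$read_sigma > 0) {
    mat <- mat + rnorm(length(mat), 0, cfg$noise$read_sigma)
  }
  mat <- pmin(pmax(round(mat), 0), 65535)
  fluorescence_stack(array(mat, c(cfg$nx, cfg$ny, n)),
                     cfg$pixel_size_nm, cfg$frame_interval_s)
}

#' Bundled scene presets
#'
#' Ready-made configurations mirroring the study conditions:
#' \describe{
#'   \item{`aged`}{400 static organelles, modal area 14 px (0.710 um^2 at
#'     225 nm), 5.25% longer than 2 um, 4.25% with length:width > 3,
#'     occupancy 0.18; flickering; 120 s at 2 Hz.}
#'   \item{`young_structure`}{600 static organelles, modal area 1 px
#'     (0.051 um^2), occupancy ~0.083; flickering; 120 s at 2 Hz.}
#'   \item{`young_motility`}{1135 small organelles in a long, thin
#'     myocyte-like cell, exactly 215 of them motile (19%), movers biased
#'     towards the cell periphery, directed runs of 0.8-12 um at 40-95
#'     nm/s; no flickers; 600 s at 0.5 Hz.}
#'   \item{`overlap_pair`}{two parallel rods 2 px apart with independent
#'     flicker schedules and a 1 px Gaussian PSF so their blurred images
#'     overlap; noiseless. Tests separation of electrically discrete but
#'     optically overlapping organelles.}
#' }
#'
#' @param name preset name.
#' @param rng_seed seed forwarded to the config.
#' @param n_organelles optional reduced organelle count (scenes keep
#'   their composition proportions); used for quick demonstrations.
#' @return a [scene_config()].
#' @export
scene_preset <- function(name = c("aged", "young_structure",
                                  "young_motility", "overlap_pair"),
                         rng_seed = 1L, n_organelles = NULL) {
  name <- match.arg(name)
  set.seed(rng_seed + 1000L)  # placement shuffling only
  cfg <- switch(name,
    aged = {
      shapes <- data.frame(
        shape = c(rep("blob", 160), rep("rod", 240)),
        len_px = c(rep(4L, 160), rep(3L, 25), rep(5L, 35), rep(6L, 59),
                   rep(6L, 100), rep(12L, 17), rep(9L, 4)),
        wid_px = c(rep(4L, 160), rep(2L, 25), rep(4L, 35), rep(5L, 59),
                   rep(6L, 100), rep(3L, 17), rep(4L, 4)))
      shapes <- shapes[sample.int(nrow(shapes)), ]
      grid <- expand.grid(i = 0:49, j = 0:7)
      shapes$x <- 12L + 16L * grid$i
      shapes$y <- 8L + 8L * grid$j
      shapes$orientation <- 0
      shapes$motile <- FALSE
      scene_config(nx = 808L, ny = 72L, frame_interval_s = 0.5,
                   duration_s = 120, organelles = shapes,
                   cell = c(4L, 4L, 803L, 67L), rng_seed = rng_seed)
    },
    young_structure = {
      shapes <- data.frame(
        shape = "rod",
        len_px = c(rep(1L, 330), rep(2L, 120), rep(3L, 60), rep(3L, 60),
                   rep(6L, 30)),
        wid_px = c(rep(1L, 330), rep(1L, 120), rep(1L, 60), rep(2L, 60),
                   rep(2L, 30)))
      shapes <- shapes[sample.int(nrow(shapes)), ]
      grid <- expand.grid(i = 0:74, j = 0:7)
      shapes$x <- 7L + 7L * grid$i
      shapes$y <- 6L + 4L * grid$j
      shapes$orientation <- 0
      shapes$motile <- FALSE
      scene_config(nx = 536L, ny = 40L, frame_interval_s = 0.5,
                   duration_s = 120, organelles = shapes,
                   cell = c(4L, 4L, 531L, 35L), rng_seed = rng_seed)
    },
    young_motility = {
      n_total <- 1136L
      shapes <- data.frame(
        shape = "rod",
        len_px = c(rep(1L, 626), rep(2L, 230), rep(3L, 140), rep(3L, 140)),
        wid_px = c(rep(1L, 626), rep(1L, 230), rep(1L, 140), rep(2L, 140)))
      shapes <- shapes[sample.int(n_total), ]
      grid <- expand.grid(i = 0:141, j = 0:7)
      # rows sit at depths 4, 8, 12, 16 px from the nearest cell edge
      row_y <- c(8L, 12L, 16L, 20L, 27L, 31L, 35L, 39L)
      shapes$x <- 7L + 6L * grid$i
      shapes$y <- row_y[grid$j + 1L]
      shapes <- shapes[seq_len(1135L), ]       # 1135 organelles
      shapes$orientation <- 0
      # peripheral bias: movers preferentially drawn from shallow rows
      depth_w <- c(1.2, 1.1, 1.0, 0.9)[c(1:4, 4:1)]
      w <- depth_w[match(shapes$y, row_y)]
      movers <- sample.int(nrow(shapes), 215L, prob = w)
      shapes$motile <- FALSE
      shapes$motile[movers] <- TRUE
      scene_config(nx = 868L, ny = 48L, frame_interval_s = 2,
                   duration_s = 600, organelles = shapes,
                   cell = c(4L, 4L, 857L, 43L),
                   flicker = list(rate_per_min = 0),
                   rng_seed = rng_seed)
    },
    overlap_pair = {
      shapes <- data.frame(
        shape = "rod", len_px = c(8L, 8L), wid_px = c(2L, 2L),
        x = c(20L, 20L), y = c(18L, 22L), orientation = 0,
        motile = FALSE)
      scene_config(nx = 48L, ny = 40L, frame_interval_s = 0.5,
                   duration_s = 120, organelles = shapes,
                   flicker = list(rate_per_min = 4),
                   noise = list(shot = FALSE, read_sigma = 0),
                   bleach_rate_per_min = 0, psf_sigma_px = 1,
                   rng_seed = rng_seed)
    })
  if (!is.null(n_organelles) && n_organelles < nrow(cfg$organelles)) {
    keep <- sort(sample.int(nrow(cfg$organelles), n_organelles))
    cfg$organelles <- cfg$organelles[keep, , drop = FALSE]
  }
  cfg
}

#' Write a rendered scene to disk
#'
#' Writes `movie.tif` (16-bit counts), `truth_masks.tif` (16-bit label
#' image, organelle index + 1), `cell_mask.tif`, `truth_organelles.csv`
#' (per-organelle geometry, flags and planted motility) and
#' `config.json`. Written movies round-trip exactly through
#' [read_stack_tiff()].
#'
#' @param truth a [build_scene()] result.
#' @param stack the matching [render_stack()] output.
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_scene <- function(truth, stack, outdir) {
  stopifnot(inherits(truth, "scene_truth"), inherits(stack, "flstack"))
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", outdir)
  }
  cfg <- truth$config
  write_stack_tiff(stack, file.path(outdir, "movie.tif"))
  labels <- matrix(0L, cfg$nx, cfg$ny)
  for (i in seq_along(truth$footprints)) {
    fp <- truth$footprints[[i]]
    labels[fp[, 1L] + 1L + fp[, 2L] * cfg$nx] <- i
  }
  write_label_tiff(labels, file.path(outdir, "truth_masks.tif"))
  write_label_tiff(truth$cell_mask * 1L, file.path(outdir, "cell_mask.tif"))
  org <- truth$organelles
  if (!is.null(org)) {
    org$area_px <- vapply(truth$footprints, nrow, integer(1))
    org$length_um <- vapply(truth$shape_records,
                            function(r) r$length_um, numeric(1))
    org$width_um <- vapply(truth$shape_records,
                           function(r) r$width_um, numeric(1))
    write.csv(org, file.path(outdir, "truth_organelles.csv"),
              row.names = FALSE)
  }
  cfg_out <- unclass(cfg)
  cfg_out$organelles <- NULL  # carried by truth_organelles.csv
  jsonlite::write_json(cfg_out, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(outdir, c("movie.tif", "truth_masks.tif",
                                "cell_mask.tif", "truth_organelles.csv",
                                "config.json")))
}
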