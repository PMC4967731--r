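#' Estimate whole-cell drift by phase correlation
#'
#' Estimates a per-frame global translation relative to the first frame
#' with 2D phase correlation, refined to sub-pixel precision by parabolic
#' interpolation around the correlation peak. The result is subtracted
#' from centroid tracks so motility is scored independently of any
#' whole-cell movement. Featureless frames (zero spectral energy) yield
#' zero drift with a warning.
#'
#' @param stack a [fluorescence_stack()] with at least two frames.
#' @return numeric matrix `n x 2` of cumulative drift `(dx, dy)` in
#'   pixels; first row is `(0, 0)`.
#' @export
estimate_global_drift <- function(stack) {
  stopifnot(inherits(stack, "flstack"))
  if (stack$n < 2L) stop("at least two frames are required")
  ref <- stack$intensities[, , 1L]
  Fref <- fft(ref)
  nx <- stack$nx; ny <- stack$ny
  drift <- matrix(0, stack$n, 2L, dimnames = list(NULL, c("dx", "dy")))
  warned <- FALSE
  for (t in 2L:stack$n) {
    Ft <- fft(stack$intensities[, , t])
    cross <- Fref * Conj(Ft)
    mag <- Mod(cross)
    if (max(mag) == 0) {
      warned <- TRUE
      next
    }
    r <- Re(fft(cross / pmax(mag, .Machine$double.eps), inverse = TRUE))
    pk <- which(r == max(r), arr.ind = TRUE)[1L, ]
    # sub-pixel refinement: 1D parabola through the peak and wrapped
    # neighbours in each axis
    wrap <- function(i, n) ((i - 1L) %% n) + 1L
    px <- pk[1L]; py <- pk[2L]
    fx <- c(r[wrap(px - 1L, nx), py], r[px, py], r[wrap(px + 1L, nx), py])
    fy <- c(r[px, wrap(py - 1L, ny)], r[px, py], r[px, wrap(py + 1L, ny)])
    sub <- function(f) {
      den <- f[1L] - 2 * f[2L] + f[3L]
      if (den == 0) 0 else 0.5 * (f[1L] - f[3L]) / den
    }
    dx <- (px - 1L) + sub(fx)
    dy <- (py - 1L) + sub(fy)
    if (dx > nx / 2) dx <- dx - nx
    if (dy > ny / 2) dy <- dy - ny
    # the correlation peak sits at minus the scene displacement
    drift[t, ] <- c(-dx, -dy)
  }
  if (warned) warning("featureless frame(s): drift set to zero")
  drift
}

# intensity-weighted centroid in a window (half-size h) around a 0-based
# position. Background is the window median; weights below 30% of the
# peak are zeroed so diffuse shot noise cannot drag the centroid towards
# the window centre or a neighbouring organelle.
local_centroid <- function(frame, pos, h) {
  nx <- nrow(frame); ny <- ncol(frame)
  cx <- round(pos[1L]); cy <- round(pos[2L])
  x0 <- max(0L, cx - h); x1 <- min(nx - 1L, cx + h)
  y0 <- max(0L, cy - h); y1 <- min(ny - 1L, cy + h)
  if (x0 > x1 || y0 > y1) return(c(NA_real_, NA_real_))
  win <- frame[(x0:x1) + 1L, (y0:y1) + 1L, drop = FALSE]
  w <- win - median(win)
  mx <- max(w)
  if (mx <= 0) return(c(NA_real_, NA_real_))
  w[w < 0.3 * mx] <- 0
  sw <- sum(w)
  xs <- x0:x1; ys <- y0:y1
  c(sum(rowSums(w) * xs) / sw, sum(colSums(w) * ys) / sw)
}

#' Track organelle centroids through a movie
#'
#' For each mask, starts from the mask's intensity-weighted centroid and
#' re-localizes it every `interval_frames` frames by an intensity-weighted
#' centroid in a small window around the predicted position (previous
#' position plus the change in estimated global drift). Positions are
#' drift-corrected and reported both in pixels and micrometres. Frames
#' where the organelle cannot be localized (e.g. flicker-dark) are
#' recorded as gaps, not errors.
#'
#' @param stack a [fluorescence_stack()].
#' @param masks list of `mito_mask` objects (from [segment_stack()] or
#'   ground truth).
#' @param interval_frames sampling interval in frames (default: one
#'   second's worth of frames, at least 1).
#' @param drift optional `n x 2` drift matrix from
#'   [estimate_global_drift()]; `NULL` computes it, `FALSE` disables
#'   drift correction.
#' @param window_half half-size of the localization window, pixels
#'   (default 2, i.e. 5 x 5; use 1 for densely packed scenes so a
#'   passing neighbour cannot invade the window).
#' @param speed_floor_px minimum displacement (pixels) over a speed lag
#'   for a window to count as "moving" when averaging speed.
#' @param speed_lag_s lag over which instantaneous speeds are measured
#'   (default 20 s); a coarse lag keeps pixel-quantization jitter out of
#'   the speed estimate.
#' @param max_step_px per-sample displacement clamp, pixels. Organelle
#'   speeds are physically bounded (directed transport tops out near
#'   100 nm/s), so steps beyond the clamp are treated as localization
#'   failures and truncated.
#' @return list of class `track_set`: `tracks` (list with per-organelle
#'   `centroids_px` (drift-corrected, 0-based), `t_s`, `max_excursion_um`,
#'   `mean_speed_nm_s`, `n_gaps`), `interval_frames`, `pixel_size_nm`.
#' @export
track_centroids <- function(stack, masks, interval_frames = NULL,
                            drift = NULL, window_half = 2L,
                            speed_floor_px = 0.5, max_step_px = 1.5,
                            speed_lag_s = 20) {
  stopifnot(inherits(stack, "flstack"))
  if (length(masks) < 1L) stop("no masks to track")
  if (is.null(interval_frames)) {
    interval_frames <- max(1L, round(1 / stack$frame_interval_s))
  }
  interval_frames <- as.integer(interval_frames)
  if (is.null(drift)) {
    drift <- estimate_global_drift(stack)
  } else if (identical(drift, FALSE)) {
    drift <- matrix(0, stack$n, 2L)
  }
  samples <- seq(1L, stack$n, by = interval_frames)
  t_s <- (samples - 1L) * stack$frame_interval_s
  px_um <- stack$pixel_size_nm / 1000
  dt_s <- interval_frames * stack$frame_interval_s
  nm <- length(masks)
  live <- vapply(masks, function(m) {
    inherits(m, "mito_mask") && !is.null(m$pixels)
  }, logical(1))
  last <- matrix(NA_real_, nm, 2L)
  for (i in which(live)) last[i, ] <- colMeans(masks[[i]]$pixels)
  # "home" patch: the starting centroid pixel plus its 4-neighbours.
  # Used for the departure check: a truly motile organelle goes dark at
  # its starting pixel, whereas a tracking window dragged along by a
  # neighbour crossing it does not. The 4-neighbours absorb the
  # occasional one-axis rounding mismatch under whole-field drift
  # without being fooled by an organelle parked diagonally adjacent.
  home <- vector("list", nm)
  for (i in which(live)) {
    c0 <- round(last[i, ])
    home[[i]] <- cbind(x = c0[1L] + c(0L, -1L, 1L, 0L, 0L),
                       y = c0[2L] + c(0L, 0L, 0L, -1L, 1L))
  }
  cent <- array(NA_real_, c(length(samples), 2L, nm))
  retention <- matrix(NA_real_, length(samples), nm)
  home_peak0 <- rep(NA_real_, nm)
  gaps <- integer(nm)
  max_step <- max_step_px
  # frames outer so each frame is extracted from the stack exactly once
  for (s in seq_along(samples)) {
    fr <- samples[s]
    frame <- stack$intensities[, , fr]
    bg <- median(frame)
    dstep <- if (s > 1L) drift[fr, ] - drift[samples[s - 1L], ] else c(0, 0)
    dr <- round(drift[fr, ])
    for (i in which(live)) {
      pred <- last[i, ] + dstep
      loc <- local_centroid(frame, pred, window_half)
      if (anyNA(loc)) {
        gaps[i] <- gaps[i] + 1L
        last[i, ] <- pred
      } else {
        # clamp the step: organelle speeds are physically bounded, so a
        # larger jump is a neighbouring organelle invading the window,
        # not movement of this organelle
        d <- loc - pred
        dn <- sqrt(sum(d^2))
        if (dn > max_step) loc <- pred + d * (max_step / dn)
        cent[s, , i] <- loc - drift[fr, ]
        last[i, ] <- loc
      }
      hp <- home[[i]]
      xs <- hp[, 1L] + dr[1L]; ys <- hp[, 2L] + dr[2L]
      keep <- xs >= 0L & xs < stack$nx & ys >= 0L & ys < stack$ny
      if (any(keep)) {
        peak <- max(frame[xs[keep] + 1L + ys[keep] * stack$nx]) - bg
        if (s == 1L) home_peak0[i] <- max(peak, .Machine$double.eps)
        retention[s, i] <- peak / home_peak0[i]
      }
    }
  }
  tracks <- vector("list", nm)
  for (i in seq_len(nm)) {
    if (!live[i]) {
      tracks[[i]] <- list(organelle_id = i, centroids_px = NULL,
                          t_s = t_s, max_excursion_um = NA_real_,
                          mean_speed_nm_s = NA_real_, n_gaps = NA_integer_,
                          status = masks[[i]]$status)
      next
    }
    ci <- cent[, , i, drop = FALSE]
    dim(ci) <- c(length(samples), 2L)
    ok <- which(!is.na(ci[, 1L]))
    exc <- if (length(ok) >= 2L) {
      p0 <- ci[ok[1L], ]
      max(sqrt((ci[ok, 1L] - p0[1L])^2 + (ci[ok, 2L] - p0[2L])^2)) * px_um
    } else 0
    # speeds over a coarse lag; only windows moving at close to the
    # track's peak rate are averaged, so ramp-in/ramp-out windows at the
    # edges of a directed burst do not dilute the burst speed
    lag <- max(1L, round(speed_lag_s / dt_s))
    mean_speed <- 0
    if (length(ok) > lag) {
      oo <- ok[seq_len(length(ok) - lag)]
      o2 <- ok[seq_len(length(ok) - lag) + lag]
      disp <- sqrt((ci[o2, 1L] - ci[oo, 1L])^2 +
                     (ci[o2, 2L] - ci[oo, 2L])^2)
      lag_dt <- (o2 - oo) * dt_s
      moving <- disp > pmax(speed_floor_px, 0.6 * max(disp))
      if (any(moving)) {
        mean_speed <- mean(disp[moving] / lag_dt[moving]) *
          stack$pixel_size_nm
      }
    }
    ret <- retention[, i]
    tracks[[i]] <- list(organelle_id = i, centroids_px = ci, t_s = t_s,
                        max_excursion_um = exc,
                        mean_speed_nm_s = mean_speed, n_gaps = gaps[i],
                        home_retention = ret,
                        home_vacated = all(is.na(ret)) ||
                          min(ret, na.rm = TRUE) < 0.5,
                        status = "ok")
  }
  structure(list(tracks = tracks, interval_frames = interval_frames,
                 pixel_size_nm = stack$pixel_size_nm),
            class = "track_set")
}

#' Classify motile organelles
#'
#' An organelle is motile if its drift-corrected excursion from the start
#' of any observation window of `window_minutes` exceeds `threshold_um`
#' AND it vacated its starting pixel at some point of the recording (the
#' departure check computed by [track_centroids()]): two identical
#' organelles crossing paths are ambiguous to any local tracker, but a
#' static organelle's own pixel never goes dark, so a tracking window
#' that was merely dragged along by a passing neighbour is vetoed.
#' The default threshold of 0.45 um (two pixels at 225 nm) is a
#' configurable stand-in for the by-eye criterion used in manual
#' counting; the smallest movement counted in the source data was about
#' 0.5 um.
#'
#' @param tracks a [track_centroids()] result.
#' @param window_minutes observation window, minutes (default 10).
#' @param threshold_um excursion threshold, micrometres (default 0.45).
#' @return list of class `motility_report`: `n`, `n_motile`, `fraction`,
#'   `motile` (logical vector), `max_excursion_um` (per organelle).
#' @export
classify_motile <- function(tracks, window_minutes = 10,
                            threshold_um = 0.45) {
  stopifnot(inherits(tracks, "track_set"))
  win_s <- window_minutes * 60
  px_um <- tracks$pixel_size_nm / 1000
  exc <- vapply(tracks$tracks, function(tr) {
    if (is.null(tr$centroids_px)) return(NA_real_)
    cent <- tr$centroids_px
    ok <- which(!is.na(cent[, 1L]))
    if (length(ok) < 2L) return(0)
    ts <- tr$t_s[ok]
    best <- 0
    for (s in seq_along(ok)) {
      inwin <- ok[ts - ts[s] >= 0 & ts - ts[s] <= win_s]
      if (length(inwin) < 2L) next
      p0 <- cent[ok[s], ]
      d <- sqrt((cent[inwin, 1L] - p0[1L])^2 +
                  (cent[inwin, 2L] - p0[2L])^2)
      best <- max(best, max(d))
    }
    best * px_um
  }, numeric(1))
  vacated <- vapply(tracks$tracks, function(tr) {
    !isFALSE(tr$home_vacated)
  }, logical(1))
  motile <- !is.na(exc) & exc > threshold_um & vacated
  structure(list(n = length(exc), n_motile = sum(motile),
                 fraction = mean(motile), motile = motile,
                 max_excursion_um = exc,
                 threshold_um = threshold_um,
                 window_minutes = window_minutes),
            class = "motility_report")
}

#' @export
print.motility_report <- function(x, ...) {
  cat(sprintf(
    "<motility_report> %d of %d motile (%.1f%%) at > %.2f um in %g min\n",
    x$n_motile, x$n, 100 * x$fraction, x$threshold_um, x$window_minutes))
  invisible(x)
}

#' Signed distance field from the cell edge
#'
#' Solves the unit-speed Eikonal problem for a traced cell mask via an
#' exact Euclidean distance transform, signed positive inside the cell
#' and negative outside, with a half-pixel offset so that the zero level
#' sits on the mask boundary (an interior pixel adjacent to the edge is
#' half a pixel from it). Distances are in micrometres.
#'
#' @param cell_mask logical or 0/1 matrix indexed `[x, y]`.
#' @param pixel_size_nm pixel size, nm.
#' @return list of class `distance_field`: `values` (matrix, um),
#'   `pixel_size_nm`.
#' @export
signed_distance <- function(cell_mask, pixel_size_nm = 225) {
  cell <- cell_mask != 0
  if (!any(cell)) stop("cell mask is empty")
  inside <- EBImage::distmap(matrix(as.numeric(cell), nrow(cell)))
  outside <- EBImage::distmap(matrix(as.numeric(!cell), nrow(cell)))
  signed_px <- ifelse(cell, inside - 0.5, -(outside - 0.5))
  structure(list(values = signed_px * pixel_size_nm / 1000,
                 pixel_size_nm = pixel_size_nm),
            class = "distance_field")
}

# bilinear interpolation of a field at 0-based (x, y) positions
interp_field <- function(values, xy) {
  nx <- nrow(values); ny <- ncol(values)
  x <- pmin(pmax(xy[, 1L], 0), nx - 1)
  y <- pmin(pmax(xy[, 2L], 0), ny - 1)
  x0 <- pmin(floor(x), nx - 2); y0 <- pmin(floor(y), ny - 2)
  fx <- x - x0; fy <- y - y0
  i <- x0 + 1L; j <- y0 + 1L
  v00 <- values[cbind(i, j)]; v10 <- values[cbind(i + 1L, j)]
  v01 <- values[cbind(i, j + 1L)]; v11 <- values[cbind(i + 1L, j + 1L)]
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
}

#' Relate motility to distance from the cell edge
#'
#' Evaluates each organelle's distance from the cell edge (signed
#' distance field interpolated at the first observed centroid) and
#' summarizes the motile subset against all organelles, with a Welch two
#' sample comparison of motile vs non-motile distances at alpha = 0.05.
#' Organelles whose reference centroid falls outside the cell are
#' excluded with a warning.
#'
#' @param tracks a [track_centroids()] result.
#' @param motility a [classify_motile()] result for the same tracks.
#' @param field a [signed_distance()] field.
#' @return list of class `edge_distance_report`: per-group mean, SEM and
#'   n, the per-organelle distances, and the test (or a note when there
#'   are no motile organelles).
#' @export
motility_vs_edge <- function(tracks, motility, field) {
  stopifnot(inherits(tracks, "track_set"),
            inherits(motility, "motility_report"),
            inherits(field, "distance_field"))
  ref <- t(vapply(tracks$tracks, function(tr) {
    if (is.null(tr$centroids_px)) return(c(NA_real_, NA_real_))
    ok <- which(!is.na(tr$centroids_px[, 1L]))
    if (length(ok) == 0L) return(c(NA_real_, NA_real_))
    tr$centroids_px[ok[1L], ]
  }, numeric(2)))
  dist_um <- rep(NA_real_, nrow(ref))
  has <- !is.na(ref[, 1L])
  dist_um[has] <- interp_field(field$values, ref[has, , drop = FALSE])
  inside <- !is.na(dist_um) & dist_um >= 0
  if (any(has & !inside)) {
    warning(sprintf("%d organelle(s) outside the cell mask excluded",
                    sum(has & !inside)))
  }
  d <- dist_um[inside]
  mot <- motility$motile[inside]
  sem <- function(v) if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_
  res <- list(
    all_mean_um = mean(d), all_sem_um = sem(d), n_all = length(d),
    motile_mean_um = if (any(mot)) mean(d[mot]) else NA_real_,
    motile_sem_um = if (any(mot)) sem(d[mot]) else NA_real_,
    n_motile = sum(mot),
    distances_um = dist_um, motile = motility$motile,
    alpha = 0.05
  )
  if (any(mot) && any(!mot) && sum(mot) > 1L && sum(!mot) > 1L &&
      (sd(d[mot]) > 0 || sd(d[!mot]) > 0)) {
    tt <- t.test(d[mot], d[!mot])
    res$test <- list(t = unname(tt$statistic), p_value = tt$p.value)
  } else {
    res$test <- NULL
    res$note <- if (!any(mot)) "no motile organelles" else
      "too few organelles in one group for a test"
  }
  structure(res, class = "edge_distance_report")
}

#' @export
print.edge_distance_report <- function(x, ...) {
  cat(sprintf(
    "<edge_distance_report> all: %.2f +/- %.2f um (n = %d)\n",
    x$all_mean_um, x$all_sem_um, x$n_all))
  if (!is.na(x$motile_mean_um)) {
    cat(sprintf("  motile: %.2f +/- %.2f um (n = %d)\n",
                x$motile_mean_um, x$motile_sem_um, x$n_motile))
  }
  if (!is.null(x$test)) {
    cat(sprintf("  motile vs non-motile: t = %.2f, p = %.3g\n",
                x$test$t, x$test$p_value))
  } else if (!is.null(x$note)) cat("  ", x$note, "\n")
  invisible(x)
}
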