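#' Rolling fully-polarized baseline (All_On stack)
#'
#' Estimates, for every pixel and frame, the fluorescence that would be
#' seen if every organelle under the pixel were fully polarized: the
#' arithmetic mean of the brightest 20% of that pixel's intensities within
#' a rolling time window `[t - w, t + w]` (w frames each side), clamped at
#' the ends of the recording. The number of values averaged is
#' `ceiling(0.2 * window_length)`, so at least one value always
#' contributes. The rolling baseline absorbs slow photobleaching and
#' minor cell movement while ignoring the transient dips caused by
#' flickers.
#'
#' @param stack a [fluorescence_stack()].
#' @param window_seconds half-window, seconds (default 60). Converted to
#'   frames via the stack's frame interval; must be at least one frame.
#' @return list of class `allon_stack`: `values` (array shaped like the
#'   input) and `window_frames` (the half-window in frames).
#' @export
compute_all_on <- function(stack, window_seconds = 60) {
  stopifnot(inherits(stack, "flstack"))
  if (!is.numeric(window_seconds) || window_seconds <= 0) {
    stop("window_seconds must be > 0")
  }
  w <- as.integer(round(window_seconds / stack$frame_interval_s))
  if (w < 1L) stop("baseline window is shorter than one frame")
  vals <- cpp_all_on(as.numeric(stack$intensities), stack$nx, stack$ny,
                     stack$n, w)
  structure(list(values = vals, window_frames = w), class = "allon_stack")
}

#' Instantaneous depolarization stack (Delta)
#'
#' `Delta = All_On - I`, elementwise: zero for a fully polarized pixel,
#' large and positive during a depolarization flicker.
#'
#' @param stack a [fluorescence_stack()].
#' @param all_on the matching [compute_all_on()] result.
#' @return list of class `delta_stack` with field `values`.
#' @export
compute_delta <- function(stack, all_on) {
  stopifnot(inherits(stack, "flstack"), inherits(all_on, "allon_stack"))
  if (!identical(dim(stack$intensities), dim(all_on$values))) {
    stop("stack and All_On shapes differ")
  }
  structure(list(values = all_on$values - stack$intensities),
            class = "delta_stack")
}

#' Depolarization-rate stack (dD/dt)
#'
#' Central two-point finite difference of the Delta stack over a stencil
#' of `dt` frames: `dDdt(t) = Delta(t + dt/2) - Delta(t - dt/2)`. `dt` in
#' frames must be even (so `dt/2` is an integer) and at least 2. Frames
#' where the stencil would reach outside the recording are set to `NA`
#' and excluded from downstream covariance computation; zero-padding them
#' would inject spurious covariance.
#'
#' @param delta a [compute_delta()] result.
#' @param dt_seconds differentiation period, seconds (default 4).
#' @param frame_interval_s seconds per frame.
#' @return list of class `ddt_stack`: `values` (array, `NA` at the
#'   boundary frames), `dt_frames`, `valid_t` (0-based first/last valid
#'   frame indices).
#' @export
compute_ddt <- function(delta, dt_seconds = 4, frame_interval_s) {
  stopifnot(inherits(delta, "delta_stack"))
  dt <- as.integer(round(dt_seconds / frame_interval_s))
  if (dt < 2L || dt %% 2L != 0L) {
    stop(sprintf("dt of %d frames is invalid: need an even count >= 2 so dt/2 is an integer", dt))
  }
  d <- dim(delta$values)
  n <- d[3L]
  h <- dt %/% 2L
  if (n <= dt) stop("recording shorter than the differentiation stencil")
  vals <- array(NA_real_, d)
  # 1-based: frame i holds Delta(i + h) - Delta(i - h), valid for
  # i in (h+1) .. (n-h)
  idx <- (h + 1L):(n - h)
  vals[, , idx] <- delta$values[, , idx + h, drop = FALSE] -
    delta$values[, , idx - h, drop = FALSE]
  structure(list(values = vals, dt_frames = dt,
                 valid_t = c(h, n - h - 1L)),
            class = "ddt_stack")
}

#' Seeded temporal covariance map
#'
#' For a seed pixel `(xs, ys)`, computes the temporal covariance of every
#' pixel's dD/dt series with the seed's series over a square region
#' (default 40 x 40: `xs - 20 <= x < xs + 20`, likewise in y, clipped at
#' image borders). The covariance is the population covariance
#' `sum((a - mean(a)) * (b - mean(b))) / m` over the `m` frames where the
#' derivative stencil is defined. The map is then normalized by its
#' maximum, which discards the (inseparable) variance and brightness
#' information and leaves a relative map with maximum exactly 1.
#'
#' If the seed series has zero variance, or the raw maximum is not
#' positive, there is no usable flicker at the seed and the map is
#' returned with `status = "no_flicker"`.
#'
#' @param ddt a [compute_ddt()] result.
#' @param seed a [seed_point()] (0-based).
#' @param region_half half-width of the region in pixels (default 20).
#' @return list of class `covariance_map`: `raw`, `normalized` (matrices
#'   over the clipped region), `x0`, `y0` (0-based origin of the region),
#'   `seed`, `status` ("ok" or "no_flicker").
#' @export
covariance_map <- function(ddt, seed, region_half = 20L) {
  stopifnot(inherits(ddt, "ddt_stack"), inherits(seed, "seed_point"))
  d <- dim(ddt$values)
  check_seed(seed, d[1L], d[2L])
  rh <- as.integer(region_half)
  if (rh < 1L) stop("region_half must be >= 1")
  # 0-based half-open [xs - rh, xs + rh), clipped to the image
  x0 <- max(0L, seed$xs - rh); x1 <- min(d[1L] - 1L, seed$xs + rh - 1L)
  y0 <- max(0L, seed$ys - rh); y1 <- min(d[2L] - 1L, seed$ys + rh - 1L)
  tt <- (ddt$valid_t[1L]:ddt$valid_t[2L]) + 1L
  m <- length(tt)
  region <- ddt$values[(x0:x1) + 1L, (y0:y1) + 1L, tt, drop = FALSE]
  rx <- x1 - x0 + 1L; ry <- y1 - y0 + 1L
  M <- matrix(region, nrow = rx * ry, ncol = m)
  b <- ddt$values[seed$xs + 1L, seed$ys + 1L, tt]
  bc <- b - mean(b)
  if (sum(bc * bc) == 0) {
    return(structure(list(raw = NULL, normalized = NULL, x0 = x0, y0 = y0,
                          seed = seed, status = "no_flicker"),
                     class = "covariance_map"))
  }
  # sum(bc) == 0, so M %*% bc / m is exactly the population covariance
  raw <- matrix(as.vector(M %*% bc) / m, rx, ry)
  mx <- max(raw)
  if (mx <= 0) {
    return(structure(list(raw = raw, normalized = NULL, x0 = x0, y0 = y0,
                          seed = seed, status = "no_flicker"),
                     class = "covariance_map"))
  }
  structure(list(raw = raw, normalized = raw / mx, x0 = x0, y0 = y0,
                 seed = seed, status = "ok"),
            class = "covariance_map")
}

# 8-connected flood fill over a logical matrix, from 1-based (i, j).
# Returns a logical matrix marking the component containing the start.
flood_fill8 <- function(above, i0, j0) {
  nr <- nrow(above); nc <- ncol(above)
  comp <- matrix(FALSE, nr, nc)
  if (!above[i0, j0]) return(comp)
  queue <- integer(nr * nc)
  queue[1L] <- (j0 - 1L) * nr + i0
  comp[i0, j0] <- TRUE
  qh <- 1L; qt <- 1L
  while (qh <= qt) {
    lin <- queue[qh]; qh <- qh + 1L
    j <- (lin - 1L) %/% nr + 1L
    i <- lin - (j - 1L) * nr
    for (dj in -1L:1L) {
      jj <- j + dj
      if (jj < 1L || jj > nc) next
      for (di in -1L:1L) {
        if (di == 0L && dj == 0L) next
        ii <- i + di
        if (ii < 1L || ii > nr) next
        if (above[ii, jj] && !comp[ii, jj]) {
          comp[ii, jj] <- TRUE
          qt <- qt + 1L
          queue[qt] <- (jj - 1L) * nr + ii
        }
      }
    }
  }
  comp
}

#' Threshold a covariance map and flood-fill from the seed
#'
#' Applies the covariance threshold (default +0.4) to the normalized map
#' and keeps only the 8-connected component containing the seed pixel,
#' excluding the occasional distant pixel that exceeds the threshold by
#' chance. If the seed pixel itself is below threshold the seed is
#' rejected (`status = "seed_below_threshold"`).
#'
#' @param cov a [covariance_map()] result.
#' @param threshold normalized covariance threshold, default 0.4.
#' @return list of class `mito_mask`: `pixels` (integer matrix of 0-based
#'   `(x, y)` rows), `seed`, `area_px`, `threshold`, `status`.
#' @export
threshold_and_fill <- function(cov, threshold = 0.4) {
  stopifnot(inherits(cov, "covariance_map"))
  if (cov$status != "ok") {
    return(structure(list(pixels = NULL, seed = cov$seed, area_px = 0L,
                          threshold = threshold, status = cov$status),
                     class = "mito_mask"))
  }
  i0 <- cov$seed$xs - cov$x0 + 1L
  j0 <- cov$seed$ys - cov$y0 + 1L
  above <- cov$normalized >= threshold
  if (!above[i0, j0]) {
    return(structure(list(pixels = NULL, seed = cov$seed, area_px = 0L,
                          threshold = threshold,
                          status = "seed_below_threshold"),
                     class = "mito_mask"))
  }
  comp <- flood_fill8(above, i0, j0)
  w <- which(comp, arr.ind = TRUE)
  pixels <- cbind(x = w[, 1L] - 1L + cov$x0, y = w[, 2L] - 1L + cov$y0)
  structure(list(pixels = pixels, seed = cov$seed,
                 area_px = nrow(pixels), threshold = threshold,
                 status = "ok"),
            class = "mito_mask")
}

#' Build a mitochondrion mask directly from a pixel set
#'
#' Convenience constructor used when masks originate outside the
#' covariance pipeline (simulator ground truth, label images read from
#' disk). Pixels are 0-based `(x, y)` rows.
#'
#' @param pixels two-column matrix of 0-based pixel coordinates.
#' @param seed optional [seed_point()]; defaults to the rounded centroid.
#' @param status mask status string.
#' @return `mito_mask` object.
#' @export
mito_mask <- function(pixels, seed = NULL, status = "ok") {
  pixels <- matrix(as.integer(pixels), ncol = 2L,
                   dimnames = list(NULL, c("x", "y")))
  if (nrow(pixels) < 1L) stop("mask needs at least one pixel")
  if (is.null(seed)) {
    seed <- seed_point(round(mean(pixels[, 1L])), round(mean(pixels[, 2L])))
  }
  structure(list(pixels = pixels, seed = seed, area_px = nrow(pixels),
                 threshold = NA_real_, status = status),
            class = "mito_mask")
}

#' @export
print.mito_mask <- function(x, ...) {
  cat(sprintf("<mito_mask> seed (%d, %d), %d px, status: %s\n",
              x$seed$xs, x$seed$ys, x$area_px, x$status))
  invisible(x)
}

#' Segment a stack from a list of seed points
#'
#' Runs the full covariance pipeline: rolling baseline, depolarization
#' stack, temporal derivative (computed once for the whole stack), then a
#' covariance map, threshold and flood fill per seed. Failures at one
#' seed (no flicker, seed below threshold) are reported in that mask's
#' `status` and do not abort the run. Masks from distinct seeds are kept
#' separately even when they overlap: electrically discrete organelles
#' may overlap optically.
#'
#' @param stack a [fluorescence_stack()].
#' @param seeds list of [seed_point()] (or a two-column matrix of 0-based
#'   coordinates).
#' @param window_seconds,dt_seconds,region_half,threshold pipeline
#'   parameters; defaults 60 s, 4 s, 20 px (40 x 40 region), +0.4.
#' @return list of class `falm_segmentation`: `masks` (list of
#'   `mito_mask`, one per seed, in input order), `params`.
#' @export
segment_stack <- function(stack, seeds, window_seconds = 60,
                          dt_seconds = 4, region_half = 20L,
                          threshold = 0.4) {
  stopifnot(inherits(stack, "flstack"))
  if (is.matrix(seeds) || is.data.frame(seeds)) {
    seeds <- apply(as.matrix(seeds)[, 1:2, drop = FALSE], 1L,
                   function(r) seed_point(r[1L], r[2L]), simplify = FALSE)
  }
  if (length(seeds) < 1L) stop("at least one seed point is required")
  allon <- compute_all_on(stack, window_seconds)
  delta <- compute_delta(stack, allon)
  ddt <- compute_ddt(delta, dt_seconds, stack$frame_interval_s)
  masks <- lapply(seeds, function(s) {
    threshold_and_fill(covariance_map(ddt, s, region_half), threshold)
  })
  structure(list(masks = masks,
                 params = list(window_seconds = window_seconds,
                               dt_seconds = dt_seconds,
                               region_half = region_half,
                               threshold = threshold)),
            class = "falm_segmentation")
}

#' Suggest seed points from the derivative stack
#'
#' Automatic replacement for interactive seed clicking: ranks local
#' maxima of the per-pixel temporal maximum of |dD/dt| and greedily keeps
#' peaks at least `min_separation` pixels (Chebyshev distance) apart.
#' Deterministic given its inputs; may return an empty list.
#'
#' @param ddt a [compute_ddt()] result.
#' @param min_peak minimum peak height in |dD/dt| units; by default a
#'   quarter of the strongest peak, which suppresses background while
#'   keeping any organelle within 4x of the brightest flicker.
#' @param min_separation minimum spacing between accepted seeds, pixels.
#' @return list of [seed_point()] objects, strongest first.
#' @export
suggest_seeds <- function(ddt, min_peak = NULL, min_separation = 5L) {
  stopifnot(inherits(ddt, "ddt_stack"))
  tt <- (ddt$valid_t[1L]:ddt$valid_t[2L]) + 1L
  score <- apply(abs(ddt$values[, , tt, drop = FALSE]), c(1L, 2L), max)
  if (is.null(min_peak)) min_peak <- 0.25 * max(score)
  nx <- nrow(score); ny <- ncol(score)
  # local maximum: >= all 8 neighbours (image border padded with -Inf)
  pad <- matrix(-Inf, nx + 2L, ny + 2L)
  pad[2:(nx + 1L), 2:(ny + 1L)] <- score
  is_max <- score >= min_peak
  for (di in -1L:1L) for (dj in -1L:1L) {
    if (di == 0L && dj == 0L) next
    is_max <- is_max &
      score >= pad[(2:(nx + 1L)) + di, (2:(ny + 1L)) + dj]
  }
  cand <- which(is_max, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(list())
  ord <- order(score[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  kept <- matrix(integer(0), 0L, 2L)
  for (r in seq_len(nrow(cand))) {
    p <- cand[r, ]
    if (nrow(kept) == 0L ||
        all(pmax(abs(kept[, 1L] - p[1L]),
                 abs(kept[, 2L] - p[2L])) >= min_separation)) {
      kept <- rbind(kept, p)
    }
  }
  apply(kept, 1L, function(r) seed_point(r[1L] - 1L, r[2L] - 1L),
        simplify = FALSE)
}
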