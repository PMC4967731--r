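#' Pixel corner points of a mask
#'
#' The point set used for ellipse fitting is the set of distinct pixel
#' corners, not centres: each mask pixel `(x, y)` contributes the four
#' corners `(x, y)`, `(x+1, y)`, `(x, y+1)`, `(x+1, y+1)` and shared
#' corners are deduplicated. Using corners gives a one-pixel organelle a
#' non-zero length.
#'
#' @param mask a `mito_mask`.
#' @return numeric matrix of distinct corner coordinates (columns x, y).
#' @export
mask_corner_points <- function(mask) {
  stopifnot(inherits(mask, "mito_mask"))
  if (is.null(mask$pixels) || nrow(mask$pixels) == 0L) {
    stop("mask has no pixels")
  }
  px <- mask$pixels
  corners <- rbind(
    px,
    cbind(px[, 1L] + 1L, px[, 2L]),
    cbind(px[, 1L], px[, 2L] + 1L),
    cbind(px[, 1L] + 1L, px[, 2L] + 1L)
  )
  corners <- unique(corners)
  colnames(corners) <- c("x", "y")
  matrix(as.numeric(corners), ncol = 2L,
         dimnames = list(NULL, c("x", "y")))
}

#' Minimum bounding ellipse (minimum-volume enclosing ellipse)
#'
#' Fits the smallest-area ellipse containing every input point, with
#' centre, axis lengths and rotation free, by Khachiyan's iterative
#' reweighting. After convergence the quadratic form is rescaled so that
#' every point satisfies the ellipse inequality exactly (at most a
#' `1 + tolerance` area inflation), making the containment contract
#' unconditional. Degenerate inputs (fewer than 3 points, or collinear
#' points) fall back to the minimal enclosing circle of the farthest
#' point pair.
#'
#' @param points numeric matrix with two columns (x, y).
#' @param tolerance Khachiyan convergence tolerance (default 1e-4).
#' @param max_iter iteration cap; exceeding it is reported as a failed
#'   convergence.
#' @return list of class `ellipse_fit`: `centre` (x, y),
#'   `major_axis_length`, `minor_axis_length` (full lengths, same units
#'   as the points), `rotation` (radians in `[0, pi)`, major axis),
#'   `converged`, `degenerate`.
#' @export
min_bounding_ellipse <- function(points, tolerance = 1e-4,
                                 max_iter = 10000L) {
  points <- matrix(as.numeric(points), ncol = 2L)
  if (nrow(points) < 1L || anyNA(points)) {
    stop("at least one finite point is required")
  }
  points <- unique(points)
  np <- nrow(points)
  ctr <- colMeans(points)
  centred <- sweep(points, 2L, ctr)
  if (np < 3L || qr(centred)$rank < 2L) {
    # collinear / tiny sets: minimal enclosing circle of the farthest pair
    dmat <- as.matrix(dist(points))
    ij <- which(dmat == max(dmat), arr.ind = TRUE)[1L, ]
    c0 <- (points[ij[1L], ] + points[ij[2L], ]) / 2
    r <- max(sqrt(rowSums(sweep(points, 2L, c0)^2)))
    return(structure(list(centre = c0, major_axis_length = 2 * r,
                          minor_axis_length = 2 * r, rotation = 0,
                          converged = TRUE, degenerate = TRUE),
                     class = "ellipse_fit"))
  }
  d <- 2L
  Q <- t(cbind(points, 1))            # (d+1) x N lifted points
  Qt <- t(Q)
  u <- rep(1 / np, np)
  converged <- FALSE
  # Khachiyan reweighting with Wolfe-Atwood "away" steps: weight is also
  # allowed to move off interior points, which converges far faster than
  # increase-only updates at tight tolerances
  for (iter in seq_len(max_iter)) {
    X <- crossprod(sqrt(u) * Qt)
    XQ <- tryCatch(solve(X, Q), error = function(e) NULL)
    if (is.null(XQ)) {       # degenerate support: restart from uniform
      u <- rep(1 / np, np)
      next
    }
    M <- colSums(Q * XQ)
    jp <- which.max(M)
    ep <- M[jp] / (d + 1) - 1
    act <- which(u > 0)
    jm <- act[which.min(M[act])]
    em <- 1 - M[jm] / (d + 1)
    if (max(ep, em) <= tolerance) {
      converged <- TRUE
      break
    }
    if (ep >= em) {
      j <- jp
      step <- (M[j] - (d + 1)) / ((d + 1) * (M[j] - 1))
    } else {
      j <- jm
      # the interior-optimal decrease only exists for M > 1; otherwise
      # the best move is to drop the point entirely
      opt <- if (M[j] > 1 + 1e-12) {
        (M[j] - (d + 1)) / ((d + 1) * (M[j] - 1))
      } else -Inf
      step <- max(opt, -u[j] / (1 - u[j]))
    }
    u <- (1 - step) * u
    u[j] <- u[j] + step
    u[u < 0] <- 0            # guard floating-point undershoot
    u <- u / sum(u)
  }
  c0 <- as.vector(t(points) %*% u)
  S <- t(points) %*% (u * points) - tcrossprod(c0)
  A <- solve(S) / d
  # enforce exact containment: scale so max quadratic form value is 1
  dc <- sweep(points, 2L, c0)
  vals <- rowSums((dc %*% A) * dc)
  s <- max(vals)
  if (s > 1) A <- A / s
  e <- eigen(A, symmetric = TRUE)
  semi <- 1 / sqrt(e$values)          # ascending in semi-axis? values desc
  # eigen() returns eigenvalues in decreasing order: semi is increasing
  major <- 2 * semi[2L]
  minor <- 2 * semi[1L]
  v <- e$vectors[, 2L]                # direction of the major axis
  rot <- atan2(v[2L], v[1L]) %% pi
  structure(list(centre = c0, major_axis_length = major,
                 minor_axis_length = minor, rotation = rot,
                 converged = converged, degenerate = FALSE),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(
    "<ellipse_fit> centre (%.3f, %.3f), axes %.3f x %.3f, rotation %.1f deg%s\n",
    x$centre[1L], x$centre[2L], x$major_axis_length, x$minor_axis_length,
    x$rotation * 180 / pi,
    if (x$degenerate) " [degenerate: enclosing circle]" else ""))
  invisible(x)
}

#' Per-organelle shape record
#'
#' Converts a mask and its bounding-ellipse fit to physical units: area
#' from the pixel count, length and width from the ellipse axes. Flags
#' the morphological cut-offs used for population fractions: `long_flag`
#' for length > 2 um and `elongated_flag` for length:width ratio > 3.
#'
#' @param mask a `mito_mask` with at least one pixel.
#' @param pixel_size_nm effective pixel size, nm.
#' @param tolerance ellipse fit tolerance, passed to
#'   [min_bounding_ellipse()].
#' @return list of class `shape_record`: `area_um2`, `length_um`,
#'   `width_um`, `aspect_ratio`, `long_flag`, `elongated_flag`,
#'   `degenerate`, `area_px`, `fit`.
#' @export
shape_record <- function(mask, pixel_size_nm = 225, tolerance = 1e-4) {
  stopifnot(inherits(mask, "mito_mask"))
  px_um <- pixel_size_nm / 1000
  fit <- min_bounding_ellipse(mask_corner_points(mask), tolerance)
  degenerate <- fit$degenerate || fit$minor_axis_length <= 0
  aspect <- if (degenerate) NA_real_ else
    fit$major_axis_length / fit$minor_axis_length
  length_um <- fit$major_axis_length * px_um
  width_um <- fit$minor_axis_length * px_um
  structure(list(
    area_um2 = mask$area_px * px_um^2,
    length_um = length_um,
    width_um = width_um,
    aspect_ratio = aspect,
    long_flag = length_um > 2,
    elongated_flag = !degenerate && aspect > 3,
    degenerate = degenerate,
    area_px = mask$area_px,
    fit = fit
  ), class = "shape_record")
}

#' Fraction of the cell occupied by mitochondria
#'
#' Occupancy is the area of the union of all organelle masks, intersected
#' with the cell mask, divided by the cell area. Mask pixels outside the
#' cell are clipped (with a warning) rather than counted.
#'
#' @param cell_mask logical or 0/1 matrix indexed `[x, y]`.
#' @param masks list of `mito_mask` objects.
#' @return list of class `occupancy_record`: `cell_area_px`,
#'   `mito_area_px`, `fraction`.
#' @export
occupancy <- function(cell_mask, masks) {
  cell <- cell_mask != 0
  cell_area <- sum(cell)
  if (cell_area == 0L) stop("cell mask is empty")
  nx <- nrow(cell); ny <- ncol(cell)
  union <- matrix(FALSE, nx, ny)
  clipped <- 0L
  for (m in masks) {
    if (!inherits(m, "mito_mask") || is.null(m$pixels)) next
    px <- m$pixels
    keep <- px[, 1L] >= 0L & px[, 1L] < nx & px[, 2L] >= 0L & px[, 2L] < ny
    px <- px[keep, , drop = FALSE]
    lin <- px[, 1L] + 1L + px[, 2L] * nx
    inside <- cell[lin]
    clipped <- clipped + sum(!keep) + sum(!inside)
    union[lin[inside]] <- TRUE
  }
  if (clipped > 0L) {
    warning(sprintf("%d organelle pixels outside the cell mask were clipped",
                    clipped))
  }
  mito_area <- sum(union)
  structure(list(cell_area_px = cell_area, mito_area_px = mito_area,
                 fraction = mito_area / cell_area),
            class = "occupancy_record")
}

#' Population summary of organelle shapes
#'
#' Summarizes a list of [shape_record()]s: geometric mean area (with a
#' back-transformed log-SEM), modal area, 95th percentile area (type-7
#' quantile), mean of the largest `ceiling(0.05 n)` organelles, and the
#' fractions of long (> 2 um) and elongated (ratio > 3) organelles.
#' Because mask areas are integer pixel counts, the mode is estimated on
#' a histogram whose bins are centred on integer multiples of the
#' single-pixel area (0.050625 um^2 at 225 nm) and reported as the bin
#' centre, i.e. the most frequent pixel count times the pixel area.
#'
#' @param records list of `shape_record`s (n >= 1).
#' @param pixel_size_nm pixel size used for the mode bin width, nm.
#' @return list of class `population_summary`.
#' @export
summarize_population <- function(records, pixel_size_nm = 225) {
  if (length(records) < 1L) stop("no shape records")
  areas <- vapply(records, function(r) r$area_um2, numeric(1))
  area_px <- vapply(records, function(r) r$area_px, numeric(1))
  long <- vapply(records, function(r) isTRUE(r$long_flag), logical(1))
  degen <- vapply(records, function(r) isTRUE(r$degenerate), logical(1))
  elong <- vapply(records, function(r) isTRUE(r$elongated_flag), logical(1))
  n <- length(areas)
  pos <- areas[areas > 0]
  gm <- exp(mean(log(pos)))
  gm_sem <- if (length(pos) > 1L) {
    gm * sd(log(pos)) / sqrt(length(pos))
  } else NA_real_
  px_area <- (pixel_size_nm / 1000)^2
  counts <- table(area_px)
  mode_px <- as.numeric(names(counts)[which.max(counts)])
  k <- ceiling(0.05 * n)
  top <- sort(areas, decreasing = TRUE)[seq_len(k)]
  structure(list(
    n = n,
    geometric_mean_area = gm,
    geometric_mean_area_sem = gm_sem,
    mode_area = mode_px * px_area,
    p95_area = unname(quantile(areas, 0.95, type = 7)),
    mean_top5pct_area = mean(top),
    n_top5pct = k,
    fraction_long = mean(long),
    fraction_elongated = mean(elong[!degen]),
    n_degenerate = sum(degen)
  ), class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<population_summary> n = %d\n",
           "  geometric mean area %.3f +/- %.3f um^2, mode %.3f um^2\n",
           "  95th percentile %.2f um^2, mean of largest 5%% %.2f um^2 (n = %d)\n",
           "  long (>2 um): %.1f%%, elongated (ratio > 3): %.1f%%\n"),
    x$n, x$geometric_mean_area, x$geometric_mean_area_sem, x$mode_area,
    x$p95_area, x$mean_top5pct_area, x$n_top5pct,
    100 * x$fraction_long, 100 * x$fraction_elongated))
  invisible(x)
}

# pooled two-proportion z statistic
prop_z_test <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  p <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2)
}

#' Compare two organelle populations
#'
#' Areas are compared with a two-sample Kolmogorov-Smirnov test (the
#' area distributions are far from normal). Each morphological
#' proportion (long, elongated) is compared two ways: a pooled
#' two-proportion z-test, and an unpaired t test on the 0/1 indicator
#' vectors; both are reported. Significance threshold 0.05.
#'
#' @param a,b lists of `shape_record`s.
#' @return list of class `population_comparison`: `ks` (statistic,
#'   p_value), `proportions` (data frame with z and t results per
#'   metric), `alpha`.
#' @export
compare_populations <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) stop("both populations must be non-empty")
  area_a <- vapply(a, function(r) r$area_um2, numeric(1))
  area_b <- vapply(b, function(r) r$area_um2, numeric(1))
  # areas are pixel-quantized so ties are expected; use the asymptotic KS
  ks <- suppressWarnings(ks.test(area_a, area_b, exact = FALSE))
  flag_tab <- lapply(c(long = "long_flag", elongated = "elongated_flag"),
                     function(f) {
    ia <- vapply(a, function(r) as.numeric(isTRUE(r[[f]])), numeric(1))
    ib <- vapply(b, function(r) as.numeric(isTRUE(r[[f]])), numeric(1))
    zt <- prop_z_test(sum(ia), length(ia), sum(ib), length(ib))
    tt <- if (sd(ia) == 0 && sd(ib) == 0) {
      list(statistic = c(t = 0), p.value = 1)
    } else t.test(ia, ib)
    data.frame(p_a = zt$p1, p_b = zt$p2, z = zt$z, p_z = zt$p_value,
               t = unname(tt$statistic), p_t = tt$p.value)
  })
  props <- do.call(rbind, flag_tab)
  props <- cbind(metric = rownames(props), props)
  rownames(props) <- NULL
  structure(list(
    ks = list(statistic = unname(ks$statistic), p_value = ks$p.value),
    proportions = props,
    alpha = 0.05
  ), class = "population_comparison")
}

#' @export
print.population_comparison <- function(x, ...) {
  cat(sprintf("<population_comparison> KS D = %.4f, p = %.3g\n",
              x$ks$statistic, x$ks$p_value))
  print(x$proportions)
  invisible(x)
}
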