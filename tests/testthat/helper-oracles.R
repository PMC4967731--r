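# Independent brute-force oracles used across the suite. These stay
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can arbitrate.

# rolling brightest-20% mean, evaluated directly per (x, y, t)
oracle_all_on <- function(arr, half_window) {
  d <- dim(arr)
  out <- array(NA_real_, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) {
    for (t in seq_len(d[3])) {
      t0 <- max(1L, t - half_window)
      t1 <- min(d[3], t + half_window)
      win <- sort(arr[x, y, t0:t1], decreasing = TRUE)
      k <- ceiling(0.2 * length(win))
      out[x, y, t] <- mean(win[seq_len(k)])
    }
  }
  out
}

# population covariance of two series by explicit summation
oracle_cov <- function(a, b) {
  m <- length(a)
  am <- sum(a) / m
  bm <- sum(b) / m
  s <- 0
  for (t in seq_len(m)) s <- s + (a[t] - am) * (b[t] - bm)
  s / m
}

# fraction of truth pixels recovered by a mask
mask_recall <- function(truth_px, mask) {
  if (mask$status != "ok") return(0)
  truth_key <- paste(truth_px[, 1], truth_px[, 2])
  got_key <- paste(mask$pixels[, 1], mask$pixels[, 2])
  mean(truth_key %in% got_key)
}

mask_jaccard <- function(truth_px, mask) {
  if (mask$status != "ok") return(0)
  a <- paste(truth_px[, 1], truth_px[, 2])
  b <- paste(mask$pixels[, 1], mask$pixels[, 2])
  length(intersect(a, b)) / length(union(a, b))
}

# smallest enclosing ellipse found by a refining grid search over centre
# and rotation; for each candidate (centre, angle) the optimal axes are
# computed exactly by maximizing a*b over the feasible polytope of
# (1/a^2, 1/b^2), whose optimum lies on a vertex or a tangency point.
oracle_mbe_area <- function(points) {
  best_axes_area <- function(u2, v2) {
    # maximize alpha*beta s.t. u2*alpha + v2*beta <= 1, alpha, beta > 0
    # returns the minimal ellipse area pi/sqrt(alpha*beta)
    cand <- list()
    n <- length(u2)
    for (i in seq_len(n)) {
      if (u2[i] > 0 && v2[i] > 0) {
        cand[[length(cand) + 1]] <- c(1 / (2 * u2[i]), 1 / (2 * v2[i]))
      }
    }
    if (n >= 2) {
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        den <- u2[i] * v2[j] - u2[j] * v2[i]
        if (abs(den) < 1e-14) next
        a <- (v2[j] - v2[i]) / den
        b <- (u2[i] - u2[j]) / den
        if (a > 1e-12 && b > 1e-12) cand[[length(cand) + 1]] <- c(a, b)
      }
    }
    best <- Inf
    for (ab in cand) {
      if (all(u2 * ab[1] + v2 * ab[2] <= 1 + 1e-9)) {
        area <- pi / sqrt(ab[1] * ab[2])
        if (area < best) best <- area
      }
    }
    best
  }
  eval_grid <- function(cxs, cys, angs) {
    best <- list(area = Inf)
    for (ang in angs) {
      ca <- cos(ang); sa <- sin(ang)
      for (cx in cxs) for (cy in cys) {
        u <- (points[, 1] - cx) * ca + (points[, 2] - cy) * sa
        v <- -(points[, 1] - cx) * sa + (points[, 2] - cy) * ca
        area <- best_axes_area(u^2, v^2)
        if (area < best$area) best <- list(area = area, cx = cx, cy = cy,
                                           ang = ang)
      }
    }
    best
  }
  rng_x <- range(points[, 1]); rng_y <- range(points[, 2])
  span <- max(diff(rng_x), diff(rng_y), 1e-6)
  cxs <- seq(rng_x[1], rng_x[2], length.out = 7)
  cys <- seq(rng_y[1], rng_y[2], length.out = 7)
  angs <- seq(0, pi, length.out = 19)[-19]
  best <- eval_grid(cxs, cys, angs)
  dc <- span / 6; da <- pi / 18
  for (ref in 1:4) {
    cxs <- seq(best$cx - dc, best$cx + dc, length.out = 5)
    cys <- seq(best$cy - dc, best$cy + dc, length.out = 5)
    angs <- seq(best$ang - da, best$ang + da, length.out = 5)
    best <- eval_grid(cxs, cys, angs)
    dc <- dc / 2; da <- da / 2
  }
  best$area
}

ellipse_area <- function(fit) {
  pi * fit$major_axis_length * fit$minor_axis_length / 4
}

# centroid seeds for a scene truth
truth_seeds <- function(truth) {
  lapply(truth$footprints, function(fp) {
    seed_point(round(mean(fp[, 1])), round(mean(fp[, 2])))
  })
}
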