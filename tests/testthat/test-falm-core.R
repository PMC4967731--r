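test_that("rolling baseline reproduces hand-derived and brute-force values", {
  # constant stack: mean of brightest 20% of a constant is the constant
  st <- fluorescence_stack(array(7, c(3, 3, 20)), 225, 1)
  ao <- compute_all_on(st, 5)
  expect_true(all(ao$values == 7))

  # single spike of 10 in 10 frames, full-stack window: top 20% of 10
  # values is {10, 0}, mean 5
  st <- fluorescence_stack(array(c(0, 0, 0, 0, 10, 0, 0, 0, 0, 0),
                                 c(1, 1, 10)), 225, 1)
  ao <- compute_all_on(st, 20)
  expect_true(all(ao$values == 5))

  # random small stacks against the brute-force windowed evaluation,
  # including the clamped windows at both ends
  set.seed(101)
  for (rep in 1:5) {
    arr <- array(rpois(4 * 3 * 30, 50), c(4, 3, 30))
    st <- fluorescence_stack(arr, 225, 1)
    w <- sample(2:12, 1)
    ao <- compute_all_on(st, w)
    expect_equal(ao$values, oracle_all_on(arr, w), tolerance = 1e-12)
  }
})

test_that("baseline window shorter than one frame is rejected", {
  st <- fluorescence_stack(array(1, c(2, 2, 10)), 225, 1)
  expect_error(compute_all_on(st, 0.2), "shorter than one frame")
  expect_error(compute_all_on(st, -1), "window_seconds")
})

test_that("depolarization stack is All_On minus intensity", {
  st <- fluorescence_stack(array(7, c(2, 2, 10)), 225, 1)
  ao <- compute_all_on(st, 3)
  expect_true(all(compute_delta(st, ao)$values == 0))

  # dip from 10 to 2 while the baseline holds 10 gives Delta = 8
  series <- rep(10, 40); series[15:20] <- 2
  st <- fluorescence_stack(array(series, c(1, 1, 40)), 225, 1)
  ao <- compute_all_on(st, 40)
  expect_true(all(ao$values == 10))
  delta <- compute_delta(st, ao)
  expect_equal(as.vector(delta$values[1, 1, 15:20]), rep(8, 6))
  expect_equal(as.vector(delta$values[1, 1, 1:14]), rep(0, 14))

  bad <- compute_all_on(fluorescence_stack(array(1, c(3, 3, 10)), 225, 1), 3)
  expect_error(compute_delta(st, bad), "shapes differ")
})

test_that("temporal derivative applies the two-point stencil and drops boundaries", {
  # Delta steps 0 -> 8 at frame 50 (0-based), dt = 40 frames:
  # dD/dt = 8 exactly for t in [30, 69], 0 on other interior frames
  n <- 100
  series <- rep(0, n); series[51:n] <- 8   # 1-based frame 51 = 0-based 50
  delta <- structure(list(values = array(series, c(1, 1, n))),
                     class = "delta_stack")
  ddt <- compute_ddt(delta, dt_seconds = 40, frame_interval_s = 1)
  expect_equal(ddt$dt_frames, 40L)
  v <- as.vector(ddt$values[1, 1, ])
  expect_equal(which(!is.na(v)) - 1L, 20:79)          # valid stencil range
  expect_equal(v[(30:69) + 1L], rep(8, 40))
  expect_equal(v[(20:29) + 1L], rep(0, 10))
  expect_equal(v[(70:79) + 1L], rep(0, 10))

  # at 10 Hz, 4 s corresponds to a stencil half-width of 20 frames
  ddt10 <- compute_ddt(structure(list(values = array(0, c(1, 1, 100))),
                                 class = "delta_stack"), 4, 0.1)
  expect_equal(ddt10$dt_frames, 40L)
  expect_equal(ddt10$valid_t, c(20L, 79L))

  expect_error(compute_ddt(delta, 41, 1), "even")
  expect_error(compute_ddt(delta, 1, 1), "even")
})

test_that("covariance map matches the brute-force estimator and normalizes to 1", {
  set.seed(7)
  arr <- array(rnorm(8 * 8 * 60), c(8, 8, 60))
  ddt <- structure(list(values = arr, dt_frames = 2L,
                        valid_t = c(0L, 59L)),
                   class = "ddt_stack")
  cm <- covariance_map(ddt, seed_point(4, 4), region_half = 20)
  expect_equal(cm$status, "ok")
  expect_equal(dim(cm$raw), c(8L, 8L))   # clipped at the borders
  b <- arr[5, 5, ]
  for (x in 1:8) for (y in 1:8) {
    expect_equal(cm$raw[x, y], oracle_cov(arr[x, y, ], b),
                 tolerance = 1e-12)
  }
  # covariance of the seed with itself is its variance
  expect_equal(cm$raw[5, 5], oracle_cov(b, b))
  expect_equal(max(cm$normalized), 1)

  # anti-phase pixel: cov(a, -a + c) = -var(a)
  arr2 <- arr
  arr2[1, 1, ] <- -b + 3
  ddt2 <- structure(list(values = arr2, dt_frames = 2L,
                         valid_t = c(0L, 59L)), class = "ddt_stack")
  cm2 <- covariance_map(ddt2, seed_point(4, 4), 20)
  expect_equal(cm2$raw[1, 1], -oracle_cov(b, b), tolerance = 1e-12)
  expect_lt(cm2$normalized[1, 1], 0.4)
})

test_that("constant input annihilates the pipeline and flags the seed", {
  st <- fluorescence_stack(array(5, c(10, 10, 50)), 225, 1)
  ao <- compute_all_on(st, 10)
  delta <- compute_delta(st, ao)
  expect_true(all(delta$values == 0))
  ddt <- compute_ddt(delta, 4, 1)
  expect_true(all(ddt$values[, , 3:48] == 0))
  cm <- covariance_map(ddt, seed_point(5, 5), 20)
  expect_equal(cm$status, "no_flicker")
  mask <- threshold_and_fill(cm)
  expect_equal(mask$status, "no_flicker")
})

test_that("threshold and flood fill keep only the seed's 8-connected component", {
  norm <- matrix(0, 9, 9)
  norm[5, 5] <- 1
  cm <- structure(list(raw = norm, normalized = norm, x0 = 0L, y0 = 0L,
                       seed = seed_point(4, 4), status = "ok"),
                  class = "covariance_map")
  mask <- threshold_and_fill(cm, 0.4)
  expect_equal(mask$status, "ok")
  expect_equal(mask$area_px, 1L)
  expect_equal(unname(mask$pixels[1, ]), c(4L, 4L))

  # two above-threshold blobs; only the one containing the seed is kept,
  # with a diagonal (8-connected) bridge inside the seed blob
  norm2 <- matrix(0, 9, 9)
  norm2[4:5, 4:5] <- 0.9
  norm2[6, 6] <- 0.8            # diagonal neighbour: included
  norm2[1:2, 8:9] <- 0.95       # distant blob: excluded
  cm2 <- structure(list(raw = norm2, normalized = norm2, x0 = 0L, y0 = 0L,
                        seed = seed_point(4, 4), status = "ok"),
                   class = "covariance_map")
  mask2 <- threshold_and_fill(cm2, 0.4)
  expect_equal(mask2$area_px, 5L)
  expect_false(any(mask2$pixels[, 2] >= 7))
  expect_true(any(mask2$pixels[, 1] == 5 & mask2$pixels[, 2] == 5))

  # seed below threshold is a rejected seed, not an empty mask
  norm3 <- matrix(0, 9, 9); norm3[2, 2] <- 1
  cm3 <- structure(list(raw = norm3, normalized = norm3, x0 = 0L, y0 = 0L,
                        seed = seed_point(4, 4), status = "ok"),
                   class = "covariance_map")
  expect_equal(threshold_and_fill(cm3, 0.4)$status, "seed_below_threshold")
})

test_that("masks are 8-connected components containing their seed", {
  set.seed(11)
  for (rep in 1:20) {
    norm <- matrix(runif(15 * 15, -0.2, 1), 15, 15)
    sx <- sample(0:14, 1); sy <- sample(0:14, 1)
    norm[sx + 1, sy + 1] <- 1
    cm <- structure(list(raw = norm, normalized = norm, x0 = 0L, y0 = 0L,
                         seed = seed_point(sx, sy), status = "ok"),
                    class = "covariance_map")
    mask <- threshold_and_fill(cm, 0.4)
    expect_equal(mask$status, "ok")
    key <- paste(mask$pixels[, 1], mask$pixels[, 2])
    expect_true(paste(sx, sy) %in% key)
    # every mask pixel reaches the seed through mask pixels (BFS over
    # Chebyshev-adjacent pairs)
    px <- mask$pixels
    reach <- rep(FALSE, nrow(px))
    reach[which(px[, 1] == sx & px[, 2] == sy)] <- TRUE
    repeat {
      grew <- FALSE
      for (i in which(!reach)) {
        if (any(reach & pmax(abs(px[, 1] - px[i, 1]),
                             abs(px[, 2] - px[i, 2])) == 1)) {
          reach[i] <- TRUE; grew <- TRUE
        }
      }
      if (!grew) break
    }
    expect_true(all(reach))
  }
})

test_that("two organelles with identical footprints but offset schedules share the footprint", {
  # both organelles occupy the same pixels; their flickers are offset by
  # more than dt, so each seed recovers (at least) the common footprint
  fp <- as.matrix(expand.grid(x = 8:12, y = 8:9))
  n <- 240
  t_s <- (seq_len(n) - 1) * 0.5
  f1 <- ifelse(t_s >= 20 & t_s < 25, 0.2, 1)
  f2 <- ifelse(t_s >= 60 & t_s < 65, 0.2, 1)
  arr <- array(40, c(24, 20, n))
  for (t in seq_len(n)) {
    arr[, , t][fp + 1L] <- 40 + 400 * f1[t] + 400 * f2[t]
  }
  st <- fluorescence_stack(arr, 225, 0.5)
  seg <- segment_stack(st, list(seed_point(10, 8), seed_point(10, 9)))
  for (m in seg$masks) {
    expect_equal(m$status, "ok")
    expect_gte(mask_recall(fp, m), 0.9)
  }
})

test_that("segmentation separates optically overlapping, electrically discrete organelles", {
  cfg <- scene_preset("overlap_pair", rng_seed = 7)
  truth <- build_scene(cfg)
  stack <- render_stack(truth)
  seg <- segment_stack(stack, truth_seeds(truth))
  expect_length(seg$masks, 2L)
  for (i in 1:2) {
    expect_equal(seg$masks[[i]]$status, "ok")
    expect_gte(mask_recall(truth$footprints[[i]], seg$masks[[i]]), 0.9)
  }
  # the two masks are not the same pixel set
  k1 <- paste(seg$masks[[1]]$pixels[, 1], seg$masks[[1]]$pixels[, 2])
  k2 <- paste(seg$masks[[2]]$pixels[, 1], seg$masks[[2]]$pixels[, 2])
  expect_false(setequal(k1, k2))
})

test_that("duplicate seeds inside one organelle give near-identical masks", {
  cfg <- scene_preset("overlap_pair", rng_seed = 9)
  truth <- build_scene(cfg)
  stack <- render_stack(truth)
  fp <- truth$footprints[[1]]
  seg <- segment_stack(stack, list(
    seed_point(fp[3, 1], fp[3, 2]), seed_point(fp[10, 1], fp[10, 2])))
  expect_gte(mask_jaccard(seg$masks[[1]]$pixels, seg$masks[[2]]), 0.8)
})

test_that("per-seed failures are reported without aborting the run", {
  cfg <- scene_preset("overlap_pair", rng_seed = 7)
  truth <- build_scene(cfg)
  stack <- render_stack(truth)
  seeds <- c(truth_seeds(truth), list(seed_point(2, 2)))  # background seed
  seg <- segment_stack(stack, seeds)
  st <- vapply(seg$masks, function(m) m$status, character(1))
  expect_equal(st[1:2], c("ok", "ok"))
  expect_true(st[3] != "ok")
  expect_error(segment_stack(stack, list()), "at least one seed")
})

test_that("seed suggestion finds flicker locations deterministically", {
  zero <- structure(list(values = array(0, c(10, 10, 20)), dt_frames = 2L,
                         valid_t = c(1L, 18L)), class = "ddt_stack")
  expect_length(suggest_seeds(zero, min_peak = 1), 0L)

  cfg <- scene_preset("overlap_pair", rng_seed = 13)
  truth <- build_scene(cfg)
  stack <- render_stack(truth)
  ao <- compute_all_on(stack, 60)
  ddt <- compute_ddt(compute_delta(stack, ao), 4, stack$frame_interval_s)
  seeds <- suggest_seeds(ddt, min_peak = 100, min_separation = 3)
  expect_gte(length(seeds), 2L)
  # the two strongest suggestions land inside the two organelles
  for (i in 1:2) {
    hit <- vapply(truth$footprints, function(fp) {
      any(abs(fp[, 1] - seeds[[i]]$xs) <= 1 &
            abs(fp[, 2] - seeds[[i]]$ys) <= 1)
    }, logical(1))
    expect_true(any(hit))
  }
  seeds2 <- suggest_seeds(ddt, min_peak = 100, min_separation = 3)
  expect_identical(seeds, seeds2)
})
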