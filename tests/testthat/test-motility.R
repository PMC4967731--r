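# a small helper scene: a few isolated organelles, optionally one mover
iso_scene <- function(motile_run_um = NULL, duration_s = 140,
                      drift = c(0, 0), seed = 3) {
  org <- data.frame(shape = "rod", len_px = 2L, wid_px = 2L,
                    x = c(12L, 40L, 64L), y = c(6L, 18L, 6L),
                    orientation = 0, motile = c(!is.null(motile_run_um),
                                                FALSE, FALSE))
  scene_config(nx = 80L, ny = 24L, frame_interval_s = 2,
               duration_s = duration_s, organelles = org,
               flicker = list(rate_per_min = 0),
               motility = list(
                 brownian_sigma_nm = 0,
                 speed_range_nm_s = c(95, 95),
                 distance_range_um = c(motile_run_um %||% 1,
                                       motile_run_um %||% 1)),
               drift_px_per_frame = drift, rng_seed = seed)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a static movie has zero estimated drift", {
  truth <- build_scene(iso_scene())
  cfg <- truth$config; cfg$noise$shot <- FALSE; cfg$noise$read_sigma <- 0
  truth$config <- cfg
  stack <- render_stack(truth)
  dr <- estimate_global_drift(stack)
  expect_lt(max(abs(dr)), 0.05)
})

test_that("an integer roll of the image is recovered by phase correlation", {
  set.seed(17)
  base <- matrix(rpois(60 * 40, 30), 60, 40)
  base[20:24, 10:13] <- 500
  base[40:42, 25:30] <- 350
  arr <- array(0, c(60, 40, 3))
  arr[, , 1] <- base
  arr[, , 2] <- base
  rolled <- base[c(58:60, 1:57), ]          # shift +3 in x
  rolled <- rolled[, c(3:40, 1:2)]          # shift -2 in y
  arr[, , 3] <- rolled
  st <- fluorescence_stack(arr, 225, 1)
  dr <- estimate_global_drift(st)
  expect_equal(unname(dr[2, ]), c(0, 0), tolerance = 0.05)
  expect_equal(unname(dr[3, ]), c(3, -2), tolerance = 0.05)
})

test_that("a stationary organelle shows sub-0.1 um excursion", {
  truth <- build_scene(iso_scene())
  stack <- render_stack(truth)
  masks <- lapply(truth$footprints, mito_mask)
  tracks <- track_centroids(stack, masks, interval_frames = 1,
                            drift = FALSE)
  for (tr in tracks$tracks[2:3]) {
    expect_lt(tr$max_excursion_um, 0.1)
  }
})

test_that("a 12 um directed run is recovered with its speed", {
  truth <- build_scene(iso_scene(motile_run_um = 12, seed = 5))
  stack <- render_stack(truth)
  masks <- lapply(truth$footprints, mito_mask)
  tracks <- track_centroids(stack, masks, interval_frames = 1,
                            drift = FALSE)
  expect_equal(tracks$tracks[[1]]$max_excursion_um, 12, tolerance = 0.3 / 12)
  expect_equal(tracks$tracks[[1]]$mean_speed_nm_s, 95, tolerance = 0.1)
})

test_that("motility classification is monotone in the threshold", {
  truth <- build_scene(iso_scene(motile_run_um = 3, seed = 7))
  stack <- render_stack(truth)
  masks <- lapply(truth$footprints, mito_mask)
  tracks <- track_centroids(stack, masks, interval_frames = 1,
                            drift = FALSE)
  fr <- vapply(c(0.2, 0.45, 1, 2.9, 100), function(th) {
    classify_motile(tracks, 10, th)$fraction
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_equal(fr[2], 1 / 3)                 # only the planted mover
  expect_equal(fr[5], 0)                     # threshold above any excursion
})

test_that("a whole-field drift ramp does not change classification", {
  t1 <- build_scene(iso_scene(motile_run_um = 3, seed = 9))
  s1 <- render_stack(t1)
  masks <- lapply(t1$footprints, mito_mask)
  m1 <- classify_motile(track_centroids(s1, masks, interval_frames = 1,
                                        drift = FALSE))
  t2 <- build_scene(iso_scene(motile_run_um = 3, seed = 9,
                              drift = c(0.05, -0.03)))
  s2 <- render_stack(t2)
  m2 <- classify_motile(track_centroids(s2, masks, interval_frames = 1))
  expect_identical(m1$motile, m2$motile)
  expect_equal(m1$n_motile, 1L)
})

test_that("signed distance field has the Eikonal and boundary properties", {
  # 1-pixel-wide strip: every interior pixel is half a pixel from the edge
  strip <- matrix(FALSE, 20, 9); strip[3:18, 5] <- TRUE
  f <- signed_distance(strip, 225)
  expect_equal(unique(round(f$values[4:17, 5], 9)), 0.5 * 0.225)
  expect_true(all(f$values[!strip] < 0))

  # disc of radius R: centre distance within 5% of R * pixel size
  R <- 30; n <- 120
  g <- expand.grid(x = 1:n, y = 1:n)
  disc <- matrix((g$x - 60)^2 + (g$y - 60)^2 <= R^2, n, n)
  fd <- signed_distance(disc, 225)
  expect_equal(fd$values[60, 60], R * 0.225, tolerance = 0.05)

  # distance is monotone along an inward ray of a convex mask
  ray <- fd$values[60, 31:60]
  expect_true(all(diff(ray) > 0))

  # |grad d| = 1 away from the (pixel-quantized) boundary and the
  # central skeleton; the probe band keeps ~10 px clear of both
  idx <- 2:(n - 1)
  gx <- (fd$values[idx + 1, idx] - fd$values[idx - 1, idx]) / (2 * 0.225)
  gy <- (fd$values[idx, idx + 1] - fd$values[idx, idx - 1]) / (2 * 0.225)
  gmag <- sqrt(gx^2 + gy^2)
  r <- sqrt((matrix(g$x, n, n)[idx, idx] - 60)^2 +
              (matrix(g$y, n, n)[idx, idx] - 60)^2)
  inside <- r > 12 & r < R - 10
  outside <- r > R + 10 & r < 2 * R
  expect_true(all(abs(gmag[inside] - 1) <= 0.05))
  expect_true(all(abs(gmag[outside] - 1) <= 0.05))

  expect_error(signed_distance(matrix(FALSE, 5, 5)), "empty")
})

test_that("edge-distance report orders planted peripheral movers correctly", {
  # synthetic tracks: movers planted at mean depth ~2.0 um, the rest
  # deeper (~2.5 um); ordering of the means must be recovered
  cell <- matrix(FALSE, 60, 44); cell[3:58, 3:42] <- TRUE
  field <- signed_distance(cell, 225)
  set.seed(19)
  mk_track <- function(x, y) {
    list(organelle_id = 1L,
         centroids_px = matrix(rep(c(x, y), each = 5), 5, 2),
         t_s = 0:4, max_excursion_um = 0, mean_speed_nm_s = 0,
         n_gaps = 0L, home_vacated = FALSE, status = "ok")
  }
  # depth in pixels ~ y - 2.5 for small y: movers at y ~ 11 (2.0 um),
  # non-movers at y ~ 13.6 (2.5 um)
  ys_mot <- round(rnorm(40, 11.4, 1)); ys_non <- round(rnorm(120, 13.6, 1))
  tracks <- structure(list(
    tracks = c(lapply(ys_mot, function(y) mk_track(30, y)),
               lapply(ys_non, function(y) mk_track(30, y))),
    interval_frames = 1L, pixel_size_nm = 225), class = "track_set")
  motile <- c(rep(TRUE, 40), rep(FALSE, 120))
  mot <- structure(list(n = 160L, n_motile = 40L, fraction = 0.25,
                        motile = motile,
                        max_excursion_um = as.numeric(motile),
                        threshold_um = 0.45, window_minutes = 10),
                   class = "motility_report")
  rep <- motility_vs_edge(tracks, mot, field)
  expect_lt(rep$motile_mean_um, rep$all_mean_um)
  expect_false(is.null(rep$test))

  # all organelles at one distance: equal means
  tracks_eq <- structure(list(
    tracks = lapply(1:10, function(i) mk_track(30, 20)),
    interval_frames = 1L, pixel_size_nm = 225), class = "track_set")
  mot_eq <- structure(list(n = 10L, n_motile = 5L, fraction = 0.5,
                           motile = rep(c(TRUE, FALSE), 5),
                           max_excursion_um = rep(1, 10),
                           threshold_um = 0.45, window_minutes = 10),
                      class = "motility_report")
  rep_eq <- motility_vs_edge(tracks_eq, mot_eq, field)
  expect_equal(rep_eq$motile_mean_um, rep_eq$all_mean_um)

  # no motile organelles: reported as a note, no test
  mot_none <- structure(list(n = 10L, n_motile = 0L, fraction = 0,
                             motile = rep(FALSE, 10),
                             max_excursion_um = rep(0, 10),
                             threshold_um = 0.45, window_minutes = 10),
                        class = "motility_report")
  rep_none <- motility_vs_edge(tracks_eq, mot_none, field)
  expect_true(is.na(rep_none$motile_mean_um))
  expect_match(rep_none$note, "no motile")
})
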