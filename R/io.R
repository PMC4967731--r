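#' Default run configuration
#'
#' The analysis defaults: 225 nm effective pixel size, 10 Hz acquisition,
#' 60 s baseline half-window, 4 s differentiation period, 40 x 40
#' covariance region, +0.4 normalized covariance threshold, 1e-4 ellipse
#' tolerance, 10 min motility window with a 0.45 um excursion threshold
#' sampled every 1 s. All overridable via [load_config()].
#'
#' @return named list of class `run_config`.
#' @export
falm_defaults <- function() {
  structure(list(
    pixel_size_nm = 225,
    frame_interval_s = 0.1,
    window_s = 60,
    dt_s = 4,
    region_half = 20L,
    threshold = 0.4,
    mbe_tolerance = 1e-4,
    motility_window_min = 10,
    motility_threshold_um = 0.45,
    sampling_interval_s = 1,
    log_level = "info"
  ), class = "run_config")
}

#' Load a run configuration from JSON or YAML
#'
#' Reads a config file (format chosen by extension), validates every
#' field and fills unset fields with the defaults from
#' [falm_defaults()]. Unknown keys are rejected so typos fail loudly.
#' An empty file yields the full default configuration.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  user <- if (ext == "json") {
    if (file.size(path) == 0) list() else jsonlite::read_json(path)
  } else if (ext %in% c("yaml", "yml")) {
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  } else stop("config must be .json, .yaml or .yml")
  defaults <- falm_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(unclass(defaults), lapply(user, unlist))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  num_pos <- c("pixel_size_nm", "frame_interval_s", "window_s", "dt_s",
               "region_half", "mbe_tolerance", "motility_window_min",
               "motility_threshold_um", "sampling_interval_s")
  for (f in num_pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0) {
      stop(sprintf("config field '%s' must be a positive number", f))
    }
  }
  if (!is.numeric(cfg$threshold) || cfg$threshold <= 0 ||
      cfg$threshold > 1) {
    stop("config field 'threshold' must be in (0, 1]")
  }
  invisible(cfg)
}

#' Save a run configuration
#'
#' @param config a `run_config` list.
#' @param path output path (`.json`, `.yaml` or `.yml`).
#' @return invisibly, `path`.
#' @export
save_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(unclass(config), path)
  } else stop("config must be .json, .yaml or .yml")
  invisible(path)
}

#' Read a single-channel TIFF stack
#'
#' Multi-page TIFFs written by [write_stack_tiff()] store counts divided
#' by 65535 in 16 bits; reading rescales and rounds back to integer
#' counts, so a written movie round-trips exactly.
#'
#' @param path TIFF path.
#' @param pixel_size_nm,frame_interval_s calibration for the stack.
#' @return a [fluorescence_stack()].
#' @export
read_stack_tiff <- function(path, pixel_size_nm = 225,
                            frame_interval_s = 0.1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n <- length(pages)
  # TIFF pages are [row = y, col = x]; stack stores [x, y, t]
  arr <- array(0, c(ncol(pages[[1L]]), nrow(pages[[1L]]), n))
  for (t in seq_len(n)) arr[, , t] <- t(pages[[t]])
  fluorescence_stack(round(arr * 65535), pixel_size_nm, frame_interval_s)
}

#' Write a stack as a 16-bit multi-page TIFF
#'
#' @param stack a [fluorescence_stack()] of integer counts (0..65535).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "flstack"))
  pages <- lapply(seq_len(stack$n), function(t) {
    t(stack$intensities[, , t]) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a 16-bit label image
#'
#' @param labels integer matrix indexed `[x, y]` (0 = background).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_label_tiff <- function(labels, path) {
  tiff::writeTIFF(t(labels) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label image (or binary mask) written as TIFF or PNG
#'
#' @param path image path.
#' @return integer matrix indexed `[x, y]`.
#' @export
read_label_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  matrix(as.integer(round(t(img) * 65535)), ncol(img), nrow(img))
}

#' Convert a label image to mitochondrion masks
#'
#' @param labels integer matrix indexed `[x, y]`.
#' @return list of `mito_mask`, one per non-zero label, ordered by label.
#' @export
masks_from_labels <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  lapply(ids, function(id) {
    w <- which(labels == id, arr.ind = TRUE)
    mito_mask(cbind(w[, 1L] - 1L, w[, 2L] - 1L))
  })
}

#' Read a seed CSV (header `x,y`, 0-based pixels)
#'
#' @param path CSV path.
#' @return list of [seed_point()].
#' @export
read_seeds_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("x", "y") %in% names(df))) {
    stop("seed CSV needs columns 'x' and 'y'")
  }
  lapply(seq_len(nrow(df)), function(i) seed_point(df$x[i], df$y[i]))
}

# FNV-1a hash of a string, reported as 8 hex digits; used to stamp
# outputs with the configuration they were produced under
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte, kept in double arithmetic (h exceeds int range)
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

config_hash <- function(config) {
  fnv1a(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA))
}

#' Run the full analysis pipeline
#'
#' Chains segmentation, morphometry and (when a cell mask is given)
#' occupancy and motility: reads the movie and seeds, segments each seed,
#' writes a label TIFF and per-seed CSV, fits shapes, writes per-organelle
#' records and the population summary, and writes a manifest carrying an
#' FNV-1a hash of the configuration so reruns are identifiable. All
#' stages are deterministic, so rerunning with identical inputs
#' reproduces identical outputs.
#'
#' @param stack a [fluorescence_stack()] or a movie TIFF path.
#' @param seeds list of [seed_point()], a seeds CSV path, or `NULL` to
#'   auto-suggest seeds from the derivative stack.
#' @param outdir output directory.
#' @param config a `run_config` (default [falm_defaults()]).
#' @param cell_mask optional cell mask (matrix or TIFF/PNG path) enabling
#'   occupancy and motility stages.
#' @param do_motility run tracking/classification (needs `cell_mask` for
#'   the edge-distance report).
#' @return invisibly, a list with the per-stage results and output paths.
#' @export
run_pipeline <- function(stack, seeds = NULL, outdir, config = falm_defaults(),
                         cell_mask = NULL, do_motility = FALSE) {
  if (is.character(stack)) {
    stack <- read_stack_tiff(stack, config$pixel_size_nm,
                             config$frame_interval_s)
  }
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", outdir)
  }
  if (is.character(cell_mask)) cell_mask <- read_label_image(cell_mask)
  if (is.character(seeds)) seeds <- read_seeds_csv(seeds)
  log_counts <- list()
  if (is.null(seeds)) {
    allon <- compute_all_on(stack, config$window_s)
    ddt <- compute_ddt(compute_delta(stack, allon), config$dt_s,
                       stack$frame_interval_s)
    seeds <- suggest_seeds(ddt, min_separation = 3L)
    if (length(seeds) == 0L) stop("no seeds supplied and none suggested")
    log_counts$suggested_seeds <- length(seeds)
  }

  seg <- segment_stack(stack, seeds, config$window_s, config$dt_s,
                       config$region_half, config$threshold)
  px_um <- config$pixel_size_nm / 1000
  labels <- matrix(0L, stack$nx, stack$ny)
  rows <- vector("list", length(seg$masks))
  for (i in seq_along(seg$masks)) {
    m <- seg$masks[[i]]
    if (m$status == "ok") {
      labels[m$pixels[, 1L] + 1L + m$pixels[, 2L] * stack$nx] <- i
    }
    rows[[i]] <- data.frame(seed_x = m$seed$xs, seed_y = m$seed$ys,
                            area_px = m$area_px,
                            area_um2 = m$area_px * px_um^2,
                            status = m$status)
  }
  seg_df <- do.call(rbind, rows)
  write_label_tiff(labels, file.path(outdir, "masks.tif"))
  write.csv(seg_df, file.path(outdir, "segments.csv"), row.names = FALSE)
  log_counts$seeds <- length(seg$masks)
  log_counts$segmented <- sum(seg_df$status == "ok")

  ok <- which(seg_df$status == "ok")
  records <- lapply(seg$masks[ok], shape_record,
                    pixel_size_nm = config$pixel_size_nm,
                    tolerance = config$mbe_tolerance)
  shapes_df <- data.frame(
    seed_x = seg_df$seed_x[ok], seed_y = seg_df$seed_y[ok],
    area_um2 = vapply(records, function(r) r$area_um2, numeric(1)),
    length_um = vapply(records, function(r) r$length_um, numeric(1)),
    width_um = vapply(records, function(r) r$width_um, numeric(1)),
    aspect_ratio = vapply(records, function(r) r$aspect_ratio, numeric(1)),
    long = vapply(records, function(r) r$long_flag, logical(1)),
    elongated = vapply(records, function(r) r$elongated_flag, logical(1)))
  write.csv(shapes_df, file.path(outdir, "shapes.csv"), row.names = FALSE)
  summary <- if (length(records) > 0L) {
    summarize_population(records, config$pixel_size_nm)
  } else NULL
  out <- list(segmentation = seg, records = records, summary = summary,
              outdir = outdir)

  if (!is.null(cell_mask) && length(ok) > 0L) {
    out$occupancy <- suppressWarnings(
      occupancy(cell_mask, seg$masks[ok]))
  }
  if (do_motility) {
    interval <- max(1L, round(config$sampling_interval_s /
                                stack$frame_interval_s))
    tracks <- track_centroids(stack, seg$masks[ok],
                              interval_frames = interval)
    mot <- classify_motile(tracks, config$motility_window_min,
                           config$motility_threshold_um)
    out$tracks <- tracks
    out$motility <- mot
    track_rows <- do.call(rbind, lapply(tracks$tracks, function(tr) {
      if (is.null(tr$centroids_px)) return(NULL)
      data.frame(id = tr$organelle_id, t_s = tr$t_s,
                 x_um = tr$centroids_px[, 1L] * px_um,
                 y_um = tr$centroids_px[, 2L] * px_um)
    }))
    write.csv(track_rows, file.path(outdir, "tracks.csv"),
              row.names = FALSE)
    mot_json <- list(n = mot$n, n_motile = mot$n_motile,
                     fraction = mot$fraction,
                     threshold_um = mot$threshold_um)
    if (!is.null(cell_mask)) {
      field <- signed_distance(cell_mask, config$pixel_size_nm)
      edge <- suppressWarnings(motility_vs_edge(tracks, mot, field))
      out$edge <- edge
      write.csv(data.frame(id = seq_along(edge$distances_um),
                           distance_um = edge$distances_um,
                           motile = edge$motile),
                file.path(outdir, "edge_distance.csv"), row.names = FALSE)
      mot_json$motile_mean_edge_um <- edge$motile_mean_um
      mot_json$all_mean_edge_um <- edge$all_mean_um
    }
    jsonlite::write_json(mot_json, file.path(outdir, "motility.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if (!is.null(summary)) {
    jsonlite::write_json(
      list(n = summary$n,
           geometric_mean_area_um2 = summary$geometric_mean_area,
           mode_area_um2 = summary$mode_area,
           p95_area_um2 = summary$p95_area,
           mean_top5pct_area_um2 = summary$mean_top5pct_area,
           fraction_long = summary$fraction_long,
           fraction_elongated = summary$fraction_elongated,
           occupancy = if (!is.null(out$occupancy))
             out$occupancy$fraction else NULL),
      file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(
    config_hash = config_hash(config),
    config = unclass(config),
    counts = log_counts,
    files = list.files(outdir))
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
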