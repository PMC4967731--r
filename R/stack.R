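#' Fluorescence image stack with physical calibration
#'
#' Container for a single-channel time-lapse recording. Intensities are
#' stored as a 3D array indexed `[x, y, t]` (0-based coordinates are used
#' in all user-facing tables and seed files; array indexing in R is
#' 1-based internally). Calibration records the effective pixel size at
#' the sample (nm) and the frame interval (s).
#'
#' @param intensities numeric array `(nx, ny, n)` of non-negative, finite
#'   intensities, or a matrix (interpreted as a single frame).
#' @param pixel_size_nm effective pixel size at the sample, nanometres.
#' @param frame_interval_s time between frames, seconds.
#' @return An object of class `flstack` with fields `intensities`, `nx`,
#'   `ny`, `n`, `pixel_size_nm`, `frame_interval_s`.
#' @examples
#' st <- fluorescence_stack(array(1, c(4, 4, 10)), 225, 0.1)
#' st$n
#' @export
fluorescence_stack <- function(intensities, pixel_size_nm = 225,
                               frame_interval_s = 0.1) {
  if (is.matrix(intensities)) {
    intensities <- array(intensities, c(dim(intensities), 1L))
  }
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    stop("intensities must be a 3D array (x, y, t)")
  }
  if (!all(is.finite(intensities))) stop("all intensities must be finite")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0) {
    stop("pixel_size_nm must be > 0")
  }
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0) {
    stop("frame_interval_s must be > 0")
  }
  d <- dim(intensities)
  structure(
    list(
      intensities = intensities,
      nx = d[1L], ny = d[2L], n = d[3L],
      pixel_size_nm = as.numeric(pixel_size_nm),
      frame_interval_s = as.numeric(frame_interval_s)
    ),
    class = "flstack"
  )
}

#' @export
print.flstack <- function(x, ...) {
  cat(sprintf(
    "<flstack> %d x %d px, %d frames | %.3g nm/px, %.3g s/frame (%.3g s total)\n",
    x$nx, x$ny, x$n, x$pixel_size_nm, x$frame_interval_s,
    x$n * x$frame_interval_s
  ))
  invisible(x)
}

#' Seed point (0-based pixel coordinates)
#'
#' @param x,y integer pixel coordinates, 0-based, as used in seed CSV
#'   files and all serialized outputs.
#' @return A list of class `seed_point` with fields `xs`, `ys`.
#' @export
seed_point <- function(x, y) {
  structure(list(xs = as.integer(round(x)), ys = as.integer(round(y))),
            class = "seed_point")
}

# bounds check against a stack / array dims
check_seed <- function(seed, nx, ny) {
  if (seed$xs < 0L || seed$xs >= nx || seed$ys < 0L || seed$ys >= ny) {
    stop(sprintf("seed (%d, %d) outside image %d x %d", seed$xs, seed$ys,
                 nx, ny))
  }
  invisible(seed)
}
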