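#' Line-scan and frame-series containers
#'
#' A `linescan` holds one fluorescence channel of a line-scan: a matrix
#' with one row per scanned line (time) and one column per pixel along
#' the line (space), plus scan timing and which leading rows were
#' acquired with the laser off (the background estimate). A
#' `frame_series` holds a 3-D array `frame x y x x` at a fixed frame
#' rate.
#'
#' @param pixels numeric matrix, rows = lines in time, columns = space.
#' @param line_period time per line in s.
#' @param pixel_size pixel size in um.
#' @param dark_line_rows integer indices of laser-off rows (may be
#'   empty).
#' @return An object of class `linescan`.
#' @export
linescan <- function(pixels, line_period, pixel_size = 0.2,
                     dark_line_rows = integer(0)) {
  pixels <- as.matrix(pixels)
  if (!(line_period > 0)) stop("`line_period` must be positive", call. = FALSE)
  structure(
    list(pixels = pixels, line_period = line_period,
         pixel_size = pixel_size,
         dark_line_rows = as.integer(dark_line_rows)),
    class = "linescan"
  )
}

#' @rdname linescan
#' @param frames 3-D numeric array `frame x y x x`.
#' @param frame_rate frames per second.
#' @export
frame_series <- function(frames, frame_rate = 30, pixel_size = 0.2) {
  stopifnot(length(dim(frames)) == 3L)
  if (!(frame_rate > 0)) stop("`frame_rate` must be positive", call. = FALSE)
  structure(
    list(frames = frames, frame_rate = frame_rate, pixel_size = pixel_size),
    class = "frame_series"
  )
}

#' Scan acquisition geometry for the synthetic renderer
#'
#' @param line_period line-scan period in s; the corresponding rate must
#'   lie in the 100-300 Hz acquisition band (default 200 Hz).
#' @param frame_rate frame-series rate in Hz (default 30, resonant
#'   scanner).
#' @param pixel_size um per pixel.
#' @param n_pixels pixels per scanned line.
#' @param photon_budget expected photons per pixel at baseline
#'   fluorescence (shot-noise scale).
#' @param background_offset expected counts with the laser off.
#' @param n_dark_lines number of leading laser-off lines used for
#'   background estimation.
#' @return An object of class `imaging_geometry`.
#' @export
imaging_geometry <- function(line_period = 1 / 200, frame_rate = 30,
                             pixel_size = 0.2, n_pixels = 64,
                             photon_budget = 200, background_offset = 20,
                             n_dark_lines = 20) {
  rate <- 1 / line_period
  if (rate < 100 || rate > 300) {
    stop("line rate must lie within 100-300 Hz", call. = FALSE)
  }
  if (!(photon_budget > 0)) stop("`photon_budget` must be positive", call. = FALSE)
  structure(
    list(line_period = line_period, frame_rate = frame_rate,
         pixel_size = pixel_size, n_pixels = n_pixels,
         photon_budget = photon_budget,
         background_offset = background_offset,
         n_dark_lines = n_dark_lines),
    class = "imaging_geometry"
  )
}

# Internal: resample a trace onto arbitrary times by linear
# interpolation, holding the end values outside the trace support.
resample_trace <- function(tr, times) {
  stats::approx(trace_times(tr), tr$values, xout = times, rule = 2)$y
}

#' Render a two-channel synthetic line-scan
#'
#' Renders photon-noise-limited scan images from fluorescence profiles.
#' Each structure occupies a column band; its expected counts are
#' `background_offset + photon_budget * F(t) / F(0)` (fluorescence
#' normalized to its initial/resting value so baseline pixels sit at the
#' photon budget). Columns not covered by a structure, and the first
#' `n_dark_lines` rows (laser off), carry `background_offset` only. The
#' green channel reports calcium; the red channel is a calcium-blind
#' volume tracer rendered at constant brightness. Pixel values are
#' Poisson draws around the expectation (no read noise) unless
#' `noiseless = TRUE`.
#'
#' @param structures list of entries `list(profile = <F trace>,
#'   columns = <integer column indices>)`.
#' @param geom an [imaging_geometry()].
#' @param duration scan duration in s (dark lines included).
#' @param seed optional integer seed.
#' @param noiseless if `TRUE`, return the expected counts exactly.
#' @return A list with `green` and `red` [linescan()] objects.
#' @export
render_linescan <- function(structures, geom, duration = NULL,
                            seed = NULL, noiseless = FALSE) {
  stopifnot(inherits(geom, "imaging_geometry"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(duration)) {
    ends <- vapply(structures, function(s) {
      tt <- trace_times(s$profile)
      tt[length(tt)]
    }, 0)
    duration <- max(ends) + geom$n_dark_lines * geom$line_period
  }
  n_lines <- as.integer(floor(duration / geom$line_period))
  dark <- seq_len(min(geom$n_dark_lines, n_lines))
  live <- setdiff(seq_len(n_lines), dark)
  line_t <- (live - 1L - length(dark)) * geom$line_period # live lines start at t=0

  expected_g <- matrix(geom$background_offset, n_lines, geom$n_pixels)
  expected_r <- matrix(geom$background_offset, n_lines, geom$n_pixels)
  for (s in structures) {
    cols <- s$columns
    if (any(cols < 1L | cols > geom$n_pixels)) {
      stop("structure columns outside the scanned line", call. = FALSE)
    }
    f <- resample_trace(s$profile, line_t)
    f0 <- f[1L]
    if (!(f0 > 0)) stop("structure profile must start positive", call. = FALSE)
    expected_g[live, cols] <- geom$background_offset +
      geom$photon_budget * f / f0
    expected_r[live, cols] <- geom$background_offset + geom$photon_budget
  }
  draw <- function(expected) {
    px <- if (noiseless) expected else {
      matrix(stats::rpois(length(expected), expected),
             nrow(expected), ncol(expected))
    }
    linescan(px, line_period = geom$line_period,
             pixel_size = geom$pixel_size, dark_line_rows = dark)
  }
  list(green = draw(expected_g), red = draw(expected_r))
}

#' Render a two-channel synthetic frame series
#'
#' Frame-scan analogue of [render_linescan()]: a rectangular field with
#' one bright structure band whose green brightness follows the supplied
#' fluorescence profile while the red tracer stays constant.
#'
#' @param profile fluorescence [trace()] driving the structure's green
#'   brightness.
#' @param geom an [imaging_geometry()].
#' @param ny,nx frame dimensions in pixels.
#' @param structure_rows,structure_cols pixel index sets occupied by the
#'   structure.
#' @param n_frames number of frames.
#' @inheritParams render_linescan
#' @return A list with `green` and `red` [frame_series()] objects.
#' @export
render_frameseries <- function(profile, geom, ny = 32, nx = 32,
                               structure_rows = 12:20,
                               structure_cols = 4:28,
                               n_frames = 100, seed = NULL,
                               noiseless = FALSE) {
  stopifnot(inherits(geom, "imaging_geometry"))
  if (!is.null(seed)) set.seed(seed)
  frame_t <- (seq_len(n_frames) - 1L) / geom$frame_rate
  f <- resample_trace(profile, frame_t)
  f0 <- f[1L]
  if (!(f0 > 0)) stop("profile must start positive", call. = FALSE)
  g <- array(geom$background_offset, c(n_frames, ny, nx))
  r <- array(geom$background_offset, c(n_frames, ny, nx))
  for (i in seq_len(n_frames)) {
    g[i, structure_rows, structure_cols] <- geom$background_offset +
      geom$photon_budget * f[i] / f0
    r[i, structure_rows, structure_cols] <- geom$background_offset +
      geom$photon_budget
  }
  if (!noiseless) {
    g[] <- stats::rpois(length(g), g)
    r[] <- stats::rpois(length(r), r)
  }
  list(green = frame_series(g, geom$frame_rate, geom$pixel_size),
       red = frame_series(r, geom$frame_rate, geom$pixel_size))
}
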