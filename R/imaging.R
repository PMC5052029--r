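#' Subtract the laser-off background from a line-scan
#'
#' The background is a single scalar per channel, estimated as the mean
#' over the laser-off rows acquired at the start of the scan (for
#' 2-photon imaging this is a near-optimal estimate of the background at
#' the scanned structure). Negative pixel values are allowed after
#' subtraction.
#'
#' @param ls a [linescan()].
#' @param background optional scalar background; required when the scan
#'   has no dark rows.
#' @return A [linescan()] with the background subtracted everywhere.
#' @export
subtract_background <- function(ls, background = NULL) {
  stopifnot(inherits(ls, "linescan"))
  if (is.null(background)) {
    if (!length(ls$dark_line_rows)) {
      stop("no laser-off rows and no configured background value",
           call. = FALSE)
    }
    background <- mean(ls$pixels[ls$dark_line_rows, , drop = FALSE])
  }
  out <- ls
  out$pixels <- ls$pixels - background
  out
}

#' Spatially averaged line-scan profile
#'
#' Averages the selected columns within each scanned line, yielding one
#' mean fluorescence value per line: the line-scan profile of the
#' structure. Laser-off rows are dropped so the profile starts at the
#' first illuminated line (t = 0).
#'
#' @param ls a [linescan()].
#' @param columns integer column indices covering the structure.
#' @param drop_dark drop laser-off rows from the profile (default TRUE).
#' @return A fluorescence [trace()] with `dt = line_period`.
#' @export
linescan_profile <- function(ls, columns, drop_dark = TRUE) {
  stopifnot(inherits(ls, "linescan"))
  if (!length(columns)) stop("empty column selection", call. = FALSE)
  if (any(columns < 1L | columns > ncol(ls$pixels))) {
    stop("columns outside the line-scan", call. = FALSE)
  }
  px <- ls$pixels
  if (drop_dark && length(ls$dark_line_rows)) {
    px <- px[-ls$dark_line_rows, , drop = FALSE]
  }
  trace(rowMeans(px[, columns, drop = FALSE]),
        dt = ls$line_period, units = "au")
}

#' Sliding-average smoothing of a profile
#'
#' Centered moving mean with an odd window (5- and 9-point windows are
#' the display conventions). At the edges the window shrinks to the
#' available samples rather than reflecting, so no data are invented at
#' the trace ends where the baseline is measured.
#'
#' @param p a profile [trace()].
#' @param window odd window length in samples.
#' @return The smoothed [trace()].
#' @export
sliding_average <- function(p, window = 5) {
  stopifnot(inherits(p, "trace"))
  if (window %% 2 != 1) stop("`window` must be odd", call. = FALSE)
  n <- length(p$values)
  if (window > n) stop("`window` longer than the profile", call. = FALSE)
  k <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, p$values))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  out <- p
  out$values <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  out
}

# Internal: 1-D Gaussian convolution with reflect padding along the
# rows (margin = 1) or columns (margin = 2) of a matrix.
gauss_conv_1d <- function(x, sigma, margin) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(4 * sigma))
  kern <- exp(-((-r:r)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  conv_vec <- function(v) {
    n <- length(v)
    idx <- c(rev(seq_len(min(r, n))), seq_len(n),
             n + 1L - seq_len(min(r, n)))
    if (r > n) stop("Gaussian kernel wider than the image", call. = FALSE)
    padded <- v[idx]
    out <- numeric(n)
    for (j in -r:r) out <- out + kern[j + r + 1L] * padded[(r + 1L + j):(r + n + j)]
    out
  }
  if (margin == 1L) t(apply(x, 1L, conv_vec)) else apply(x, 2L, conv_vec)
}

#' Separable 2-D Gaussian filtering of a line-scan
#'
#' Sequential application of two orthogonal 1-D Gaussian kernels
#' (unit-sum, reflect padding): sigma 2 px along time (rows) and 1 px
#' along space (columns) by default. The printed "width of 2 pixel" is
#' ambiguous; it is interpreted as the Gaussian sigma and both sigmas
#' are plain arguments.
#'
#' @param ls a [linescan()].
#' @param sigma_t_px,sigma_x_px Gaussian sigmas in pixels along time and
#'   space; 0 disables that axis.
#' @return The filtered [linescan()].
#' @export
gaussian_filter2d <- function(ls, sigma_t_px = 2, sigma_x_px = 1) {
  stopifnot(inherits(ls, "linescan"))
  if (sigma_t_px < 0 || sigma_x_px < 0) stop("sigmas must be >= 0", call. = FALSE)
  out <- ls
  px <- gauss_conv_1d(ls$pixels, sigma_t_px, margin = 2L) # along time (rows)
  px <- gauss_conv_1d(px, sigma_x_px, margin = 1L)        # along space (cols)
  out$pixels <- px
  out
}

#' Fractional fluorescence change of a line-scan profile
#'
#' `dF/F = (F_peak - F_0) / F_0`, where `F_0` is the mean over the
#' 150 ms immediately before the current injection and `F_peak` the
#' mean over a 150 ms window starting 100 ms after the beginning of the
#' injection. Window lengths and the peak delay are arguments so train
#' stimuli of other durations can shift them.
#'
#' @param p background-subtracted profile [trace()].
#' @param stim_onset start of the current injection in s.
#' @param baseline_window,peak_delay,peak_window window parameters in s.
#' @return The dF/F fraction (dimensionless).
#' @export
df_over_f <- function(p, stim_onset, baseline_window = 0.15,
                      peak_delay = 0.1, peak_window = 0.15) {
  stopifnot(inherits(p, "trace"))
  tt <- trace_times(p)
  eps <- p$dt / 2
  i0 <- tt >= stim_onset - baseline_window - eps & tt < stim_onset - eps
  ip <- tt >= stim_onset + peak_delay - eps &
    tt < stim_onset + peak_delay + peak_window - eps
  if (!any(i0) || !any(ip)) {
    stop("profile does not cover the dF/F windows", call. = FALSE)
  }
  f0 <- mean(p$values[i0])
  if (f0 <= 0) {
    stop("baseline fluorescence F0 <= 0; check background subtraction",
         call. = FALSE)
  }
  (mean(p$values[ip]) - f0) / f0
}

#' Frame-scan calcium response as a dG/R ratio
#'
#' `dG` is the ROI-mean green (indicator) fluorescence over the
#' post-stimulus frames minus the pre-stimulus frames; `R` is the
#' ROI-mean of the background-corrected red (tracer) average computed
#' across all frames entering the dG analysis. The red channel is
#' calcium-blind, so the ratio normalizes for dye content and imaging
#' depth.
#'
#' @param green,red [frame_series()] objects on the same grid.
#' @param roi list with integer vectors `rows` and `cols`.
#' @param pre_frames,post_frames disjoint frame index vectors before and
#'   after the stimulus.
#' @param red_background scalar background subtracted from the red
#'   average.
#' @return The dG/R ratio (dimensionless).
#' @export
dg_over_r <- function(green, red, roi, pre_frames, post_frames,
                      red_background = 0) {
  stopifnot(inherits(green, "frame_series"), inherits(red, "frame_series"))
  n <- dim(green$frames)[1L]
  if (any(c(pre_frames, post_frames) < 1L) ||
      any(c(pre_frames, post_frames) > n)) {
    stop("frame indices out of range", call. = FALSE)
  }
  if (length(intersect(pre_frames, post_frames))) {
    stop("pre and post frame sets must be disjoint", call. = FALSE)
  }
  roi_mean <- function(fs, frames) {
    mean(fs$frames[frames, roi$rows, roi$cols])
  }
  dG <- roi_mean(green, post_frames) - roi_mean(green, pre_frames)
  all_frames <- c(pre_frames, post_frames)
  R <- roi_mean(red, all_frames) - red_background
  if (R <= 0) stop("red normalization R <= 0", call. = FALSE)
  dG / R
}
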