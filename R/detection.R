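#' Amplitude-weighted decay time constant
#'
#' `(A1 tau1 + A2 tau2) / (A1 + A2)`; reduces to `tau1` when a single
#' component (or a degenerate second amplitude of 0) is given.
#'
#' @param taus,amplitudes numeric vectors of equal length.
#' @return The weighted time constant.
#' @export
weighted_tau <- function(taus, amplitudes) {
  stopifnot(length(taus) == length(amplitudes))
  sum(amplitudes * taus) / sum(amplitudes)
}

#' Calcium response templates
#'
#' A `ca_template` is a unit-peak response shape used by the
#' scaled-template detector: a 2.5 s template for classifying line-scan
#' trials and a 1 s template for onset localization in time-lapse ROI
#' profiles.
#'
#' `build_template` averages brightness-over-time profiles from trials
#' with clear responses (all resampled to a common sampling interval),
#' crops to the template length and normalizes the peak to 1.
#'
#' @param profiles list of [trace()] profiles showing clear responses.
#' @param length_s template length in s (2.5 for response
#'   classification, 1 for onset estimation).
#' @param dt common sampling interval in s; defaults to the first
#'   profile's.
#' @return An object of class `ca_template` with fields `values`, `dt`,
#'   `length_s`.
#' @export
build_template <- function(profiles, length_s = 2.5, dt = NULL) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, TRUE, "trace")))
  if (is.null(dt)) dt <- profiles[[1L]]$dt
  if (!(dt > 0)) stop("inconsistent sampling interval", call. = FALSE)
  times <- seq(0, length_s - dt / 2, by = dt)
  resampled <- vapply(profiles, function(p) {
    tt <- trace_times(p) - p$t0
    if (tt[length(tt)] < times[length(times)] - 1e-9) {
      stop("profile shorter than the template length", call. = FALSE)
    }
    stats::approx(tt, p$values, xout = times, rule = 2)$y
  }, numeric(length(times)))
  avg <- rowMeans(resampled)
  pk <- max(abs(avg))
  if (pk == 0) stop("zero-variance template", call. = FALSE)
  structure(list(values = avg / pk, dt = dt, length_s = length_s),
            class = "ca_template")
}

#' Canonical synthetic calcium-response template
#'
#' Convenience constructor of an idealized transient (exponential rise
#' to an exponential decay), peak-normalized — useful when no recorded
#' clear-response library is at hand.
#'
#' @param length_s template length in s.
#' @param dt sampling interval in s.
#' @param rise_tau,decay_tau shape constants in s.
#' @return A `ca_template`.
#' @export
ca_response_template <- function(length_s = 2.5, dt = 0.005,
                                 rise_tau = 0.08, decay_tau = 1.5) {
  t <- seq(0, length_s - dt / 2, by = dt)
  v <- (1 - exp(-t / rise_tau)) * exp(-t / decay_tau)
  structure(list(values = v / max(v), dt = dt, length_s = length_s),
            class = "ca_template")
}

# Internal closed-form scaled-template fit on an aligned segment.
# Least squares of y ~ a * T + c; the detection criterion is the fitted
# scale divided by its standard error (residual SD over the template's
# root sum of squared deviations). Scale- and offset-equivariant.
cb_core <- function(y, Tv, cap = 1e6) {
  n <- length(y)
  Tm <- Tv - mean(Tv)
  sst <- sum(Tm^2)
  if (sst == 0) stop("zero-variance template", call. = FALSE)
  a <- sum(Tm * y) / sst
  c0 <- mean(y) - a * mean(Tv)
  resid <- y - a * Tv - c0
  se <- sqrt(sum(resid^2) / (n - 2L)) / sqrt(sst)
  # numerically-zero guard: a flat (or perfectly fitted) segment has both
  # scale and residual at machine precision; the ratio is then noise
  eps <- 1e-10 * (max(abs(y)) + 1)
  crit <- if (se < eps) {
    if (abs(a) < eps) 0 else sign(a) * cap
  } else {
    max(min(a / se, cap), -cap)
  }
  list(scale = a, offset = c0, criterion = crit)
}

#' Scaled-template fit and detection criterion at one position
#'
#' Fits `scale * template + offset` to the profile segment aligned at
#' `position` by least squares and computes the detection criterion:
#' the fitted scale divided by its standard error. A noiseless embed
#' has zero residual; its criterion is capped at `cap` (default 1e6) to
#' keep the value finite.
#'
#' @param p a profile [trace()].
#' @param template a `ca_template` (e.g. [build_template()]); it is
#'   resampled to the profile's sampling interval if needed.
#' @param position alignment time in s (profile time base); defaults to
#'   the profile start.
#' @param threshold detection threshold on the criterion (default 3.0).
#' @param cap criterion cap for noiseless fits.
#' @return An object of class `detection_result`: `best_scale`,
#'   `best_offset`, `criterion`, `position`, `is_response`
#'   (`criterion > threshold`, strict), `onset` (`NA`; filled by
#'   [onset_time()]).
#' @export
cb_fit_and_criterion <- function(p, template, position = NULL,
                                 threshold = 3.0, cap = 1e6) {
  stopifnot(inherits(p, "trace"), inherits(template, "ca_template"))
  if (is.null(position)) position <- p$t0
  Tv <- template_on_grid(template, p$dt)
  i0 <- time_to_index(p, position)
  i1 <- i0 + length(Tv) - 1L
  if (i0 < 1L || i1 > length(p$values)) {
    stop("template does not fit within the profile at this position",
         call. = FALSE)
  }
  fit <- cb_core(p$values[i0:i1], Tv, cap)
  structure(
    list(best_scale = fit$scale, best_offset = fit$offset,
         criterion = fit$criterion, position = position,
         is_response = fit$criterion > threshold, onset = NA_real_),
    class = "detection_result"
  )
}

# Internal: resample a template onto a sampling interval.
template_on_grid <- function(template, dt) {
  if (abs(dt - template$dt) < 1e-12) return(template$values)
  t_old <- (seq_along(template$values) - 1L) * template$dt
  t_new <- seq(0, template$length_s - dt / 2, by = dt)
  stats::approx(t_old, template$values, xout = t_new, rule = 2)$y
}

#' Classify a trial as a calcium response
#'
#' A trial is a response when the stimulus-aligned detection criterion
#' strictly exceeds the threshold (3.0 by default, the
#' sensitivity/selectivity optimum; a criterion of exactly 3.0 is not a
#' response).
#'
#' @inheritParams cb_fit_and_criterion
#' @return Logical.
#' @export
classify_response <- function(p, template, threshold = 3.0,
                              position = NULL) {
  cb_fit_and_criterion(p, template, position, threshold)$is_response
}

#' Calcium signal onset from a time-lapse ROI profile
#'
#' The profile is re-sampled at 1 kHz by linear interpolation; the 1 s
#' onset template is slid along it, the scaled-template fit and
#' detection criterion are computed at every 1 ms lag, and the onset is
#' the lag with the maximal criterion, provided that criterion exceeds
#' the threshold (earliest lag on ties).
#'
#' @param roi_profile a [trace()] ROI brightness-over-time profile.
#' @param template the 1 s onset `ca_template`.
#' @param threshold detection threshold (default 3.0).
#' @param resample_rate resampling rate in Hz (default 1000).
#' @return A list with `onset` (s; `NA` when no lag exceeds the
#'   threshold), `criterion` (at the onset lag, or the maximum found)
#'   and `defined`.
#' @export
onset_time <- function(roi_profile, template, threshold = 3.0,
                       resample_rate = 1000) {
  stopifnot(inherits(roi_profile, "trace"), inherits(template, "ca_template"))
  dt <- 1 / resample_rate
  tt <- trace_times(roi_profile)
  t_new <- seq(tt[1L], tt[length(tt)], by = dt)
  y <- stats::approx(tt, roi_profile$values, xout = t_new)$y
  Tv <- template_on_grid(template, dt)
  nT <- length(Tv)
  n_lag <- length(y) - nT + 1L
  if (n_lag < 1L) stop("profile shorter than the template", call. = FALSE)
  crit <- numeric(n_lag)
  for (i in seq_len(n_lag)) {
    crit[i] <- cb_core(y[i:(i + nT - 1L)], Tv)$criterion
  }
  i_best <- which.max(crit) # which.max returns the earliest maximum
  if (crit[i_best] > threshold) {
    list(onset = t_new[i_best], criterion = crit[i_best], defined = TRUE)
  } else {
    list(onset = NA_real_, criterion = crit[i_best], defined = FALSE)
  }
}
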