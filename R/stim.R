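#' Quantal EPSC kinetics
#'
#' Kinetic description of the miniature-EPSC-shaped current used as the
#' elementary quantum of all mock PSP stimuli. The waveform is a
#' difference of exponentials, peak-normalized and scaled to `amplitude`.
#' The quantal amplitude defaults to 12 pA, the literature consensus for
#' miniature EPSCs in NG2 cells. The rise and decay constants are not
#' measured quantities: the defaults give a sub-millisecond-rising,
#' few-millisecond quantal current and are plain configuration keys.
#'
#' @param amplitude peak current in pA (>= 0); default 12.
#' @param rise_tau rise time constant in ms (> 0).
#' @param decay_tau decay time constant in ms (> rise_tau).
#' @param polarity `+1` for an excitatory (depolarizing) quantum, `-1`
#'   for the small inverted probe used to measure the passive response.
#' @return An object of class `quantal_kinetics`.
#' @export
quantal_kinetics <- function(amplitude = 12, rise_tau = 0.2,
                             decay_tau = 1.2, polarity = 1) {
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  if (!(rise_tau > 0) || !(decay_tau > rise_tau)) {
    stop("need decay_tau > rise_tau > 0", call. = FALSE)
  }
  if (!polarity %in% c(-1, 1)) stop("`polarity` must be +1 or -1", call. = FALSE)
  structure(
    list(amplitude = amplitude, rise_tau = rise_tau,
         decay_tau = decay_tau, polarity = polarity),
    class = "quantal_kinetics"
  )
}

# Internal: peak-normalized difference-of-exponentials kernel on a time
# grid (seconds), kinetics in ms. Peak value is exactly 1 at the analytic
# peak time; on the sampled grid max |value| <= 1.
quantal_kernel <- function(kin, dt, duration = NULL) {
  tr_ms <- kin$rise_tau
  td_ms <- kin$decay_tau
  if (is.null(duration)) duration <- 10 * td_ms / 1000 # s; tail < 1% of peak
  t_ms <- seq(0, duration * 1000, by = dt * 1000)
  w <- exp(-t_ms / td_ms) - exp(-t_ms / tr_ms)
  t_peak <- tr_ms * td_ms / (td_ms - tr_ms) * log(td_ms / tr_ms)
  peak <- exp(-t_peak / td_ms) - exp(-t_peak / tr_ms)
  w / peak
}

#' Build a single quantal EPSC current trace
#'
#' @param kin a [quantal_kinetics()].
#' @param dt sampling interval in seconds (default 1/20000).
#' @param duration trace duration in seconds; defaults to ten decay
#'   constants so the tail returns below 1% of peak.
#' @return A current [trace()] in pA whose extremum equals
#'   `polarity * amplitude` (up to grid discretization of the peak).
#' @examples
#' q <- build_quantal_epsc(quantal_kinetics())
#' max(q$values) # 12 pA
#' @export
build_quantal_epsc <- function(kin, dt = 1 / 20000, duration = NULL) {
  stopifnot(inherits(kin, "quantal_kinetics"))
  if (!(dt > 0)) stop("`dt` must be positive", call. = FALSE)
  k <- quantal_kernel(kin, dt, duration)
  # rescale so the sampled maximum hits the configured amplitude exactly
  m <- max(abs(k))
  vals <- if (m > 0 && kin$amplitude > 0) {
    kin$polarity * kin$amplitude * k / m
  } else {
    numeric(length(k))
  }
  trace(vals, dt = dt, units = "pA")
}

# Internal: superpose copies of the quantal kernel at `onsets_s`
# (seconds), each scaled by the matching entry of `scales`.
superpose_quanta <- function(kin, onsets_s, scales, dt, duration) {
  kernel <- build_quantal_epsc(kin, dt = dt)$values
  n_out <- as.integer(round(duration / dt)) + 1L
  out <- numeric(n_out)
  # snap onsets to the grid, ties toward zero
  idx <- 1L + as.integer(sign(onsets_s / dt) *
                           floor(abs(onsets_s / dt) + 0.5 - 1e-12))
  for (j in seq_along(idx)) {
    i0 <- idx[j]
    if (i0 > n_out) next
    len <- min(length(kernel), n_out - i0 + 1L)
    sl <- i0:(i0 + len - 1L)
    out[sl] <- out[sl] + scales[j] * kernel[seq_len(len)]
  }
  trace(out, dt = dt, units = "pA")
}

#' Build a regular mock PSP train
#'
#' Linear superposition of `n` quantal waveforms at `rate` Hz, each
#' scaled by the quantal content `Q`. The canonical strong stimulus is
#' 10 mock PSPs at 100 Hz.
#'
#' @inheritParams build_quantal_epsc
#' @param n number of PSPs in the train (>= 1).
#' @param rate train frequency in Hz.
#' @param Q integer number of quanta per PSP (>= 0).
#' @param duration optional trace duration (s); must hold the whole train.
#' @return A current [trace()] in pA.
#' @export
build_psp_train <- function(kin, n = 10, rate = 100, Q = 1,
                            dt = 1 / 20000, duration = NULL) {
  stopifnot(inherits(kin, "quantal_kinetics"))
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (!(rate > 0)) stop("`rate` must be positive", call. = FALSE)
  if (Q < 0) stop("`Q` must be >= 0", call. = FALSE)
  onsets <- (seq_len(n) - 1L) / rate
  tail_s <- 10 * kin$decay_tau / 1000
  need <- onsets[n] + tail_s
  if (is.null(duration)) duration <- need
  if (duration < need - 1e-12) {
    stop(sprintf("train needs %.4g s but trace buffer is %.4g s",
                 need, duration), call. = FALSE)
  }
  superpose_quanta(kin, onsets, rep(Q, n), dt, duration)
}

#' Build a Gaussian-dispersed quantal train
#'
#' Models desynchronized presynaptic firing: each of `n_syn` synapses
#' releases `q_per_syn` vesicles at times drawn i.i.d. from
#' `Normal(center, sd)`, and the stimulus is the superposition of one
#' quantal current per vesicle. The default dispersion is 25 ms.
#' Release times falling outside the trace window are clipped to the
#' window edge (with a warning) rather than dropped, so the total
#' quantal content is preserved.
#'
#' @inheritParams build_quantal_epsc
#' @param n_syn number of synapses (>= 1).
#' @param q_per_syn vesicles released per synapse (default 10).
#' @param sd standard deviation of release times in ms (default 25).
#' @param center mean release time in ms (default `4 * sd`).
#' @param seed integer seed; the same seed reproduces the waveform
#'   bit-for-bit.
#' @param duration trace duration in s; default `2 * center / 1000` plus
#'   the quantal tail.
#' @return A list with `trace` (current [trace()], pA) and
#'   `release_times` (seconds, length `n_syn * q_per_syn`, ground truth).
#' @examples
#' g <- build_gaussian_train(quantal_kinetics(), n_syn = 20, seed = 1)
#' length(g$release_times) # 200
#' @export
build_gaussian_train <- function(kin, n_syn, q_per_syn = 10, sd = 25,
                                 center = 4 * sd, seed = NULL,
                                 dt = 1 / 20000, duration = NULL) {
  stopifnot(inherits(kin, "quantal_kinetics"))
  if (n_syn < 1) stop("`n_syn` must be >= 1", call. = FALSE)
  if (!(sd > 0)) stop("`sd` must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_rel <- n_syn * q_per_syn
  times_s <- stats::rnorm(n_rel, mean = center, sd = sd) / 1000
  if (is.null(duration)) {
    duration <- 2 * center / 1000 + 10 * kin$decay_tau / 1000
  }
  clipped <- times_s < 0 | times_s > duration
  if (any(clipped)) {
    warning(sprintf("%d release time(s) clipped to the trace window",
                    sum(clipped)), call. = FALSE)
    times_s <- pmin(pmax(times_s, 0), duration)
  }
  tr <- superpose_quanta(kin, times_s, rep(1, n_rel), dt, duration)
  list(trace = tr, release_times = times_s)
}

#' Stimulus strength normalized across cells
#'
#' The voltage impact of a quantal barrage scales with the cell's input
#' resistance, so stimulus strength is expressed as the product of the
#' quantal content `Q` and the input resistance `R_in`, in multiples of
#' the 250 MOhm population-average NG2 cell. Injecting 100 Q into
#' 250 MOhm and 50 Q into 500 MOhm both give 25,000 Q.MOhm = 100
#' reference-cell quanta.
#'
#' @param Q integer quantal content (>= 0).
#' @param R_in input resistance in MOhm (> 0).
#' @param reference_R reference resistance in MOhm (default 250).
#' @return An object of class `strength_norm` with fields `Q`, `R_in`,
#'   `product` (Q.MOhm) and `equivalents_250`.
#' @export
normalized_strength <- function(Q, R_in, reference_R = 250) {
  if (Q < 0) stop("`Q` must be >= 0", call. = FALSE)
  if (!(R_in > 0)) stop("`R_in` must be positive", call. = FALSE)
  structure(
    list(Q = Q, R_in = R_in, product = Q * R_in,
         equivalents_250 = Q * R_in / reference_R),
    class = "strength_norm"
  )
}

#' Scale a small passive probe response
#'
#' To display the waveform a large injection would produce in the
#' absence of voltage-gated channels, the small hyperpolarizing probe
#' response recorded in the same cell is multiplied by the (negative)
#' amplitude ratio of the target injection over the probe injection.
#' Linear scaling leaves the time base and half-width untouched.
#'
#' @param probe_response a voltage [trace()].
#' @param ratio scaling factor (target amplitude / probe amplitude,
#'   negative when the probe is inverted).
#' @return A [trace()] with scaled values.
#' @export
scale_passive_response <- function(probe_response, ratio) {
  stopifnot(inherits(probe_response, "trace"))
  out <- probe_response
  out$values <- probe_response$values * ratio
  out
}
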