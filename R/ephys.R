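#' Amplitude and half-width metrics of a PSP voltage response
#'
#' Baseline is the mean over a window immediately preceding the stimulus
#' onset; amplitude is the extremum relative to baseline (signed);
#' half-width is the time between the two half-amplitude crossings, each
#' located by linear interpolation between the bracketing samples (first
#' crossing from the left, last from the right — stable to sub-sample
#' precision at 20 kHz).
#'
#' @param V voltage [trace()] in mV.
#' @param stim_onset stimulus onset time in s.
#' @param baseline_window length of the pre-onset baseline window in s.
#' @param search_end optional end of the response search window in s
#'   (default: end of trace).
#' @return An object of class `psp_metrics`: `baseline` and `peak_Vm`
#'   (mV), `amplitude` (mV, signed), `half_width` (ms, `NA` when
#'   undefined), `onset_index`, `peak_index`, and `defined` (FALSE for a
#'   flat trace with no half-amplitude crossings).
#' @export
psp_metrics <- function(V, stim_onset, baseline_window = 0.01,
                        search_end = NULL) {
  stopifnot(inherits(V, "trace"))
  tt <- trace_times(V)
  i_on <- time_to_index(V, stim_onset)
  if (i_on < 2L) stop("baseline window must precede the stimulus onset",
                      call. = FALSE)
  bl_idx <- which(tt >= stim_onset - baseline_window & tt < stim_onset)
  if (!length(bl_idx)) stop("baseline window contains no samples", call. = FALSE)
  baseline <- mean(V$values[bl_idx])

  i_end <- if (is.null(search_end)) length(V$values) else time_to_index(V, search_end)
  seg <- V$values[i_on:i_end]
  rel <- seg - baseline
  i_pk <- which.max(abs(rel))
  amplitude <- rel[i_pk]
  peak_Vm <- seg[i_pk]

  out <- structure(
    list(baseline = baseline, amplitude = amplitude, peak_Vm = peak_Vm,
         half_width = NA_real_, onset_index = i_on,
         peak_index = i_on + i_pk - 1L, defined = FALSE),
    class = "psp_metrics"
  )
  if (amplitude == 0) return(out)
  # work on the positive-going shape regardless of polarity
  sh <- rel * sign(amplitude)
  level <- abs(amplitude) / 2
  up <- which(sh[-length(sh)] < level & sh[-1L] >= level)
  dn <- which(sh[-length(sh)] >= level & sh[-1L] < level)
  up <- up[up < i_pk]
  dn <- dn[dn >= i_pk]
  if (!length(up) || !length(dn)) return(out)
  i1 <- up[1L]   # first crossing from the left
  i2 <- dn[length(dn)] # last crossing from the right
  frac1 <- (level - sh[i1]) / (sh[i1 + 1L] - sh[i1])
  frac2 <- (level - sh[i2]) / (sh[i2 + 1L] - sh[i2])
  out$half_width <- 1000 * V$dt * ((i2 + frac2) - (i1 + frac1))
  out$defined <- TRUE
  out
}

#' Half-width and amplitude ratios of an active vs scaled-passive PSP
#'
#' The active voltage response is normalized on the passive response the
#' same injection would produce (the probe response scaled to the target
#' injection). Ratios below 1 mean the voltage-gated channels shorten or
#' attenuate the PSP.
#'
#' @param active,scaled_passive [psp_metrics()] of the active response
#'   and of the scaled passive reference.
#' @return A list with `hw_ratio` and `amp_ratio`.
#' @export
ratios_vs_passive <- function(active, scaled_passive) {
  stopifnot(inherits(active, "psp_metrics"),
            inherits(scaled_passive, "psp_metrics"))
  if (!scaled_passive$defined) {
    stop("passive reference metrics are undefined", call. = FALSE)
  }
  list(hw_ratio = active$half_width / scaled_passive$half_width,
       amp_ratio = active$amplitude / scaled_passive$amplitude)
}

#' Predicted passive peak depolarization
#'
#' Linear extrapolation of the small-probe response: the peak membrane
#' potential a stimulus of the given normalized strength would reach in
#' the absence of voltage-gated channels.
#'
#' @param strength a [normalized_strength()].
#' @param unit_passive_mV_per_equiv passive peak depolarization (mV) per
#'   250 MOhm-equivalent quantum, measured from the same cell's probe.
#' @param E_rest resting potential in mV.
#' @return Predicted peak membrane potential in mV.
#' @export
predict_passive_peak <- function(strength, unit_passive_mV_per_equiv,
                                 E_rest = -85) {
  stopifnot(inherits(strength, "strength_norm"))
  E_rest + strength$equivalents_250 * unit_passive_mV_per_equiv
}

#' Per-PSP half-widths along a stimulus train
#'
#' Measures each PSP in its inter-onset window, relative to the local
#' membrane potential at the window start (later PSPs ride on residual
#' depolarization). Reports the percent increase of the last over the
#' first half-width, the train-broadening statistic.
#'
#' @param V voltage [trace()] in mV.
#' @param onsets PSP onset times in s (sorted, non-overlapping windows).
#' @param tail window length after the last onset in s (default: the
#'   median inter-onset interval).
#' @return A list with `half_widths` (ms, per PSP; `NA` if a PSP is not
#'   bracketed inside its window) and `percent_increase`
#'   (`100 * (hw_last / hw_first - 1)`).
#' @export
train_halfwidth_series <- function(V, onsets, tail = NULL) {
  stopifnot(inherits(V, "trace"), length(onsets) >= 2L)
  if (is.unsorted(onsets)) stop("onsets must be sorted", call. = FALSE)
  isi <- diff(onsets)
  if (any(isi <= 0)) stop("windowing error: overlapping PSP windows", call. = FALSE)
  if (is.null(tail)) tail <- stats::median(isi)
  ends <- c(onsets[-1L], onsets[length(onsets)] + tail)
  hw <- vapply(seq_along(onsets), function(k) {
    i0 <- time_to_index(V, onsets[k])
    i1 <- min(time_to_index(V, ends[k]), length(V$values))
    if (i1 - i0 < 4L) stop("windowing error: window too short", call. = FALSE)
    seg <- V$values[i0:i1]
    rel <- seg - seg[1L] # local baseline: membrane potential at PSP onset
    i_pk <- which.max(abs(rel))
    if (rel[i_pk] == 0) return(NA_real_)
    sh <- rel * sign(rel[i_pk])
    level <- max(sh) / 2
    up <- which(sh[-length(sh)] < level & sh[-1L] >= level)
    dn <- which(sh[-length(sh)] >= level & sh[-1L] < level)
    up <- up[up < i_pk]
    dn <- dn[dn >= i_pk]
    if (!length(up) || !length(dn)) return(NA_real_)
    i1x <- up[1L]; i2x <- dn[length(dn)]
    f1 <- (level - sh[i1x]) / (sh[i1x + 1L] - sh[i1x])
    f2 <- (level - sh[i2x]) / (sh[i2x + 1L] - sh[i2x])
    1000 * V$dt * ((i2x + f2) - (i1x + f1))
  }, 0)
  pct <- 100 * (hw[length(hw)] / hw[1L] - 1)
  list(half_widths = hw, percent_increase = pct)
}

#' Detect spikelets riding on a PSP
#'
#' A spikelet is flagged where dV/dt exceeds a threshold and the
#' following local maximum rises at least `min_amplitude` above the
#' membrane potential at the threshold crossing. Defaults (5 mV/ms,
#' 5 mV) are declared working values, not measured ones.
#'
#' @param V voltage [trace()] sampled at 10 kHz or faster.
#' @param dvdt_threshold rate-of-rise threshold in mV/ms.
#' @param min_amplitude minimum rise above the crossing voltage in mV.
#' @param search_window look-ahead for the local maximum in s.
#' @return A data frame with columns `time` (s, threshold crossing) and
#'   `amplitude` (mV above the crossing voltage); zero rows if none.
#' @export
detect_spikelets <- function(V, dvdt_threshold = 5, min_amplitude = 5,
                             search_window = 0.01) {
  stopifnot(inherits(V, "trace"))
  if (V$dt > 1e-4 + 1e-12) {
    stop("spikelet detection needs a sampling rate of at least 10 kHz",
         call. = FALSE)
  }
  v <- V$values
  dvdt <- diff(v) / (1000 * V$dt) # mV/ms
  above <- dvdt > dvdt_threshold
  onsets <- which(above & !c(FALSE, above[-length(above)]))
  look <- as.integer(round(search_window / V$dt))
  times <- numeric(0)
  amps <- numeric(0)
  last_end <- 0L
  for (i in onsets) {
    if (i <= last_end) next
    j1 <- min(i + look, length(v))
    pk <- i + which.max(v[i:j1]) - 1L
    amp <- v[pk] - v[i]
    if (amp >= min_amplitude) {
      times <- c(times, trace_times(V)[i])
      amps <- c(amps, amp)
      last_end <- pk
    }
  }
  data.frame(time = times, amplitude = amps)
}

#' Fraction of calcium-responding trials vs stimulus strength
#'
#' Bins trials by normalized injection strength, computes the responding
#' fraction per bin, and interpolates the strength at which half of the
#' trials respond (linear interpolation between adjacent non-empty bin
#' centers at the first upward crossing of 0.5).
#'
#' @param trials data frame with numeric column `strength` and logical
#'   column `responded`.
#' @param bin_edges increasing numeric vector of bin boundaries.
#' @return A list with `curve` (data frame: `center`, `n`, `fraction`,
#'   non-empty bins only), `empty_bins` (centers of excluded bins) and
#'   `strength_50` (`NA` with a message attribute when the curve never
#'   crosses 0.5).
#' @export
responding_fraction_curve <- function(trials, bin_edges) {
  stopifnot(is.data.frame(trials),
            all(c("strength", "responded") %in% names(trials)))
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("`bin_edges` must be strictly increasing", call. = FALSE)
  }
  bins <- cut(trials$strength, breaks = bin_edges, include.lowest = TRUE)
  centers <- (bin_edges[-1L] + bin_edges[-length(bin_edges)]) / 2
  n <- as.integer(table(bins))
  frac <- vapply(levels(bins), function(l) {
    mean(trials$responded[bins == l])
  }, 0)
  keep <- n > 0L
  curve <- data.frame(center = centers[keep], n = n[keep],
                      fraction = unname(frac[keep]))
  s50 <- NA_real_
  f <- curve$fraction
  cross <- which(f[-length(f)] < 0.5 & f[-1L] >= 0.5)
  if (any(f >= 0.5) && f[1L] >= 0.5) {
    s50 <- curve$center[1L]
  } else if (length(cross)) {
    i <- cross[1L]
    s50 <- curve$center[i] + (0.5 - f[i]) / (f[i + 1L] - f[i]) *
      (curve$center[i + 1L] - curve$center[i])
  }
  list(curve = curve, empty_bins = centers[!keep], strength_50 = s50)
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Two-sided p-value by full hypergeometric summation: the probabilities
#' of all tables with the observed margins whose probability does not
#' exceed that of the observed table are summed (the "sum of small
#' p tables" convention; conventions differ, so this one is fixed
#' explicitly). The odds ratio is the plain cross-product ratio `ad/bc`.
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise:
#'   `a b / c d` (e.g. responders / non-responders by condition).
#' @return A list with `odds_ratio` (`NA` when a margin is zero) and
#'   `p_two_sided`.
#' @examples
#' fisher_exact_2x2(9, 31, 22, 21) # control 9/40 vs 4-AP 22/43 responders
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  m <- a + b      # row 1 total
  n2 <- c + d     # row 2 total
  k <- a + c      # column 1 total
  if (m == 0 || n2 == 0 || k == 0 || (b + d) == 0) {
    return(list(odds_ratio = NA_real_, p_two_sided = 1))
  }
  or <- (a * d) / (b * c) # margins are non-zero here, so never 0/0
  supp <- max(0L, k - n2):min(m, k)
  probs <- stats::dhyper(supp, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(odds_ratio = or, p_two_sided = min(1, p))
}

#' Group comparison tests
#'
#' The fixed battery used for group comparisons: two-sided paired t
#' test, Wilcoxon-Mann-Whitney rank test (exact when both groups have at
#' most 12 observations and no ties, normal approximation otherwise),
#' and a Pearson linear-correlation R-squared. The significance level
#' for all tests is 0.05, two-sided.
#'
#' @param x,y numeric vectors (equal length for `paired_t` and
#'   `pearson_r2`).
#' @param test one of `"paired_t"`, `"wmw"`, `"pearson_r2"`.
#' @return A list with `statistic` (t, W or R-squared), `p` and `test`.
#' @export
compare_groups <- function(x, y, test = c("paired_t", "wmw", "pearson_r2")) {
  test <- match.arg(test)
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (test == "paired_t") {
    if (length(x) != length(y)) stop("paired test needs equal lengths", call. = FALSE)
    d <- x - y
    if (all(d == 0)) return(list(statistic = 0, p = 1, test = test))
    ht <- stats::t.test(x, y, paired = TRUE)
    list(statistic = unname(ht$statistic), p = ht$p.value, test = test)
  } else if (test == "wmw") {
    exact <- length(x) <= 12L && length(y) <= 12L
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = !exact))
    list(statistic = unname(ht$statistic), p = ht$p.value, test = test)
  } else {
    if (length(x) != length(y)) stop("correlation needs equal lengths", call. = FALSE)
    ht <- stats::cor.test(x, y, method = "pearson")
    r2 <- unname(ht$estimate)^2
    list(statistic = r2, p = ht$p.value, test = test)
  }
}
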