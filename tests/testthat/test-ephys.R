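make_triangle <- function(base_ms, peak_mV, onset_s = 0.02,
                          total_s = 0.1, dt = 1 / 20000, baseline = -85) {
  n <- round(total_s / dt)
  v <- rep(baseline, n)
  half_n <- round(base_ms / 2 / 1000 / dt)
  i0 <- round(onset_s / dt) + 1L
  ramp <- seq(0, peak_mV, length.out = half_n + 1L)
  v[i0:(i0 + half_n)] <- baseline + ramp
  v[(i0 + half_n):(i0 + 2L * half_n)] <- baseline + rev(ramp)
  trace(v, dt = dt, units = "mV")
}

test_that("PSP metrics: geometry, offsets and time shifts", {
  tri <- make_triangle(4, 20)
  m <- psp_metrics(tri, stim_onset = 0.02, baseline_window = 0.01)
  expect_equal(m$amplitude, 20)
  expect_equal(m$half_width, 2, tolerance = 1e-6)

  # baseline-offset invariance
  shifted <- trace(tri$values + 10, dt = tri$dt, units = "mV")
  ms <- psp_metrics(shifted, stim_onset = 0.02, baseline_window = 0.01)
  expect_equal(ms$amplitude, m$amplitude)
  expect_equal(ms$half_width, m$half_width)

  # time-shift invariance
  lag <- trace(c(rep(-85, 200), tri$values), dt = tri$dt, units = "mV")
  ml <- psp_metrics(lag, stim_onset = 0.02 + 200 * tri$dt,
                    baseline_window = 0.01)
  expect_equal(ml$half_width, m$half_width)

  # time dilation scales the half-width
  dil <- trace(tri$values, dt = tri$dt * 3, units = "mV")
  md <- psp_metrics(dil, stim_onset = 0.06, baseline_window = 0.03)
  expect_equal(md$half_width, 3 * m$half_width, tolerance = 1e-6)

  # flat trace: undefined metrics
  flat <- trace(rep(-85, 2000), units = "mV")
  expect_false(psp_metrics(flat, 0.02)$defined)
})

test_that("passive amplitude matches the quadrature convolution peak", {
  inj <- padded_train(100)
  sim <- simulate_membrane(cell_params(conductances = list()), inj)
  m <- psp_metrics(sim$V, stim_onset = 0.02, baseline_window = 0.015)
  # independent oracle: adaptive quadrature of inj (*) RC impulse response,
  # integrated in stimulus time over the injection's support only (the
  # current is a sub-ms spike; quadrature over a wide window would miss it)
  tau <- 250 * 25 / 1e6 # MOhm.pF = 1e-6 s
  t_inj_end <- 0.02 + 10 * kin_default$decay_tau / 1000
  kernel_conv <- function(t) {
    f <- function(u) {
      approx(trace_times(inj), inj$values, xout = u, rule = 2)$y *
        exp(-(t - u) / tau)
    }
    # pA * MOhm = uV, hence the /1000 into mV
    hi <- min(t, t_inj_end)
    mid <- min(0.022, hi) # split at the sharp early peak of the EPSC
    (250 / 1000 / tau) *
      (integrate(f, 0.02, mid, rel.tol = 1e-8, subdivisions = 500L,
                 stop.on.error = FALSE)$value +
         integrate(f, mid, hi, rel.tol = 1e-8, subdivisions = 500L,
                   stop.on.error = FALSE)$value)
  }
  opt <- optimize(kernel_conv, c(0.02, 0.05), maximum = TRUE)
  expect_lt(abs(m$amplitude - opt$objective) / opt$objective, 0.01)
})

test_that("ratios against the scaled passive reference", {
  tri <- make_triangle(4, 20)
  m <- psp_metrics(tri, 0.02, 0.01)
  expect_equal(ratios_vs_passive(m, m), list(hw_ratio = 1, amp_ratio = 1))
  half <- psp_metrics(make_triangle(2, 20), 0.02, 0.01)
  expect_equal(ratios_vs_passive(half, m)$hw_ratio, 0.5, tolerance = 1e-6)
  flat <- psp_metrics(trace(rep(-85, 2000), units = "mV"), 0.02)
  expect_error(ratios_vs_passive(m, flat), "undefined")
})

test_that("passive peak prediction is linear in strength", {
  expect_equal(predict_passive_peak(normalized_strength(0, 250), 0.5), -85)
  p1 <- predict_passive_peak(normalized_strength(100, 250), 0.5)
  p2 <- predict_passive_peak(normalized_strength(200, 250), 0.5)
  expect_equal(p2 - -85, 2 * (p1 - -85))

  # simulator cross-check on the all-passive cell
  unit_inj <- padded_train(1)
  unit <- psp_metrics(
    simulate_membrane(cell_params(conductances = list()), unit_inj)$V,
    0.02, 0.015)$amplitude
  Q <- 120
  pred <- predict_passive_peak(normalized_strength(Q, 250), unit)
  simv <- max(simulate_membrane(cell_params(conductances = list()),
                                padded_train(Q))$V$values)
  expect_lt(abs(pred - simv) / abs(simv - -85 + 1e-9), 0.02)
})

test_that("train half-width series and percent increase", {
  dt <- 1 / 20000
  mk_train <- function(bases) {
    v <- rep(-85, round(0.12 / dt))
    for (k in seq_along(bases)) {
      tri <- make_triangle(bases[k], 15, onset_s = 0.001, total_s = 0.02)
      i0 <- round((0.02 * k - 0.019) / dt)
      v[i0:(i0 + length(tri$values) - 1L)] <-
        v[i0:(i0 + length(tri$values) - 1L)] + tri$values + 85
    }
    trace(v, dt = dt, units = "mV")
  }
  onsets <- 0.02 * (1:3) - 0.019

  same <- train_halfwidth_series(mk_train(c(4, 4, 4)), onsets)
  expect_equal(same$percent_increase, 0, tolerance = 1e-6)

  grow <- train_halfwidth_series(mk_train(c(4, 4, 6)), onsets)
  expect_equal(grow$half_widths, c(2, 2, 3), tolerance = 1e-6)
  expect_equal(grow$percent_increase, 50, tolerance = 1e-4)

  expect_error(train_halfwidth_series(mk_train(c(4, 4)), c(0.02, 0.019)),
               "sorted|overlapping")
})

test_that("control trains broaden; A-current-free trains do not", {
  run_train <- function(channels) {
    inj <- padded_train(150, n = 10, duration = 0.3)
    simulate_membrane(cell_params(conductances = channels), inj)
  }
  onsets <- 0.02 + (0:9) / 100
  ctrl <- train_halfwidth_series(run_train(default_channels())$V, onsets)
  noA <- train_halfwidth_series(run_train(default_channels(gbar_A = 0))$V,
                                onsets)
  expect_gt(ctrl$percent_increase, 5)
  expect_lt(noA$percent_increase, ctrl$percent_increase)
  expect_lt(noA$percent_increase, 5)
})

test_that("spikelet detection on constructed fixtures", {
  dt <- 1 / 20000
  tt <- seq(0, 0.2, by = dt)
  # smooth Gaussian depolarization: max dV/dt ~ 1.2 mV/ms, no events
  smooth <- trace(-85 + 30 * exp(-(tt - 0.1)^2 / (2 * 0.01^2)), units = "mV")
  expect_equal(nrow(detect_spikelets(smooth)), 0L)

  # one fast one-sided transient: instantaneous onset, dV/dt >> threshold
  v <- -85 + 30 * exp(-(tt - 0.1)^2 / (2 * 0.01^2))
  i0 <- round(0.095 / dt) + 1L
  spike <- ifelse(tt >= tt[i0], 12 * exp(-(tt - tt[i0]) / 0.0005), 0)
  ev <- detect_spikelets(trace(v + spike, units = "mV"))
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$time[1L] - tt[i0]), 2.5 * dt) # onset within 2 samples
  expect_gt(ev$amplitude[1L], 5)
})

test_that("responding fraction curve recovers a known midpoint", {
  set.seed(9)
  m <- 1000
  strength <- runif(2000, 0, 2 * m)
  trials <- data.frame(
    strength = strength,
    responded = runif(2000) < plogis((strength - m) / 120)
  )
  edges <- seq(0, 2000, by = 200)
  out <- responding_fraction_curve(trials, edges)
  expect_true(all(out$curve$fraction >= 0 & out$curve$fraction <= 1))
  expect_lt(abs(out$strength_50 - m), 200)

  all_yes <- data.frame(strength = strength, responded = TRUE)
  expect_true(all(responding_fraction_curve(all_yes, edges)$curve$fraction == 1))

  # an empty bin is excluded without disturbing the rest
  sub <- trials[trials$strength < 1800, ]
  out2 <- responding_fraction_curve(sub, edges)
  expect_equal(out2$empty_bins, 1900)
  expect_equal(out2$curve$fraction,
               responding_fraction_curve(sub, edges[-11])$curve$fraction)
})

test_that("responding fraction is non-decreasing on monotone data", {
  set.seed(4)
  strength <- runif(1000, 0, 100)
  trials <- data.frame(strength = strength, responded = strength > 55)
  out <- responding_fraction_curve(trials, seq(0, 100, by = 10))
  expect_true(all(diff(out$curve$fraction) >= 0))
})

# independent oracle: enumerate the full hypergeometric support with
# log-factorials only
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c; N <- m + n2
  lp <- function(x) {
    lfactorial(m) - lfactorial(x) - lfactorial(m - x) +
      lfactorial(n2) - lfactorial(k - x) - lfactorial(n2 - k + x) -
      (lfactorial(N) - lfactorial(k) - lfactorial(N - k))
  }
  supp <- max(0, k - n2):min(m, k)
  p <- exp(lp(supp))
  sum(p[p <= exp(lp(a)) * (1 + 1e-7)])
}

test_that("Fisher exact test equals full enumeration", {
  res <- fisher_exact_2x2(9, 31, 22, 21)
  expect_lt(abs(res$p_two_sided - fisher_oracle(9, 31, 22, 21)), 1e-12)
  expect_equal(res$odds_ratio, 189 / 682)
  expect_lt(res$p_two_sided, 0.05) # the two responder proportions differ

  expect_equal(fisher_exact_2x2(5, 5, 10, 10)$p_two_sided, 1)
  expect_equal(fisher_exact_2x2(0, 0, 3, 4)$p_two_sided, 1)
  expect_true(is.na(fisher_exact_2x2(0, 0, 3, 4)$odds_ratio))

  # symmetry under row and column swaps, on a few random tables
  set.seed(12)
  for (i in 1:20) {
    t0 <- sample.int(15, 4, replace = TRUE)
    p0 <- fisher_exact_2x2(t0[1], t0[2], t0[3], t0[4])$p_two_sided
    expect_equal(fisher_exact_2x2(t0[3], t0[4], t0[1], t0[2])$p_two_sided, p0)
    expect_equal(fisher_exact_2x2(t0[2], t0[1], t0[4], t0[3])$p_two_sided, p0)
  }
})

test_that("group comparison battery", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  expect_equal(compare_groups(x, x, "paired_t"),
               list(statistic = 0, p = 1, test = "paired_t"))

  # WMW exact p from full permutation enumeration
  xs <- c(1, 2, 3); ys <- c(10, 11, 12)
  got <- compare_groups(xs, ys, "wmw")
  pool <- c(xs, ys)
  combos <- combn(6, 3)
  w <- apply(combos, 2, function(idx) {
    sum(rank(pool)[idx]) - 3 * 4 / 2
  })
  w_obs <- sum(rank(pool)[1:3]) - 3 * 4 / 2
  p_enum <- 2 * min(mean(w <= w_obs), mean(w >= w_obs))
  expect_equal(got$p, p_enum)

  lin <- compare_groups(1:10, 2 * (1:10) + 3, "pearson_r2")
  expect_equal(lin$statistic, 1)
  expect_error(compare_groups(1, 2, "wmw"), "at least 2")
})
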