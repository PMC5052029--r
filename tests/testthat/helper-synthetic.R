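# Shared fixture builders; everything is generated in code at test time.

kin_default <- quantal_kinetics()

# passive-cell voltage response to an injection via the exact
# discrete RC convolution (piecewise-constant input), independent of
# the package integrator
rc_convolution <- function(inj, R_in = 250, C_m = 25, E_rest = -85) {
  tau_ms <- R_in * C_m / 1000
  dt_ms <- inj$dt * 1000
  decay <- exp(-dt_ms / tau_ms)
  gain <- (R_in / 1000) * (1 - decay) # mV per pA per step
  v <- numeric(length(inj$values))
  acc <- 0
  for (i in seq_along(inj$values)) {
    acc <- acc * decay + gain * inj$values[i]
    v[i] <- E_rest + acc
  }
  trace(v, dt = inj$dt, t0 = inj$t0, units = "mV")
}

# a single-PSP injection preceded by `pre_s` of baseline
padded_train <- function(Q, n = 1, rate = 100, pre_s = 0.02,
                         duration = 0.3, kin = kin_default) {
  inj <- build_psp_train(kin, n = n, rate = rate, Q = Q, duration = duration)
  trace(c(numeric(round(pre_s / inj$dt)), inj$values), dt = inj$dt,
        units = "pA")
}

# noiseless calcium transient profile: flat baseline `f0`, then a
# template-shaped transient of amplitude `amp * f0` starting at `onset_s`
embedded_transient <- function(template, onset_s, amp, f0 = 1,
                               dt = template$dt, total_s = NULL) {
  if (is.null(total_s)) total_s <- onset_s + template$length_s + 0.5
  n <- round(total_s / dt)
  v <- rep(f0, n)
  Tv <- ng2ca:::template_on_grid(template, dt)
  i0 <- round(onset_s / dt) + 1L
  sl <- i0:(i0 + length(Tv) - 1L)
  v[sl] <- v[sl] + amp * f0 * Tv
  trace(v, dt = dt, units = "au")
}
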