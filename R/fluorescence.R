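#' Calcium indicator and extrusion model
#'
#' Converts a Ca-channel current into a cytosolic calcium concentration
#' and a dye fluorescence signal. Free calcium follows
#' `d[Ca]/dt = influx_gain * i_ca - ([Ca] - ca_rest) / tau_extrusion`
#' and the dye reports it through single-site equilibrium binding
#' `F = F_max * [Ca] / ([Ca] + K_d)` (fast-buffer approximation: dye
#' kinetics are milliseconds, the transients decay over seconds).
#' The default extrusion time constant is 3.16 s, the measured
#' mono-exponential decay of NG2 cell somatic transients; the default
#' dye is 200 uM Fluo-4 with K_d = 335 nM.
#'
#' @param influx_gain calcium accumulation per unit charge, in uM per
#'   pA.s. The default (0.01) puts a strong mock PSP train in the 0.1-0.3
#'   dF/F range typical of proximal dendrites.
#' @param tau_extrusion extrusion time constant in s (default 3.16).
#' @param ca_rest resting free calcium in uM (default 0.1, i.e. 100 nM).
#' @param dye_kd dye dissociation constant in uM (default 0.335).
#' @param f_max fluorescence at dye saturation (arbitrary units).
#' @return An object of class `calcium_model`.
#' @export
calcium_model <- function(influx_gain = 0.01, tau_extrusion = 3.16,
                          ca_rest = 0.1, dye_kd = 0.335, f_max = 1) {
  if (!(tau_extrusion > 0)) stop("`tau_extrusion` must be positive", call. = FALSE)
  if (!(ca_rest > 0)) stop("`ca_rest` must be positive", call. = FALSE)
  structure(
    list(influx_gain = influx_gain, tau_extrusion = tau_extrusion,
         ca_rest = ca_rest, dye_kd = dye_kd, f_max = f_max),
    class = "calcium_model"
  )
}

#' Simulate dye fluorescence from a calcium current
#'
#' Integrates the single-pool calcium balance exactly per step (the
#' influx is held constant within a sample, so each step is a linear
#' first-order update) and maps [Ca] through the dye binding curve.
#'
#' @param model a [calcium_model()].
#' @param i_ca inward calcium current [trace()] in pA (positive =
#'   influx), e.g. from [simulate_membrane()].
#' @return A list with `ca` ([trace()], uM) and `F` ([trace()],
#'   arbitrary units).
#' @export
simulate_calcium_fluorescence <- function(model, i_ca) {
  stopifnot(inherits(model, "calcium_model"), inherits(i_ca, "trace"))
  dt <- i_ca$dt
  tau <- model$tau_extrusion
  fac <- 1 - exp(-dt / tau)
  n <- length(i_ca$values)
  ca <- numeric(n)
  # steady-state target during each step: rest + tau * gain * i_ca
  target <- model$ca_rest + tau * model$influx_gain * i_ca$values
  prev <- model$ca_rest
  for (i in seq_len(n)) {
    prev <- target[i] + (prev - target[i]) * (1 - fac)
    ca[i] <- prev
  }
  if (any(ca < 0)) stop("calcium concentration went negative", call. = FALSE)
  f <- model$f_max * ca / (ca + model$dye_kd)
  list(ca = trace(ca, dt = dt, t0 = i_ca$t0, units = "uM"),
       F = trace(f, dt = dt, t0 = i_ca$t0, units = "au"))
}
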