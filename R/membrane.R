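#' Phenomenological voltage-gated channel specification
#'
#' Channels follow Boltzmann steady-state gating
#' `x_inf(V) = 1 / (1 + exp((half - V) / slope))` with a fixed relaxation
#' time constant per gate (positive `slope` = activation, negative
#' `slope` = inactivation) and ohmic current
#' `I = gbar * m^p * h * (V - reversal)`.
#' Setting `gbar = 0` removes the channel, which is how pharmacological
#' conditions (4-AP, TTX, TEA, Cd/Ni) are modelled on synthetic data.
#'
#' The kinetic constants are not measured quantities; they are a
#' declared calibration chosen so the default cell reproduces the
#' qualitative fingerprints of NG2 cell voltage responses: A-type K
#' current engaging above -60 mV and shortening large PSPs,
#' use-dependent broadening over a 100 Hz train via A-current
#' inactivation, spikelets (not full spikes) when the A-current is
#' removed, and a low-threshold Ca conductance recruited near -45 mV.
#'
#' @param kind one of `"A_type_K"`, `"fast_Na"`, `"delayed_K"`,
#'   `"lowthresh_Ca"`.
#' @param gbar maximal conductance in nS (>= 0).
#' @param reversal reversal potential in mV.
#' @param act_half,act_slope,act_tau activation half-voltage (mV),
#'   slope (mV, > 0) and time constant (ms).
#' @param act_power exponent on the activation gate.
#' @param inact_half,inact_slope,inact_tau optional inactivation gate
#'   (slope < 0); `NULL` means the channel does not inactivate.
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(kind, gbar, reversal,
                         act_half, act_slope, act_tau, act_power = 1,
                         inact_half = NULL, inact_slope = NULL,
                         inact_tau = NULL) {
  kind <- match.arg(kind, c("A_type_K", "fast_Na", "delayed_K", "lowthresh_Ca"))
  if (gbar < 0) stop("`gbar` must be >= 0", call. = FALSE)
  if (!(act_slope > 0) || !(act_tau > 0)) {
    stop("activation slope and tau must be positive", call. = FALSE)
  }
  has_inact <- !is.null(inact_half)
  if (has_inact && (!(inact_slope < 0) || !(inact_tau > 0))) {
    stop("inactivation needs slope < 0 and tau > 0", call. = FALSE)
  }
  structure(
    list(kind = kind, gbar = gbar, reversal = reversal,
         act_half = act_half, act_slope = act_slope, act_tau = act_tau,
         act_power = act_power,
         inact_half = inact_half, inact_slope = inact_slope,
         inact_tau = inact_tau),
    class = "channel_spec"
  )
}

#' Default calibrated channel set for the synthetic NG2 cell
#'
#' One place holding the whole calibration fiction. Conductance
#' densities are unmeasured; these values were chosen (and are easy to
#' override) so that with the default passive cell:
#' * large mock PSPs peaking near -16 mV are shortened to well under
#'   70% of the passive half-width while their amplitude stays within
#'   ~15% of the passive prediction (Na inflow offsets the K loss);
#' * a 100 Hz, 100 ms train progressively broadens PSPs through A-type
#'   inactivation, and removing the A-current abolishes the broadening;
#' * removing the A-current (`gbar_A = 0`, the 4-AP condition) lets the
#'   Na conductance produce spikelets riding on strong PSPs;
#' * the low-threshold Ca conductance is recruited above about -45 mV.
#'
#' @param gbar_A,gbar_Na,gbar_Kdr,gbar_Ca maximal conductances (nS);
#'   set any to 0 to model the corresponding channel block.
#' @return A list of [channel_spec()] objects.
#' @export
default_channels <- function(gbar_A = 100, gbar_Na = 14,
                             gbar_Kdr = 8, gbar_Ca = 3) {
  list(
    # A-type K: low-threshold activation, slow enough (6 ms) to spare the
    # PSP peak while cutting its falling phase; 30 ms inactivation drives
    # the use-dependent broadening over a 100 Hz train
    channel_spec("A_type_K", gbar = gbar_A, reversal = -95,
                 act_half = -45, act_slope = 8, act_tau = 6,
                 inact_half = -78, inact_slope = -6, inact_tau = 30),
    # fast Na: offsets the A-current's amplitude loss in control and
    # produces spikelets (not full spikes) once the A-current is removed
    channel_spec("fast_Na", gbar = gbar_Na, reversal = 60,
                 act_half = -35, act_slope = 6, act_tau = 0.3,
                 inact_half = -55, inact_slope = -7, inact_tau = 3),
    # delayed-rectifier K: caps regenerative events
    channel_spec("delayed_K", gbar = gbar_Kdr, reversal = -95,
                 act_half = -25, act_slope = 9, act_tau = 2),
    # low-threshold (T-type-like) Ca: recruited near -45 mV, slowly
    # inactivating so it cannot latch a depolarized plateau
    channel_spec("lowthresh_Ca", gbar = gbar_Ca, reversal = 120,
                 act_half = -42, act_slope = 5, act_tau = 2,
                 act_power = 2,
                 inact_half = -55, inact_slope = -8, inact_tau = 40)
  )
}

#' Single-compartment cell parameters
#'
#' @param R_in input resistance in MOhm (default 250, the population
#'   average used as the normalization reference).
#' @param C_m membrane capacitance in pF (default 25; NG2 cells are
#'   electrotonically compact, giving a ~6 ms membrane time constant at
#'   250 MOhm).
#' @param E_rest holding/resting potential in mV (default -85, the
#'   current-clamp holding potential).
#' @param conductances list of [channel_spec()]; empty list for a purely
#'   passive cell.
#' @return An object of class `cell_params`.
#' @export
cell_params <- function(R_in = 250, C_m = 25, E_rest = -85,
                        conductances = default_channels()) {
  if (!(R_in > 0) || !(C_m > 0)) {
    stop("R_in and C_m must be positive", call. = FALSE)
  }
  stopifnot(all(vapply(conductances, inherits, TRUE, "channel_spec")))
  structure(
    list(R_in = R_in, C_m = C_m, E_rest = E_rest,
         conductances = conductances),
    class = "cell_params"
  )
}

boltzmann <- function(V, half, slope) 1 / (1 + exp((half - V) / slope))

#' Simulate the membrane voltage response to a current injection
#'
#' Integrates `C dV/dt = -(V - E_rest)/R_in - sum(I_channel) + I_inj`
#' with a fixed-step exponential-Euler scheme on the stimulus grid
#' (reproducibility is preferred over adaptive accuracy; the step is
#' halved internally only if the solution blows up). With all `gbar = 0`
#' this reduces exactly to the passive RC cell, the reference used for
#' the "in the absence of voltage-gated channels" prediction.
#'
#' @param cell a [cell_params()].
#' @param inj injected current [trace()] in pA.
#' @param max_halvings how many internal step halvings to attempt before
#'   giving up on a blow-up (|V| > 200 mV).
#' @return A list with `V` (voltage trace, mV) and `i_ca` (inward
#'   Ca-channel current, pA, positive = Ca influx) on the stimulus grid.
#' @examples
#' cell <- cell_params(conductances = list())
#' out <- simulate_membrane(cell, trace(numeric(100)))
#' range(out$V$values) # flat at -85 mV
#' @export
simulate_membrane <- function(cell, inj, max_halvings = 3) {
  stopifnot(inherits(cell, "cell_params"), inherits(inj, "trace"))
  for (k in 0:max_halvings) {
    refine <- 2L^k
    out <- try(integrate_membrane(cell, inj, refine), silent = TRUE)
    if (!inherits(out, "try-error")) {
      if (k > 0) {
        warning(sprintf("membrane integration used %d-fold step refinement",
                        refine), call. = FALSE)
      }
      return(out)
    }
  }
  stop(sprintf(paste0("membrane integration blew up (|V| > 200 mV) even at ",
                      "dt = %.3g ms; reduce conductances or the stimulus ",
                      "sampling interval"), 1000 * inj$dt / 2^max_halvings),
       call. = FALSE)
}

# Internal fixed-step exponential-Euler core; `refine` subdivides each
# stimulus sample into equal sub-steps (stimulus held constant within a
# sample). Units: mV, ms, nS, pA, pF.
integrate_membrane <- function(cell, inj, refine = 1L) {
  dt_ms <- inj$dt * 1000 / refine
  n <- length(inj$values)
  g_leak <- 1000 / cell$R_in # nS
  E <- cell$E_rest
  chans <- cell$conductances
  nc <- length(chans)

  # unpack channel constants into flat vectors for speed
  gbar <- vapply(chans, `[[`, 0, "gbar")
  erev <- vapply(chans, `[[`, 0, "reversal")
  ah <- vapply(chans, `[[`, 0, "act_half")
  as_ <- vapply(chans, `[[`, 0, "act_slope")
  ap <- vapply(chans, `[[`, 0, "act_power")
  afac <- if (nc) 1 - exp(-dt_ms / vapply(chans, `[[`, 0, "act_tau")) else numeric(0)
  has_h <- vapply(chans, function(ch) !is.null(ch$inact_half), TRUE)
  ih <- vapply(chans, function(ch) ch$inact_half %||% 0, 0)
  is_ <- vapply(chans, function(ch) ch$inact_slope %||% -1, 0)
  hfac <- vapply(chans, function(ch) {
    if (is.null(ch$inact_tau)) 0 else 1 - exp(-dt_ms / ch$inact_tau)
  }, 0)

  V <- E
  m <- if (nc) boltzmann(E, ah, as_) else numeric(0)
  h <- ifelse(has_h, boltzmann(E, ih, is_), 1)
  ica_idx <- which(vapply(chans, `[[`, "", "kind") == "lowthresh_Ca")
  # constant holding current pinning the resting potential at E_rest in
  # current clamp (cancels the standing channel currents at rest)
  I_hold <- if (nc) sum(gbar * m^ap * h * (E - erev)) else 0

  Vout <- numeric(n)
  icaout <- numeric(n)
  for (i in seq_len(n)) {
    I <- inj$values[i] + I_hold
    for (s in seq_len(refine)) {
      if (nc) {
        m <- m + (boltzmann(V, ah, as_) - m) * afac
        h <- ifelse(has_h, h + (boltzmann(V, ih, is_) - h) * hfac, 1)
        g <- gbar * m^ap * h
        Gtot <- g_leak + sum(g)
        drive <- g_leak * E + sum(g * erev) + I
      } else {
        Gtot <- g_leak
        drive <- g_leak * E + I
      }
      Vinf <- drive / Gtot
      V <- Vinf + (V - Vinf) * exp(-dt_ms * Gtot / cell$C_m)
      if (!is.finite(V) || abs(V) > 200) {
        stop("membrane integration blow-up", call. = FALSE)
      }
    }
    Vout[i] <- V
    icaout[i] <- if (length(ica_idx)) {
      sum(gbar[ica_idx] * m[ica_idx]^ap[ica_idx] * h[ica_idx] *
            (erev[ica_idx] - V))
    } else 0
  }
  list(V = trace(Vout, dt = inj$dt, t0 = inj$t0, units = "mV"),
       i_ca = trace(icaout, dt = inj$dt, t0 = inj$t0, units = "pA"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
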