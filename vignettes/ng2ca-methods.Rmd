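---
title: "Models and methods behind ng2ca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ng2ca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ng2ca)
```

This vignette is the package's own account of the science it
implements: the models, their assumptions, the parameters that matter,
and the places where the design was genuinely open and a choice had to
be made. Nothing stated here as a result goes beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## 1. The scientific problem

NG2 glial cells receive bona fide synaptic input but never fire action
potentials. The question the pipeline addresses is how such a cell
converts graded postsynaptic potentials (PSPs) into intracellular
calcium signals, and what role a low-threshold, fast-inactivating
A-type K⁺ conductance plays in gating that conversion. The
experimental design it mirrors: inject miniature-EPSC-shaped "mock
PSP" currents in current clamp, image dye-reported calcium with
two-photon line- and frame-scans, detect responses with a scaled
template, and compare the spatiotemporal spread of the signal with the
prediction of purely diffusional propagation.

## 2. Stimulus construction

The elementary quantum is a difference of exponentials
$w(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}$, peak-normalized and
scaled to the quantal amplitude $q = 12$ pA (literature consensus for
miniature EPSCs in these cells). **The kinetic constants are not
printed anywhere**: the defaults $\tau_r = 0.2$ ms, $\tau_d = 1.2$ ms
are a declared choice giving a sub-millisecond-rising,
few-millisecond quantal current, and both are arguments of
`quantal_kinetics()`. Stimuli are currents, so construction is exactly
linear: trains and Gaussian barrages are superpositions of shifted
copies (tested to 1e-9). Driving-force changes are neglected by
design.

Release times of the Gaussian barrage are drawn
i.i.d. $N(\text{center}, \sigma)$ with $\sigma = 25$ ms; the default
center is $4\sigma$, placing $>$ 99.99% of events inside the window.
The rare event falling outside is **clipped to the window edge, not
dropped**, so the stimulus always contains exactly
`n_syn * q_per_syn` quanta (ground truth stays consistent); clipping
warns. Onsets snap to the nearest 20 kHz sample, ties toward zero.

Stimulus strength is normalized as $Q \cdot R_\mathrm{in}$ in
multiples of 250 MΩ, the population-average input resistance, which
makes stimuli comparable across cells whose resistance varies by more
than an order of magnitude.

## 3. The synthetic cell

The generator replaces non-redistributable slice recordings. It is a
*stated world*, not a fit to data.

**Membrane.** One compartment,
$C\,dV/dt = -(V-E)/R_\mathrm{in} - \sum I_\mathrm{chan} + I_\mathrm{inj}$,
integrated with fixed-step exponential Euler on the 20 kHz stimulus
grid. Reproducibility beats adaptive accuracy here: the step is halved
only if the solution exceeds |200| mV, and then the run warns.
Defaults: $R_\mathrm{in} = 250$ MΩ, $E = -85$ mV (the current-clamp
holding potential), $C_m = 25$ pF. The capacitance is unprinted; 25 pF
gives the ~6 ms membrane time constant of an electrotonically compact
glial cell and keeps single PSPs bracketed inside 10 ms train windows.
A constant holding current cancels the standing channel currents at
rest, exactly as a current-clamp amplifier holding at −85 mV would, so
`inj = 0` yields a flat −85 mV trace even with active conductances.

**Channels.** Four phenomenological Boltzmann-gated conductances
(`default_channels()`), whose densities and kinetics are *declared
fiction* — no quantitative values exist to reproduce — calibrated once
against the qualitative fingerprints the pipeline must reproduce, and
then frozen:

| channel | role | key defaults |
|---|---|---|
| A-type K⁺ (100 nS) | shortens large PSPs; its 30 ms inactivation produces use-dependent train broadening | act. −45 mV/8 mV, τ 6 ms; inact. −78 mV, τ 30 ms |
| fast Na⁺ (14 nS) | offsets the A-current's amplitude loss; spikelets when A is blocked | act. −35 mV, τ 0.3 ms; inact. −55 mV, τ 3 ms |
| delayed K⁺ (8 nS) | caps regenerative events | act. −25 mV, τ 2 ms |
| low-threshold Ca²⁺ (3 nS) | calcium entry above ≈ −45 mV | act. −42 mV (squared gate), τ 2 ms; slow inact. τ 40 ms |

The A-current's 6 ms activation is the load-bearing choice: it is slow
enough to spare the PSP peak (amplitude ratio vs passive stays within
0.85–1.15 for peaks up to ≈ −10 mV) while cutting the falling phase
(half-width ratio ≈ 0.36 near a −16 mV peak; the acceptance suite
asserts < 0.7). The Ca²⁺ conductance inactivates slowly so it cannot
latch a depolarized plateau. Setting any `gbar` to zero models the
corresponding pharmacology (4-AP, TTX, TEA, Cd²⁺/Ni²⁺) as a pure
group label.

**Calcium and dye.** A single pool,
$d[\mathrm{Ca}]/dt = \gamma\,i_\mathrm{Ca} - ([\mathrm{Ca}] -
\mathrm{Ca}_\mathrm{rest})/\tau$, with $\tau = 3.16$ s (the measured
mono-exponential decay of somatic transients) and
$\mathrm{Ca}_\mathrm{rest} = 100$ nM. The dye reports through
single-site equilibrium binding $F = F_\mathrm{max}[\mathrm{Ca}] /
([\mathrm{Ca}] + K_d)$, $K_d = 335$ nM (Fluo-4). The fast-buffer
approximation is justified by scale separation: dye kinetics are
milliseconds, transients seconds. The influx gain (0.01 µM per pA·s)
is the one free knob; it was set so a strong mock-PSP train lands in
the 0.1–0.3 ΔF/F range typical of proximal dendrites, and it is a
plain argument.

**Imaging.** Expected counts are `background + photon_budget ×
F/F(0)`; pixel values are Poisson draws (no read noise — two-photon
PMT counting is shot-noise dominated at these budgets). The first
`n_dark_lines` rows are rendered laser-off, carrying only the
background offset: that is the background estimator the analysis
subtracts. A red, calcium-blind tracer channel is rendered at constant
brightness for ΔG/R normalization. Line rate must sit in the
100–300 Hz acquisition band; frame series run at 30 Hz. Images are
written as plain baseline 16-bit TIFF by a purpose-built minimal
writer (no TIFF library exists in the target R environment); the
test-suite validates it against an independent Python reader.

**What a green test does and does not establish.** The generator
reproduces the *qualitative* control/4-AP fingerprints and exact
Poisson photon statistics. It does not model dendritic cable
structure, stochastic channel gating, dye diffusion, bleaching, or
motion — so green calibration tests establish that the analysis code
behaves correctly on data with these statistics, not that the
biological effect sizes are reproduced.

## 4. Voltage metrics

Half-amplitude crossings are located by linear interpolation between
bracketing samples, first crossing from the left and last from the
right — stable to sub-sample precision at 20 kHz and well-defined on
noisy traces. Metrics are invariant under time shift and baseline
offset, and half-width scales exactly under time dilation (property
tests). Train half-widths are measured per inter-onset window against
the *local* membrane potential at the window start, because later PSPs
ride on residual depolarization; the broadening statistic is
$100(hw_{10}/hw_1 - 1)$.

Spikelet detection (threshold crossing of dV/dt followed by a local
maximum) uses declared defaults of 5 mV/ms and 5 mV; nothing in the
source material defines the method, so it is documented as such.

The responder-fraction curve takes config-supplied bin edges (the
source prints none); empty bins are flagged and excluded, and the 50%
point is linearly interpolated between adjacent bin centers at the
first upward crossing.

`fisher_exact_2x2` computes the two-sided p as the sum of all
hypergeometric tables with probability ≤ the observed table's
("sum of small-p tables"); this convention is stated explicitly
because two-sided Fisher conventions differ. The
Wilcoxon–Mann–Whitney test is exact for group sizes ≤ 12 without ties
and uses the continuity-corrected normal approximation above that.

## 5. Imaging quantification

ΔF/F windows are anchored to the injection start per the measurement
convention: F₀ averages the 150 ms immediately before, F_peak the
150 ms starting 100 ms after. Both windows and the delay are arguments
(train stimuli of other lengths need shifted windows). Windows are
computed on *unsmoothed* profiles by default; the sliding average
(5 or 9 points) exists for display and detection, and shrinks at the
edges rather than reflecting so no data are invented at the trace ends
where F₀ lives. The "width of 2 pixel" Gaussian display filter is
interpreted as σ = 2 px (time) × 1 px (space); the word "width" is
ambiguous and the interpretation is a config default.

Decay fits use variable projection — amplitudes and offset solved by
linear least squares for candidate time constants, only log-τ
optimized numerically — which needs no starting values and cannot be
trapped by amplitude/offset collinearity. The bi-exponential is
accepted only when the nested F-test rejects the mono fit at
α_F = 0.01 (unprinted; a config key), and an exact mono fit
short-circuits the F-test, whose statistic is meaningless on
machine-precision residuals. The reported constant for bi fits is the
amplitude-weighted τ.

## 6. Template detection

The criterion contract is fixed as: least-squares fit of
scale·T + offset, criterion = scale / SE(scale) with
SE = residual SD / √Σ(T−T̄)². It is invariant to scaling the profile
by k > 0 and to adding any constant (both at 1e-6 in tests), recovers
exact embeds to 1e-9, and its false-positive rate on pure Gaussian
noise at the 3.0 threshold is below 5% (1,000 seeded trials; the
criterion is a t-like statistic, so ~0.1–0.2% is expected and
observed). Noiseless fits are capped at 1e6; genuinely flat segments
report 0 rather than a machine-noise ratio. Classification is
stimulus-aligned; onset estimation slides the 1 s template over the
profile resampled at 1 kHz and takes the criterion-maximizing lag
(earliest on ties), subject to the same threshold — matching the two
distinct uses of the template in the original workflow.

## 7. Buffered diffusion

$\kappa = [B]K_d/(K_d + [\mathrm{Ca}]_\mathrm{rest})^2$ evaluated at
rest; buffers specified only by a binding ratio carry it verbatim
(endogenous κ = 20). $D_\mathrm{app} = (D_\mathrm{Ca} + \sum_\mathrm{
mobile} D_B \kappa_B)/(1 + \sum \kappa_B)$; with the default dye load
this evaluates to ≈ 95 µm²/s (asserted in the acceptance suite
together with κ ≈ 354.1).

The early propagation front is fixed: $x = 2\sqrt{D_\mathrm{app}t}$
for $t \le t_c = \tau_\mathrm{decay}/10 = 316$ ms. **The late-time
(extrusion-limited) expression is typographically corrupted in its
printed source and cannot be recovered dimensionally.** The package
therefore makes the late regime pluggable (`late_front` in
`diffusion_model()`) and ships a documented default: the
C¹-continuous saturating continuation
$x(t) = 2\sqrt{D_\mathrm{app}t_c}\,(2 - \sqrt{t_c/t})$, which matches
position and velocity at the crossover and saturates at twice the
crossover distance, expressing that extrusion stalls a purely
diffusional front within a few hundred milliseconds. This default is a
modelling choice of this package, not an authoritative reconstruction;
any custom form is checked for continuity at the crossover and warns
if it breaks it. `predicted_onset_delay` inverts the front (closed
form in regime 1, bisection beyond) and flags unreachable distances.

## 8. Numerical choices, in one place

* Integrator: exponential Euler, fixed 20 kHz step; halving only on
  blow-up, with a warning.
* Onset snapping: nearest sample, ties toward zero.
* Half-width ties: first crossing from the left, last from the right.
* Criterion cap 1e6; numeric-zero guard at `1e-10 (max|y| + 1)`.
* F-test α for decay model selection: 0.01.
* Manifest JSON written with fixed formatting so equal seeds give
  byte-identical files.

## 9. Known limitations

Single compartment only (no cable filtering of PSPs, no local
dendritic calcium compartments); deterministic channel gating; the
dye model omits binding kinetics and diffusion; the renderer omits
read noise, bleaching and motion; channel kinetics are calibrated
fiction constrained by qualitative behavior, so absolute conductance
values carry no biological meaning; and the late-time diffusion front
is a declared default, not a derived result.
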