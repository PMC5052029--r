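Package: ng2ca
Title: Synaptic Integration and Calcium Signal Analysis for NG2 Glial Cells
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how NG2 glial cells convert synaptic
    depolarizations into intracellular calcium signals. Builds mock
    postsynaptic-potential current stimuli (quantal EPSCs, 100 Hz trains,
    Gaussian-dispersed quantal barrages) with quanta-times-input-resistance
    strength normalization; simulates a single-compartment membrane with
    phenomenological A-type potassium, sodium and low-threshold calcium
    conductances plus a dye-fluorescence forward model and a Poisson-noise
    line-scan renderer with ground-truth manifests; quantifies voltage
    responses (amplitude, half-width, train broadening, spikelets,
    responding-fraction curves, Fisher exact and rank tests); analyses
    line- and frame-scan fluorescence (background subtraction, profiles,
    smoothing, delta-F over F, delta-G over R, mono/bi-exponential decay
    fitting with F-test model selection); detects calcium responses with a
    sliding scaled-template criterion; and predicts buffered-diffusion
    propagation fronts from apparent diffusion coefficients.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
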