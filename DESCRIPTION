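Package: ca1forge
Title: Desk-Scale Reconstruction and Simulation of the Hippocampal CA1 Circuit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and exercising a miniature, fully synthetic
    model of the rat hippocampal CA1 microcircuit: parametric
    longitudinal/transverse/radial atlas coordinates on voxel masks,
    morphology curation and topological (persistence) validation,
    rule-scored soma placement, touch-detection connectome synthesis with
    bouton-density pruning, Schaffer-collateral afferent projections,
    stochastic Tsodyks-Markram synapses with multivesicular release and
    cholinergic/calcium modulation, stimulus generators, a surrogate
    point-neuron network simulator, and a spectral/spike analysis suite
    (multitaper PSD, Morlet spectrograms, CSD, spike-phase locking, STTC,
    theta-waveform asymmetry).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
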