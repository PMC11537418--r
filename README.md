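# ca1forge

Desk-scale reconstruction and simulation of the rat hippocampal CA1
microcircuit, packaged as a tested R library with a thin command-line
dispatcher. The package re-creates, on fully synthetic volumes and
parametric morphologies, the workflow used to assemble community
atlas-based CA1 circuit models: every stage runs on a laptop in seconds to
minutes, and every stage is validated against closed-form geometry,
brute-force oracles, or in-paper worked examples.

## What it does

**Atlas coordinates.** A voxelized region mask is smoothed
(Gaussian + morphological closing), a centerline is extracted along the
ridge of the distance transform (weighted Dijkstra, cubic-spline fit), and
each voxel gets parametric coordinates (l, t, r) in [0, 1] along the
longitudinal, transverse and radial axes. The radial coordinate is the
relative position of the voxel along the segment connecting the lower
(stratum oriens / alveus, r = 0) and upper (stratum lacunosum-moleculare /
pial, r = 1) boundary shells; orientation vectors are the normalised
gradient of r. Layers (SO, SP, SR, SLM) occupy fixed r-intervals derived
from mean layer thicknesses.

**Morphologies.** SWC read/write, curation (soma centering, shrinkage
correction, zero-length-segment removal), +/-15% scale-and-jitter cloning,
PCA realignment of axons to the transverse axis, the
median-over-visible-spread (MVS) population score
`|median(A) - median(B)| / OVS(A, B)`, and topological validation by
persistence diagrams: a radial-distance filtration with the elder rule
(one bar per branch tip) plus Gaussian persistence images.

**Placement.** Composition from pyramidal-cell density x SP volume with
interneuron pools rescaled to an 89:11 E/I ratio; density-weighted
multinomial soma placement; orientation of the morphology y-axis along the
radial direction; and rule scoring

    S = I * L,   I = harmonic mean of optional interval scores
                 L = min of strict interval scores
    interval score = max(overlap(a + y0, r) / max(|a|, |r|), 0)

with an aggregate of 0 whenever any optional score falls below 0.001.

**Connectome.** Touch detection (axo-dendritic/somatic appositions within
1.0 um onto pyramidal cells, 6.0 um onto interneurons; axo-axonic cells
restricted to the PC axon initial segment, PC-PC contacts to dendrites,
SCA/Ivy/BS kept off PC somata), the appositions-to-synapses predictions
(0.1096x for I-I pathways, 1.1690x otherwise), and two-stage stochastic
pruning to target mean synapses per connection and a bouton-density
distribution with CV 0.50 (1.15 synapses per bouton).

**Schaffer collaterals.** Convergence targets as midpoints of reported
ranges (20,878 synapses per PC; 12,714 per interneuron), largest-remainder
layer allocation (SLM 0.3%, SR 67.9%, SP 7.1%, SO 24.7%), length-weighted
segment sampling with uniform offsets, and uniform fiber assignment.

**Synapses.** A stochastic Tsodyks-Markram model with multivesicular
release: facilitation u jumps by U_SE (1 - u) per spike and decays with
tau_facil; each of N_RRP vesicles recovers with rate 1/tau_rec and releases
independently with probability u. Extracellular calcium scales U_SE through
a normalised Hill function, and acetylcholine acts through two fitted Hill
curves:

    I_depol(ACh) = 0.567 * ACh^0.436 / (100^0.436 + ACh^0.436)   [nA]
    U_SE scaling = 1 / (1 + (ACh / 4.541)^0.576)

Grid-search fitting machinery (summed relative-error cost, alternating
two-step optimisation over conductance/pool-size and AMPA kinetics) and PSP
feature extraction complete the physiology layer.

**Stimuli, network, analysis.** Homogeneous and sinusoidal (offset =
amplitude) Poisson generators via thinning, phase-histogram rate functions,
medial-septum disinhibition waveforms (mean = -amplitude), rheobase
bisection, a surrogate adaptive-exponential point-neuron network with a
point-source LFP proxy, and the analysis stack: zero-phase 6th-order
Butterworth band splitting (LFP < 400 Hz, downsampled to 400 Hz; delta,
theta, gamma), sine-taper multitaper PSD at 1.5 Hz resolution, Morlet
wavelet spectrograms (7 cycles), 1-D current source density, Hilbert
spike-phase locking with the Rayleigh test (trough = 0 degrees), the
theta-waveform asymmetry index log(t_rise / t_decay), the spike time tiling
coefficient (STTC), spike correlograms, input-output gain, and an augmented
Dickey-Fuller stationarity check.

## Worked example

```r
library(ca1forge)

# layer proportions from mean thicknesses (um): SO 168, SP 59, SR 279, SLM 146
round(layer_proportions(c(SO = 168, SP = 59, SR = 279, SLM = 146)), 5)
#>      SO      SP      SR     SLM
#> 0.25767 0.09049 0.42791 0.22393

# stochastic multivesicular release over an 8-spike 30 Hz train
p <- tm_params(u_se = 0.5, tau_rec = 500, tau_facil = 50, n_rrp = 12)
tm_release(seq(0, by = 1000 / 30, length.out = 8), p, seed = 1)[, 1:3]
#>     time released g_peak
#> 1   0.00        6      6
#> 2  33.33        3      3
#> 3  66.67        1      1
#> 4 100.00        2      2
#> 5 133.33        0      0
#> 6 166.67        1      1
#> 7 200.00        0      0
#> 8 233.33        1      1

# cholinergic depolarization (nA) across concentrations (uM)
round(ach_current(c(0, 10, 100, 1e6)), 4)
#> [1] 0.0000 0.1521 0.2835 0.5570

# the bouton-density worked example: 51 single-synapse and 13 multi-synapse
# (3.69 each) connections
bouton_stats(c(rep(1, 51), rep(3.69, 13)))
#> mean 1.55, sd 1.08, cv 0.70
```

The first spike depresses the synapse (6 of 12 vesicles released, then the
pool refills slowly at tau_rec = 500 ms); the release counts track the
deterministic u*x recursion in expectation. The ACh current passes through
its half-maximum 0.2835 nA at the half-concentration 100 uM and saturates
at 0.567 nA.

## Command line

```sh
Rscript inst/cli/ca1forge.R fixtures --kind slab --out fx/
Rscript inst/cli/ca1forge.R atlas --mask fx/mask.nrrd \
    --endpoints 5,60,60 995,60,60 --out atlas/
Rscript inst/cli/ca1forge.R simulate --config sim.yaml --out sim/
```

All formats are plain text: NRRD (text encoding) for volumes, SWC for
morphologies, two-column spike tables, TSV cell/synapse stores, JSON
reports with provenance records.
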