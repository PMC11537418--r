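---
title: "Methods: desk-scale CA1 reconstruction and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale CA1 reconstruction and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical choices made where the design
was genuinely open, and what the synthetic test beds do and do not show
about real data. No empirical result is stated here that the test suite or
the acceptance script does not itself compute.

## The problem

Community reconstructions of the rat CA1 build a full-scale circuit from
heterogeneous data: a voxelized atlas volume, a library of reconstructed
morphologies, layer-wise composition and density constraints, proximity-
based ("touch detection") connectivity pruned to anatomical statistics,
the Schaffer-collateral afferents from CA3, short-term-plastic synapses,
and neuromodulation. `ca1forge` re-implements that pipeline at desk scale:
the same operations and scoring rules, exercised on synthetic volumes and
parametric morphologies small enough that every stage can be checked
against closed geometry or a brute-force oracle.

## Atlas coordinates

A `ca1_mask` is a dense boolean voxel grid with a voxel edge in
micrometres. Smoothing is a Gaussian filter (sigma in um, exposed as
config since no canonical value exists) followed by a morphological
closing (radius in voxels) and retention of the largest connected
component. Two numerical choices matter at the array border: the Gaussian
is renormalised by the in-array kernel mass (normalized convolution), and
the erosion half of the closing treats out-of-array voxels as occupied;
without these, a solid block loses its edges and corners.

The centerline follows the ridge of the interior distance transform,
computed by iterated 26-neighbour chamfer relaxation with Euclidean step
weights. A weighted Dijkstra search (edge cost = step length times the
mean inverse distance-transform value of its endpoints, floored at half a
voxel) runs between the two seed points, and the voxel path is
approximated by natural cubic splines in each coordinate over ~15 control
points. A spline rather than a Bezier curve carries the same information
with an analytic derivative.

Coordinates follow a three-step assignment. Cross-section planes are
sampled at one per voxel of arc length (the spec leaves the spacing open;
one-per-voxel makes the longitudinal quantisation equal to the grid
resolution). Each voxel and each boundary-shell point joins its nearest
plane, with ties broken toward lower l. Within a plane, the upper and
lower shell traces are ordered along the in-plane transverse axis,
parameterised by normalised arc length u, resampled to a common count, and
connected; a voxel takes t from its nearest connecting segment and r as
its relative position along that segment (r = 0 on the SO/alveus side).
Planes that receive no shell points (possible where spline curvature
bunches planes) borrow the nearest plane's shell trace. Voxels that remain
unassigned are filled from their nearest assigned neighbour; more than 1%
unassigned is an error. Finally, orientation vectors are recomputed as the
normalised numerical gradient of r, which guarantees exact correspondence
between the vector field and the coordinate space and makes
shell-exchange antisymmetry automatic.

Shells are *inputs* (point sets or voxel masks), not derived by the
package: automated shell separation is known to be unreliable on curved
cortices, so the fixtures generate them analytically. On the analytic
quarter-annulus (inner radius 40, outer 60, 24 voxels thick, 10 um voxels)
the measured r deviates from the cylindrical ratio by < 0.006 and gradient
directions deviate from radial by ~1 degree (99th percentile < 5).

Layers cut r into consecutive intervals ordered SO, SP, SR, SLM from
r = 0. Proportions derived from mean dorsal thicknesses
(SO 168, SP 59, SR 279, SLM 146 um) give SR = 0.42791 to five decimals.

## Morphologies

Curation centres the soma, removes zero-length segments, flags axon-less
cells, and compensates slice shrinkage by anisotropic scaling (defaults
0: the caller states the correction; typical histology needs ~25% in z
and ~10% in x/y). Cloning scales isotropically within +/-15% and
diversifies branches with a seeded per-branch rotation about the parent
direction (N(0, sigma_rot)) and a length factor (N(1, sigma_len), floored
at 0.2). The generating tool's actual jitter distributions are not public;
this parameterisation is a declared stand-in, and every property the
package asserts about clones (exact length scaling, bar scaling of
persistence diagrams, byte-identical reruns under a seed) is independent
of its details.

The MVS score is |median difference| / OVS. "Overall visible spread" has
no published definition; the default is the width of the union of the two
boxplot whisker intervals [Q1 - 1.5 IQR, Q3 + 1.5 IQR], consistent with
the visual-spread reading and with the score's known sample-size
dependence, and the function is a pluggable argument so other conventions
drop in. Scores below 0.3 are labelled good agreement.

Persistence diagrams use the radial filtration measured from the soma
*surface* (soma radius subtracted, floored at 0) and the elder rule: at a
branch point the component whose tip lies farthest survives; each death
contributes a bar (tip distance, merge distance), one per leaf. Apical,
basal and axonal trees are filtered separately. Persistence images average
Gaussian kernels over bars on a common grid and normalise to unit mass, so
population differences subtract cleanly.

## Placement

Composition fixes the pyramidal count as density x SP volume (264e3 /mm3
x 1.5789 mm3 = 416,830 after rounding; the package reports the computed
product rather than forcing any printed variant of it) and rescales
interneuron pools so inhibitory cells are 11% of the total. Placement
draws per-voxel counts from a multinomial with density-proportional
weights — fractional expectations are never rounded independently, so the
total is conserved exactly — and positions cells uniformly within voxels.
SR_SCA is confined to mid-SR (0.5 +/- 0.05 of the layer), SLM_PPA to the
lower SLM band (0.02-0.10).

Rule scoring is the product of a harmonic mean over optional interval
scores (zero if any optional score < 0.001) and a minimum over strict
scores; each interval score is overlap over the larger width, floored at
zero, after shifting the morphology interval by the soma position. The
harmonic mean penalises a single poor rule harder than an arithmetic mean
but lets strong rules rescue a mediocre one. Morphology choice samples
proportionally to score — "best fit" with a stochastic tie rule — with a
deterministic argmax available; positions whose candidates all score zero
are dropped and counted (a tolerance of 5% is a warning, not an error;
full-scale builds observed 2.6%).

## Connectome

Touch detection records an apposition wherever a presynaptic axon segment
passes within 1.0 um of a pyramidal target or 6.0 um of an interneuron
target. Segment-segment distances use the standard closest-point
algorithm with the full clamp sequence, vectorised over target segments;
somata are spheres (distance measured to the surface). A bounding-box
prefilter speeds up distant pairs and is verified to leave the result
identical to brute force; tests additionally re-derive distances with an
independent dense two-parameter grid search. Compartment admissibility:
axo-axonic cells contact only the PC axon initial segment (defined as the
first 60 um of axonal path length — unquantified in the literature, so
config-exposed), PC-PC contacts are dendritic, and SCA/Ivy/BS avoid PC
somata.

Pruning applies two constraint families. Synapse-level binomial thinning
with probability target/current brings the mean synapses per connection to
its target; connections that lose every synapse vanish, which removes
whole (mostly small) connections first and preserves the positive skew of
the multiplicity distribution. Axon-level thinning then draws each axon a
target bouton density from a gamma distribution with the requested mean
and CV (0.50 by default; the gamma shape is 1/CV^2) and thins that axon's
synapses to it; bouton counts are synapse counts divided by 1.15. The
division convention — realized synapses are divided by 1.15 before
comparison with bouton-density targets — was the open question; dividing
keeps the anatomical bouton data untouched. Infeasible targets (more than
available) keep all synapses and flag the pathway.

## Schaffer collaterals

Per-class convergence targets are midpoints of reported ranges; the
workflow runs separately for pyramidal cells and interneurons. Layer
totals use largest-remainder rounding (exact conservation); within a
layer, postsynaptic segments are sampled with replacement weighted by
length (so short segments are not oversampled) and synapses sit at
uniform offsets; somata are excluded. Fibers are assigned uniformly, so
per-fiber divergence is multinomial. Uniformity along l and t is
implemented by ignoring (l, t) during sampling.

## Synapse physiology

The stochastic Tsodyks-Markram model tracks a facilitation variable u
(decay tau_facil, jump U_eff (1 - u) per spike) and N_RRP vesicles, each
recovering independently with rate 1/tau_rec and releasing at a spike with
probability u. Expectations follow the classic deterministic u*x
recursion, which the tests verify at 3 Monte-Carlo sigma over thousands of
trials. Release probability is modulated multiplicatively by extracellular
calcium — a Hill curve normalised to 1 at 2 mM with profile exponents
steep 4 / intermediate 3 / shallow 2 and half-concentration 2.3 mM, all
declared stand-ins since the calibrated coefficients are unpublished — and
by acetylcholine through the fitted factor 1 / (1 + (ACh/4.541)^0.576).
The depolarizing ACh current is 0.567 ACh^0.436 / (100^0.436 + ACh^0.436)
nA, injected somatically in the surrogate network (the factor and its
application are separate functions so each is testable). Spontaneous
minis are an independent Poisson process per synapse driven through the
same release machinery.

Fitting uses the summed relative-error cost and an alternating two-step
grid search — (g_max, N_RRP) against amplitude/variability targets, then
AMPA (tau_rise, tau_decay) against kinetics targets — iterated to
stability; on-grid generating parameters of a synthetic experiment are
recovered exactly.

## Stimuli and the surrogate network

Sinusoidal rate functions use offset = amplitude, so the rate touches zero
at the trough; an explicit amplitude argument covers the alternative
reading. Inhomogeneous trains are generated by Lewis-Shedler thinning,
which is exact for bounded rates. The medial-septum disinhibition waveform
is -A + A sin(2 pi f t): mean -A, never depolarizing.

The network is deliberately a surrogate: adaptive exponential
integrate-and-fire point neurons (delta_T = 0 recovers leaky
integrate-and-fire with closed-form rheobase g_L (V_T - E_L), which the
bisection rheobase — returning the upper bound of its final bracket —
must match). Synaptic conductances aggregate per neuron into
single-exponential excitatory (tau 3 ms, E_rev 0 mV) and inhibitory
(tau 8 ms, E_rev -80 mV) channels; per-synapse stochastic TM state drives
the increments. Bath conditions act globally (calcium and ACh on U_SE,
ACh current into every cell); temperature and Mg are recorded condition
tags only. The extracellular signal is a point-source sum
I / (4 pi sigma d) with sigma = 0.3 S/m and a 10 um distance floor — a
proxy, not a forward model, so all field-potential claims in the tests
are property-level (distance scaling, dipole cancellation), never
value-level.

Consequently nothing here reproduces full-scale results that depend on
detailed multicompartment models: absolute LFP magnitudes, in vivo theta
phase-locking angles, or published asymmetry-index values are out of
scope by design.

## The toy-slice input-output experiment

The fixture circuit for the volley experiment has 110 pyramidal cells and
25 interneurons wired statistically (each PC: 40 SC synapses from a
350-fiber pool and 8 inhibitory inputs; each interneuron: 25 SC synapses
and 10 local excitatory inputs). The SC conductances (0.3 nS/vesicle onto
PCs, 4.0 nS/vesicle onto interneurons) were calibrated once, during
fixture design, to the experiment's own anchor: the full 350-fiber volley
recruits 100% of the 101 sampled neurons. Under those conditions the
control curve (feedforward inhibition intact) is more linear than the
GABA-blocked curve — Pearson r ~0.92 vs ~0.89, consistently across five
seeds — because inhibition recruited in proportion to the input delays
saturation. The effect is emergent, not programmed.

## Analysis

All filters are zero-phase (forward-backward 6th-order Butterworth), a
choice made because spike-phase analysis downstream cannot tolerate
filter-induced phase shifts; the impulse response is verified symmetric.
The raw 2 kHz signal splits at 400 Hz, the LFP is decimated to 400 Hz
(FIR anti-aliasing), and delta/theta/gamma bands are 1-3 / 4-12 /
30-120 Hz. The multitaper PSD uses sine tapers with the taper count set by
the time-bandwidth product for a 1.5 Hz resolution, scaled to satisfy
Parseval within 5%. The Morlet transform uses 7 cycles over 1-150 Hz in
0.25 Hz steps, reported in dB with a floor for silent signals. CSD is the
regularised second spatial difference with optional Gaussian channel
smoothing; it returns constants for quadratic depth profiles and zero for
linear ones, and localises synthetic dipoles to within a channel.

Spike phases come from the Hilbert analytic signal with the theta trough
at 0 degrees; per-cell locking is the circular resultant with the Rayleigh
test (the standard large-n approximation of the p-value, calibrated to a
5% +/- 2% type-I rate in the tests); cells with fewer than 10 spikes are
excluded and counted. The asymmetry index detects peaks and troughs by
z-score thresholding (default |z| > 1 — the published threshold is
unstated, so it is config) and reports log(t_rise / t_decay) per cycle.
STTC uses 10 ms tiles with exact union-length computation. The ADF
stationarity check linearly detrends first, so the trend-case 5% critical
value (-3.41) applies; it is implemented directly by OLS on the standard
augmented regression because no installed package provides it. The first
1,000 ms of any simulation are discarded before analysis.

## Problem sizes and determinism

Test-bed sizes are chosen so the full suite runs in about a minute on one
CPU: slabs of 40 x 12 x 12 voxels, a 40/60-radius quarter annulus, 20-cell
touch-wired circuits, 135-cell volley circuits, 3,000-5,000 Monte-Carlo
trials for release statistics. A single global seed fans out to named
substreams (`substream_seed`), and seeded helpers restore the caller's RNG
state, so module-level reruns are independent and bit-reproducible; every
pipeline run can emit a JSON provenance record.

## Known limitations

Point neurons cannot express dendritic computation, backpropagating
action potentials, or realistic LFP generators; the synthetic morphologies
are statistical trees without reconstruction artefacts (cut neurites,
diameter noise) so curation is exercised only on constructed cases; the
clone-jitter and calcium-profile parameterisations are stand-ins; and the
NRRD reader covers exactly the text-encoded subset the package writes.
Passing the property suites shows the algorithms are implemented
correctly under controlled geometry, not that the surrogate reproduces
biological CA1 dynamics.
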