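---
title: "Quantifying basal actomyosin networks: models, estimators and design choices"
author: "basalact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying basal actomyosin networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basalact)
```

## Scope

The basal surface of follicle cells (FCs) in the *Drosophila* egg chamber
carries three actin populations: parallel actomyosin stress fibers anchored
at integrin adhesions, a cortical ring along each cell-cell boundary, and
whip-like protrusions anchored at tricellular junctions. Integrin-null
(*mys*) clones inside wild-type tissue reorganise these networks: fewer and
dimmer fibers, more whips, a cortical F-actin build-up restricted to
mutant-mutant boundaries, higher junctional tension, shorter and more
erratic actomyosin oscillations, near-isotropic basal contractions, and a
basal surface that fails to expand.

`basalact` implements the measurement side of this biology as reusable
estimators — line-profile fiber scoring, boundary-bar cortical profiling,
oscillation spectral analysis, laser-ablation recoil velocimetry, and
label-image morphometry — plus a synthetic-data generator that emulates the
live-imaging data with recorded ground truth, so every estimator can be
validated by parameter recovery rather than against inaccessible raw
movies.

## The synthetic generator and the conditions it encodes

`synth_config()` fixes the study conditions once. All effect sizes are
transcribed from the measured biology:

| parameter | control | mutant | meaning |
|---|---|---|---|
| `fiber_count_per_cell` | 6 | 3 | parallel bundles per basal surface |
| `fiber_intensity` (a.u.) | 200 | 80 | F-actin peak height; 80/200 = the 60% reduction |
| `myosin_intensity` (a.u.) | 150 | 90 | myosin peak height; 90/150 = the 40% reduction |
| `cortical_intensity` (a.u.) | 100 | 200 | the two-fold junctional F-actin increase (basal only) |
| `whip_count_leading_edge` | 2 | 6 | whips per cell at the leading edge ("more than 5" in mutants) |
| `oscillation_period_s` | 480 | 300 | basal actomyosin pulse period |
| `period_jitter` | 0.05 | 0.20 | per-cycle period CV ("more stochastic" mutant oscillations) |
| `dv_frac_change` / `ap_frac_change` | 0.10 / 0.02 | 0.06 / 0.05 | per-cycle fractional length change; ratios 5 and 1.2 |

Recoil presets per boundary class store the baseline vertex distance
(`L0 = 5` µm), a shared viscoelastic time constant (`tau = 2` s, a typical
epithelial junction relaxation scale), and a maximal displacement `dLmax`
chosen so that the closed-form initial velocity
`dLmax (1 - e^{-0.8/tau}) / 0.8` equals the measured group velocity: 1.26
(mut-mut), 0.58 (ctrl-ctrl), 0.61 (ctrl-mut) and 0.38 µm/s
(protrusion-suppressed rescue). Morphometry stage means encode basal-area
growth of 1.7× (S8→S9) and 1.8× (S9→S10) for control and 1.5× / 1.3× for
mutant cells, with apical area, height and nuclear size genotype-invariant
(the null results).

### Scene rendering

Scenes are Voronoi mosaics of a jittered hexagonal lattice (realistic
tricellular junctions with minimal machinery); pixels far from every seed
form a cell-free rim used for background estimation. Rendering, at
0.2 µm/pixel with a constant detector offset of 20 a.u.:

* **Fibers** are vertical bundles with a Gaussian cross-section
  (σ = 0.2 µm, support truncated at ±0.4 µm), placed on integer pixel
  columns inside the cell interior (1.5 µm inside the boundary) with a
  minimum spacing of 1 µm. Grid alignment and compact support make
  rendered cross-sections non-overlapping and identical up to the preset
  intensity, so noiseless intensity ratios recover the preset fractions
  exactly.
* **The cortical ring** exploits the fact that Voronoi interfaces are seed
  bisectors: the ring is the set of pixels within 0.2 µm of the bisector,
  restricted to pixels whose two nearest seeds are the boundary's cell
  pair. This gives a constant Euclidean band width at every boundary
  orientation — a staircase-pixel band would be up to 30% thinner on
  diagonal boundaries and would bias orientation-dependent bar integrals.
  Mutant-mutant boundaries take the mutant cortical value; mixed and
  control boundaries the control value; apically all classes take the
  control value.
* **Whips** are polylines of 2-4 µm contour length anchored exactly at
  leading-edge tricellular junctions, heading over the basal surface of an
  adjacent cell and curling back when they reach 1.8 µm from their anchor,
  so the whole whip stays in the junctional neighbourhood. They are
  rendered in the F-actin channel only (whips carry no myosin).
* **Protrusion masks** (the structures measured with a membrane marker,
  not phalloidin) are stored as ground-truth pixel sets per cell and are
  not rendered into the actin channels.
* **Noise** is Poisson shot noise on the noiseless render plus additive
  Gaussian read noise (the standard confocal approximation);
  `noise_sd = 0` disables both, which is what "noiseless" means throughout
  the tests.

The generator does not model a point-spread function, 3-D stacks, or
tissue rotation; whips are static shapes, not beating flagella. Passing
recovery tests therefore demonstrates estimator correctness on idealised
imagery, not robustness to optical blur or motion artefacts.

### Traces and recoil

All oscillating channels share one phase process
(a sinusoid — the simplest waveform with a defined period, amplitude and
an exact spectral line — with optional per-cycle period jitter): myosin at
baseline + A·sin(φ), protrusion area phase-locked via the coupling phase,
basal area and both basal lengths in anti-phase (contraction on myosin
rise). Sharing the phase makes couplings exact by construction, so
correlation and anisotropy estimators have known truth. Frames arrive
every 30 s for up to one hour. Ablation traces carry a 10.4-s pre-cut
baseline and 15.2 s of recoil at 0.8-s frames, with noise scaled to
`dLmax`.

## Estimators

**Fiber scoring.** A cell's profile is sampled at pixel pitch along the
longest interior chord perpendicular to the dominant fiber orientation
(structure-tensor estimate; cortical rim of 1 µm eroded first). Samples
take the nearest pixel's value: interpolated sampling erodes on-grid peak
heights, which matters because the scoring threshold — one SD below the
mean raw peak height pooled over control cells — is sharp when the
control population is homogeneous. Peaks are strict-rise/non-strict-fall
local maxima (plateaus resolve to their leftmost sample), kept when their
height reaches the threshold, with a greedy 0.5-µm minimum separation
(sub-resolution doublets merge; fiber spacing exceeds this). Density is
peaks per micrometre of profile length, matching the published unit; the
alternative "peaks per cell area" reading of the written description
conflicts with that unit and was not used. Whole-cell and fiber-region
intensity ratios subtract the background (mean over cell-free pixels)
first; the fiber-region mask comes from ground truth with whip-overlaid
pixels excluded.

A consequence of the SD threshold worth stating: with the mutant fiber
intensity at 40% of control, every mutant peak falls below the control
reference, so noiseless mutant cells score zero peaks. The method measures
membership in the control intensity population; the recovered ordering
(mutant density below control) is the scientifically meaningful output.

**Cortical bars.** Each boundary is profiled with a 2-µm bar centred at
every boundary pixel along the local normal (gradient of a smoothed
indicator of one flanking cell — stable on pixelated boundaries), sampling
every 0.05 µm. Boundary pixels within 2 µm of a tricellular junction are
excluded (whips anchor there; bar samples on the boundary normal are then
provably at least 2 µm from any junction), as are pixels within 1.5 µm of
the tissue rim (the bar would leave the tissue). Per-boundary intensity is
the background-subtracted mean per sample — summing and averaging differ
only by a length weighting that cancels in class ratios — and class
summaries use a 15%-trimmed mean, since a single protrusion crossing can
inflate one boundary's bar severalfold. Pixel-level discretisation leaves
a 2-4% scatter on per-scene class ratios; recovery of the two-fold
mutant-mutant preset is tested at 5% with ≥20 pooled boundaries.

**Oscillations.** Preprocessing subtracts a cell-free background value,
clips at zero and smooths with a Gaussian of σ = 3 samples truncated at
3σ with reflect padding (the single smoothing scale stated with the
original analysis; at 30-s frames this is σ = 90 s). Cycle detection finds
alternating peaks and troughs with topographic prominence of at least 20%
of the signal range (a conventional default; the original peak criterion
is unstated and the threshold is exposed as a parameter). The period is
estimated two ways: the mean of adjacent-peak intervals, and the
reciprocal of the frequency of maximum power in the FFT magnitude of the
biased, lag-0-normalised autocorrelation (no window function; DC and
frequencies below 1/duration excluded to avoid trend leakage; off-bin
peaks resolve to the nearest bin, bounding the spectral error by half a
bin width). Amplitude is the mean per-cycle peak-minus-preceding-trough
difference, evaluated on the *raw* background-subtracted signal at extrema
located on the smoothed signal (`detect_cycles(refine=)`): σ = 3 smoothing
attenuates a 480-s sinusoid's amplitude roughly two-fold and would defeat
a max-minus-min statistic. Coupling is summarised by zero-lag Pearson
correlations, the lag of maximum cross-correlation, and the per-channel
period CV as the stochasticity summary.

**Ablation.** `L0` is the mean vertex distance over the 10 s immediately
before the cut (inclusive of the last pre-cut frame — the stated window is
directionally clear, the boundary convention is ours); the initial
velocity is the displacement at the first post-cut frame (0.8 s) divided
by 0.8 — a deliberately model-free estimator. Velocities are computed per
trace and then averaged (matching how group sizes are reported), not on
the averaged curve. Group comparisons use Welch's unequal-variance t-test
("t-test" alone was stated; Welch is the robust default and is labelled in
the output), with two zero-variance groups handled explicitly. Viscosity
is assumed equal across genotypes, so v0 is reported as a relative tension
proxy only.

**Morphometry.** Basal areas are planar label areas times the squared
calibration (no curvature correction — a known simplification relative to
3-D surface rendering). Growth ratios are ratios of stage means with a
percentile-bootstrap CI (200 replicates). Protrusion area is the union of
protrusion masks clipped to the cell, as a percentage of basal area. Whip
counting assigns ground-truth (or detected) whip objects to cells when
their anchor lies within 1 µm of one of the cell's leading-edge junctions;
"leading edge" is a declared scene attribute (west by default) because
tissue rotation is not simulated. The per-cycle fractional length change
underlying the D-V/A-P anisotropy is (max − min)/mean within each detected
cycle — the original change metric is not specified and this one is
scale-free.

## Numerical and degenerate-case conventions

Pixel indices are 1-based with row = y, column = x and pixel centres at
integer coordinates; every physical output is in micrometres via the
calibration. Fixed seeds give bit-identical outputs (the RNG kind is
pinned). Degenerate inputs fail loudly: cells too small to profile after
erosion, traces shorter than the smoothing kernel, missing pre-cut
windows, absent ctrl-ctrl baselines, and missing stage presets all raise
errors; empty peak sets, zero-whip scenes and empty morphometry tables are
valid results. A constant trace flags rather than errors in spectral code.
Infinite anisotropy (zero A-P change) warns and returns `Inf`.

## Problem sizes in the validation suite

The test suite and the acceptance script run the generators at the sizes
the analyses were designed around: 14-24 ablation traces per boundary
class, 16-cell mosaics (9 cells for whip-count scenes, 10 scenes per
condition), 20 trace bundles for anisotropy, 46 cells per
(stage × genotype) for morphometry, 50 seeded runs per period-recovery
condition, and 1000 random profiles for the peak-detection oracle. On one
CPU the whole suite completes in a few minutes.

## Known limitations

Rendered whips are stubs confined near junctions rather than full-length
beating flagella, a deliberate trade-off that keeps the cortical bar and
fiber-region measurements well-posed on 2-D stills. The SD-threshold fiber
score is reference-population-bound (see above). Cortical class ratios
inherit a few percent of pixelation scatter per scene. The oscillation
spectral estimate is bin-quantised; interval-based estimates are the finer
instrument off-bin. None of the estimators have been tuned for, or tested
against, real microscope data in this package.
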