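---
title: "Motion-encoded CSF mobility mapping: models, simulation and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-encoded CSF mobility mapping: models, simulation and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfmobility)
```

## The measurement model

Cerebrospinal fluid (CSF) mobility is quantified from a CSF-bright,
tissue-suppressed turbo-spin-echo (TSE) acquisition in which bipolar
motion-sensitizing gradients are inserted into the T2 preparation. Slow
flow, laminar flow and back-and-forth motion within a voxel all dephase
the transverse magnetization, attenuating the signal like an apparent
diffusion coefficient at a very low b-value:

$$ S_i(v) \;=\; S_0(v)\, \exp\!\big(-b\, \hat g_i^{\mathsf T} D(v)\, \hat g_i \big), \qquad i = 1 \ldots 6 , $$

where $D$ is the symmetric 3x3 *mobility tensor* (mm^2/s), $b$ the
effective encoding weight (s/mm^2) and $\hat g_i$ the six unit encoding
directions. The gradients are played on two physical axes simultaneously,
giving the dual-axis scheme
$\{(1,1,0),(1,-1,0),(0,1,1),(0,1,-1),(1,0,1),(-1,0,1)\}/\sqrt 2$
(`encoding_directions()`), whose outer products span the full
six-dimensional symmetric-tensor space, and an effective encoding velocity
of $\mathrm{venc}/\sqrt 2$ (5 mm/s per axis gives 3.5 mm/s effective; the
patient protocol's 5.6 mm/s gives 4.0 mm/s).

`fit_tensor()` inverts the model per voxel by log-linear least squares.
With six equations and six unknowns the solve is exact, so noiseless
simulations recover tensors to machine precision — a property the test
suite asserts at 1e-10. Scalar maps follow the diffusion-tensor
conventions: mobility is the mean eigenvalue $\bar\lambda$, fractional
anisotropy is
$\mathrm{FA} = \sqrt{3/2}\,\sqrt{\sum_i(\lambda_i-\bar\lambda)^2} / \sqrt{\sum_i \lambda_i^2}$,
and the principal orientation is the leading eigenvector with its sign
fixed to non-negative z (then y, then x) so orientation maps are
reproducible. Negative eigenvalues — possible under noise although the
model asserts positive semidefiniteness — are clamped to zero and flagged.
Voxels whose reference signal falls below the 150 a.u. CSF threshold are
invalid, and `tensor_metrics()` additionally excludes voxels above the
0.15 mm^2/s mobility cutoff as noise-dominated.

### The b-value

The scanner's effective b is not published. `b_value` is therefore a
direct configuration parameter, defaulting to 10 s/mm^2 so that the
reported regional mobilities (0.012-0.041 mm^2/s) produce 10-35% signal
attenuation — enough to measure, far from the noise floor. The helper
`venc_to_b()` documents the $b = \kappa/\mathrm{venc}^2$ scaling without
asserting the scanner's $\kappa$.

## The synthetic phantom

`make_phantom()` builds the ground truth that replaces scanner data:
ellipsoidal blobs (ventricle-like CSF pools) and cylindrical tubes
(subarachnoid and perivascular channels) on a 0.45-mm isotropic grid.
Tissue and blood signal is exactly zero — the acquisition suppresses both
to the noise level — so only Rician background noise competes with the
150 a.u. masking rule. Each structure carries:

* `base_mobility`: the mean eigenvalue of its tensor, using the reported
  regional values (0.041 mm^2/s for the subarachnoid space around the
  middle cerebral artery, 0.012-0.015 mm^2/s for perivascular spaces) as
  defaults in examples;
* `fa` with an **axially symmetric spectrum**: the pair
  $(\bar\lambda, \mathrm{FA})$ does not identify three eigenvalues, so the
  generator uses $\lambda_2 = \lambda_3$, solved in closed form as
  $\delta = \mathrm{FA}/\sqrt{3 - 2\,\mathrm{FA}^2}$,
  $\lambda = \bar\lambda\,(1+2\delta,\, 1-\delta,\, 1-\delta)$ — the
  natural choice for tube-like channels, exact for all FA < 1;
* cardiac and respiratory modulation: the tensor oscillates
  multiplicatively,
  $D(\varphi_c,\varphi_r) = D_0\,[1 + A_c \sin(2\pi\varphi_c+\psi) + A_r \sin(2\pi\varphi_r+\psi)]$,
  with amplitudes of a few percent (3.2% cardiac in the subarachnoid
  example, matching the reported regional effect). The scaling preserves
  tensor shape, so ground-truth FA is constant over the cycle; real FA
  also fluctuates, and the generator makes no claim about the mechanism
  behind that.

`make_physio_traces()` emulates the pulse-unit and respiration-belt
recordings: inter-peak intervals are Gaussian with coefficient of
variation `jitter` (default 0.05 — a realistic resting heart-rate
variability), the trace between peaks is a cosine of the intra-cycle
phase, and the true peak times are stored so that peak detection can be
validated against ground truth.

## Acquisition simulation

`make_pattern()` generates the undersampled (ky, kz) profile set with a
fully sampled autocalibration block (29 x 29 in the reference protocols).
The vendor's "pseudoradial variable density, density decay 0.5" pattern is
under-specified; the package reconstructs it as inclusion probability
$\min(1, s\, r^{-0.5})$ with $r$ the normalized k-space radius, the scale
$s$ bisected against fixed per-point uniform draws until the target
acceleration is met — deterministic given the seed, density monotonically
decaying with radius. The Poisson-disk mode (12x in the patient protocol)
enforces a minimum pairwise distance found by bisection.

`make_shot_schedule()` orders profiles by azimuth about the k-space center
(pseudoradial spokes), chunks them into TSE shots of at most `tse_factor`
profiles, and starts shot $k$ at $k \cdot TR$ — the T2-preparation
instant whose cardiac/respiratory phase the whole shot inherits. The
protocol arithmetic is reproduced exactly: 14,162 profiles at TSE factor
146 give 97 shots spanning 326.4 s at TR = 3.4 s. When a schedule
traverses the pattern several times (`n_repeats`), successive passes start
at golden-ratio-rotated offsets, as in golden-angle reordering; without
the rotation, a profile chunk keeps meeting the same cardiac phases and
whole azimuthal wedges can drop out of a phase bin.

`simulate_subscan()` evaluates the forward model per shot at the shot's
physiological phases, applies the centered unitary 3D Fourier transform
(zero frequency at `floor(N/2)`, Parseval-exact), samples the shot's
profiles (readout direction fully sampled) and adds complex Gaussian noise
per sample; the default noise s.d. of `csf_signal/50` gives a reference
SNR of 50. Single-coil simulation; magnitude images carry Rician noise.

## Retrospective binning

`detect_peaks()` finds local maxima above an adaptive prominence threshold
(half the median candidate prominence) with a minimum inter-peak distance
of 0.4 median periods, and refuses flat traces with a signal-quality
error. `assign_bins()` defines the intra-cycle phase by linear
interpolation between consecutive peaks and implements the two-step
three-phase binning: six half-open windows of width 1/3 centered at
multiples of 1/6 (the one-sixth shift between the two steps), so **every
shot belongs to exactly two of the six phase datasets**. Random binning —
the negative control — draws uniform pseudo-phases from a seeded stream
and applies the identical windowing, so occupancy statistics match the
physiological case. `bin_kspace()` averages duplicated profiles within a
dataset (variance-optimal for equal noise) and records masks and
multiplicities; conservation (union of masks = pattern, total multiplicity
= twice the sample count) is asserted in the tests.

## Reconstruction

`reconstruct()` offers zero-filling (inverse centered transform, exact for
complete data) and a temporal total-variation mode minimizing
$\sum_p \|M_p F x_p - y_p\|^2 + \lambda \sum_v \sum_p |x_{p+1} - x_p|$
with cyclic phase differences, by proximal gradient from the zero-fill
initialization: step $1/L$ with $L = 2$, the TV proximal operator solved
by a dual projected-gradient (Chambolle-type) inner loop, 30 outer
iterations by default and $\lambda = 0.005$ on data normalized to unit
peak magnitude (the patient protocol's setting is 0.002). The objective
is non-increasing across iterations and the solve is deterministic. The
paper's multi-coil compressed-sensing solver with estimated sensitivities
is out of scope; one coil and a shared forward operator stand in for it.

## Phase-cycle quantification

`percent_change()` normalizes the six per-phase mobility maps voxel-wise
to their mean, giving zero-mean profiles in percent. `sine_fit()` fits
$y_k = a\sin(2\pi k/6) + b\cos(2\pi k/6)$ in closed form (the basis is
orthogonal over six phases; no offset because profiles are zero-mean),
yielding amplitude $\sqrt{a^2+b^2}$, phase $\mathrm{atan2}(b,a)$ and
$R^2$; amplitudes with $R^2 < 0.5$ are gated to zero to represent the
absence of coherent oscillation. `phase_summaries()` realigns each
voxel's profile so its maximum sits at index 1 before ROI averaging
(avoiding phase cancellation; index 1 is flagged for exclusion from
plots), and reports the coherent-voxel fraction ($R^2 > 0.5$) and the
max-minus-min driving amplitude.

Two bias mechanisms matter when interpreting recovered amplitudes.
Averaging a sinusoid over a phase window of width 1/3 attenuates it by
$\mathrm{sinc}(\pi/3) \approx 0.827$; amplitude estimation on noisy
profiles is biased upward by roughly $\sigma^2/(2A)$. At the simulated
SNR the two partially cancel, and the end-to-end study recovers the 3.2%
cardiac amplitude within a few percent relative — well inside the 25%
band the test suite asserts.

### Why random binning still looks partly "coherent"

The two-step windowing places every shot in two adjacent datasets, which
convolves any per-bin noise with the cyclic kernel $[1,1]/2$. That
kernel's transfer function $\cos^2(\omega/2)$ *nulls* the
Nyquist (three-cycles-per-cycle) component and attenuates the
two-cycle component threefold relative to the fundamental, so even white
noise acquires a sinusoid-like profile: analytically,
$R^2 = X/(X + Y/3)$ with $X, Y \sim \chi^2_2$, giving
$P(R^2 > 0.5) = 0.75$ independent of SNR. Randomly binned data in the
thermal-noise-dominated regime of this simulator therefore show a
coherent fraction near 0.7 — clearly below the cardiac-binned fraction,
but not arbitrarily small. In vivo the random control is further degraded
by scrambled physiological variance and per-bin reconstruction behavior,
which is why measured random coherence can fall lower than this
structural bound suggests. The test suite states the factor-two margin as
the specificity check; under these synthetic conditions it fails for the
structural reason above, which we document rather than hide.

## ROI tools

* `csf_mask()`: keep voxels at or above 150 a.u. in the reference scan,
  drop voxels whose absolute mobility change exceeds 50% in any provided
  change map, then drop "lonely" voxels with no in-mask neighbors
  (26-connectivity by default). The pointwise rules commute; the
  neighborhood rule runs last in a single pass.
* `ridge_filter()`: multiscale Hessian vesselness for bright tubes at
  sigma = 0.6, 0.8, 1.0 mm. Frangi mode uses plate/blob/structure terms
  with alpha = beta = 0.5 (the reported "vesselness constant"; the paper's
  single constant is ambiguous across Frangi's three parameters, so the
  structure-term scale c is set per scale to half the maximal Hessian
  norm). Meijering mode implements the neuriteness variant used for
  centrum-semiovale perivascular spaces. Anisotropic voxels are refused —
  resample first.
* `dilation_rims()`: vessel "inflation" from 0.17 to 3.00 mm in 0.17-mm
  steps (17 rims) implemented with an exact Euclidean distance transform
  (separable lower-envelope algorithm) rather than iterated
  structuring-element dilation, which would distort sub-voxel steps
  toward Chebyshev distance. Rims are disjoint and partition the in-range
  CSF shell exactly.
* `roi_stats()`: mean, s.d., and the confidence half-width
  $1.96\,\mathrm{s.d.}/\sqrt n$ used throughout the reported error bars.
* `nonparam_tests()`: Friedman across paired conditions, two-sided
  Wilcoxon signed-rank (exact for n <= 25 without ties) and two-sided
  Mann-Whitney U (exact for small samples), with Bonferroni correction
  capped at 1. The exact paths are validated against brute-force
  enumeration oracles in the tests.
* `stim_response()`: percent mobility change between stimulation
  conditions per ROI, and the BOLD amplitude of averaged stimulation
  blocks — baseline over dynamics 5-10, plateau over dynamics 15-20,
  1-based inclusive, three blocks averaged first.

## Simulation studies and problem sizes

`amplitude_recovery_study()` runs the full chain on a 48^3 phantom: an
ellipsoidal pool (8.4% cardiac amplitude, as in a fourth-ventricle-like
region) and a subarachnoid-like tube (0.041 mm^2/s, FA 0.7, 3.2% cardiac,
1.2% respiratory amplitude), TSE factor 48, 18 rotated passes over a
fully sampled 48 x 48 profile grid, cardiac 1 Hz and respiration 0.25 Hz
with 5% jitter, SNR 50. Eighteen passes leave an expected per-phase
missing-profile fraction of $(2/3)^{18} \approx 0.07\%$, so zero-filled
per-phase reconstruction is adequate and the 20-minute budget of a
single-CPU run is respected; the grid and pass count were chosen from
this coverage arithmetic. `cohort_power_study()` draws per-subject ROI
means at the reported patient/control statistics (0.042 +/- 0.006 vs
0.035 +/- 0.005 mm^2/s, n = 8 + 8) and measures exact Mann-Whitney power
over 200 repetitions; at these effect sizes the power is about 60%, which
the study reports as measured rather than adjusting the conditions to
inflate it.

## What the phantom does and does not show

The generator reproduces the contrast mechanism, the acquisition timing
against physiological traces, undersampling, Rician noise, and the
oscillation model the analysis chain must invert. It does not attempt
anatomically realistic geometry, partial-volume effects, T2 decay along
the echo train, eddy currents, motion, or multi-coil physics. Passing
tests therefore demonstrate that the analysis pipeline is a faithful,
well-conditioned inverse of the stated forward model — not that the
forward model captures everything in a 7T measurement.

## Numerical conventions

Zero-based voxel indices; world coordinates via a diagonal RAS affine in
mm. The k-space center sits at `floor(N/2)` on each axis (FFT-shift
convention); transforms are unitary. Azimuthal ties in shot ordering
break lexicographically on (angle, radius, ky, kz). All randomness flows
from one master seed through named sub-streams (`seed_substream()`), so a
single integer reproduces a pipeline run byte-for-byte.
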