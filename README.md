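# csfmobility

Simulation and analysis of motion-encoded MRI measurements of
cerebrospinal fluid (CSF) mobility.

CSF moves — with the heartbeat, with breathing, with slow vasomotion —
and that movement is thought to drive waste clearance through
perivascular spaces. A CSF-selective, tissue-suppressed turbo-spin-echo
acquisition with motion-sensitizing gradients measures this as an
apparent-diffusion-style coefficient: for encoding direction
`g_i` the signal obeys

    S_i = S_0 * exp(-b * g_i' D g_i),   i = 1..6,

where `D` is the per-voxel symmetric *mobility tensor* (mm²/s). Six
dual-axis encoding directions identify `D` exactly; its mean eigenvalue
is the CSF mobility, its fractional anisotropy (FA) and principal
eigenvector describe how directed the motion is. Retrospectively binning
the acquired k-space shots into six cardiac (or respiratory, or random)
phases, reconstructing each phase and fitting a single-cycle sinusoid to
the per-voxel percent-change profile quantifies how strongly each
physiological force drives the CSF, with an R² ≥ 0.5 gate defining
"coherent" voxels.

This package implements that entire computational chain, together with a
synthetic phantom generator that stands in for 7T scanner data:

* `phantom_spec()` / `make_phantom()` / `make_physio_traces()` —
  CSF-bright phantoms with ground-truth anisotropic tensors, sinusoidal
  cardiac/respiratory modulation, and quasi-periodic physiological traces;
* `make_pattern()` / `make_shot_schedule()` / `simulate_acquisition()` —
  pseudoradial variable-density or Poisson-disk undersampling with a
  fully sampled autocalibration block, TSE shot timing, and the forward
  k-space simulation of the seven subscans with complex Gaussian noise;
* `detect_peaks()` / `assign_bins()` / `bin_kspace()` — physiological
  peak detection and the two-step three-phase binning (one-sixth shift,
  every shot in exactly two of six datasets);
* `reconstruct()` — zero-filled or temporal total-variation regularized
  reconstruction (proximal gradient, 30 iterations, λ = 0.005);
* `fit_tensor()` / `tensor_metrics()` — per-voxel tensor fits with
  mobility, FA, orientation maps, validity masking and the 0.15 mm²/s
  cutoff;
* `percent_change()` / `sine_fit()` / `phase_summaries()` — phase-cycle
  profiles, closed-form sinusoid fits with R² gating, realigned ROI
  averages, coherent fractions and driving amplitudes;
* `csf_mask()`, `ridge_filter()`, `dilation_rims()`, `roi_stats()`,
  `nonparam_tests()`, `stim_response()` — the 150 a.u. masking rules,
  Frangi/Meijering vesselness, 0.17→3.00 mm vessel rims via an exact
  Euclidean distance transform, nonparametric group tests and
  visual-stimulation metrics;
* `run_pipeline()` and a thin CLI (`inst/cli/csfpipe.R`) wiring the
  stages together with one master seed and a JSON report.

## Worked example

Fit a tensor from a noiseless simulated acquisition and read off the
maps:

```r
library(csfmobility)

spec <- phantom_spec(
  grid_shape = c(24, 24, 24), voxel_size = 0.45,
  structures = list(
    csf_structure("tube", p1 = c(5, 5, 2), p2 = c(5, 5, 8.5), radius = 1.2,
                  base_mobility = 0.041, fa = 0.7)),
  noise_sd = 0)
truth  <- make_phantom(spec)
cfg    <- acquisition_config(grid = c(24, 24), acs_size = 9,
                             accel_target = 1, tse_factor = 64, noise_sd = 0)
pat    <- make_pattern(cfg)
sched  <- make_shot_schedule(pat, cfg)
traces <- make_physio_traces(7 * length(sched$shots) * cfg$TR + 10)
enc    <- simulate_acquisition(truth, traces, pat, cfg)

vols <- array(0, c(24, 24, 24, 7))
for (s in 1:7) vols[, , , s] <- reconstruct_static(enc$subscans[[s]])
fit <- fit_tensor(vols, b = cfg$b_value)
fit
#> CSF mobility tensor field: 24 x 24 x 24 voxels, 386 valid (b = 10 s/mm^2)
#>   mobility 0.0410 +/- 0.0000 mm^2/s, FA 0.700 +/- 0.000, 0 clamped
```

The fitted mobility (0.041 mm²/s) and FA (0.700) equal the configured
ground truth to machine precision: with six directions the log-linear
system is exact, and the full simulate–reconstruct–fit chain is an
identity for noiseless, fully sampled data.

The oscillation chain is exercised by the built-in study:

```r
res <- amplitude_recovery_study(seed = 1)
res$recovered_p2t_pct   # ~6.3  : peak-to-trough % change recovered in the tube ROI
res$predicted_p2t_pct   # 6.4   : 2 x the configured 3.2% cardiac amplitude
res$cardiac$coherent_fraction  # ~0.87
res$random$coherent_fraction   # ~0.68 (see the methods vignette for why
                               # random binning retains substantial
                               # apparent coherence)
```

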