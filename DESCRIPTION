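Package: csfmobility
Title: Motion-Encoded CSF Mobility Tensor Mapping with Retrospective
    Physiological Binning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of motion-encoded MRI measurements of
    cerebrospinal fluid (CSF) mobility. Generates synthetic CSF phantoms
    with anisotropic ground-truth mobility tensors and cardiac/respiratory
    modulation, simulates undersampled turbo-spin-echo k-space acquisition
    of seven motion-encoded subscans, performs retrospective two-step
    physiological phase binning of k-space, reconstructs per-phase volumes
    (zero-filled or temporal total-variation regularized), fits per-voxel
    mobility tensors with mean-mobility, fractional-anisotropy and
    principal-orientation maps, quantifies phase-cycle oscillations by
    voxel-wise sinusoid fitting with R-squared gating, and provides ROI
    tools (CSF masking rules, multiscale ridge filters, vessel dilation
    rims, nonparametric group tests, stimulation-response metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
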