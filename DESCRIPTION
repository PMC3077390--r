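Package: alongtract
Title: Along-Tract Statistics for Diffusion Tensor MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tractometry pipeline for diffusion tensor imaging: per-voxel
    log-linear tensor fitting with fractional anisotropy, radial and axial
    diffusivity maps; deterministic FACT streamline tractography with
    multi-ROI bundle extraction; 30-point arc-length mean-curve profiles;
    and pointwise group statistics with covariates, Bonferroni control and
    clinical partial correlations. Includes a synthetic diffusion-phantom
    generator (curved anisotropic tubes, Rician noise, two-group cohorts
    with localized effects) so the full pipeline is testable against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
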