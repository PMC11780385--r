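Package: gistct
Title: CT-Based Response Monitoring for Neoadjuvant-Treated GIST
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring radiological response of gastrointestinal
    stromal tumours (GIST) to neoadjuvant tyrosine kinase inhibitor therapy
    from contrast-enhanced CT. Reads CT volumes and 3D lesion segmentations
    (NIfTI), extracts per-scan lesion metrics (volume, longest transaxial
    diameter, mean density in Hounsfield units), classifies
    baseline-to-follow-up change under RECIST 1.1, Choi and volumetric
    criteria, evaluates diagnostic performance against surgical-benefit
    labels (including marginal-constrained reconstruction of 2x2 confusion
    tables from published counts), computes interobserver agreement (Dice,
    Cohen's kappa, intraclass correlation), and summarises longitudinal
    shrinkage trajectories. A synthetic cohort generator produces voxelized
    lesions with plateauing exponential volume decay, density decline,
    anisotropic shrinkage and observer-perturbed duplicate masks so the whole
    pipeline can be exercised without clinical data.
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
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
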