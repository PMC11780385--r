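# gistct

CT-based response monitoring for neoadjuvant-treated gastrointestinal
stromal tumours (GIST).

Localised GISTs are often treated with tyrosine kinase inhibitors before
surgery; radiologists and surgeons then have to decide, from consecutive
contrast-enhanced CT scans, whether the tumour's response will actually
make the operation smaller or simpler. `gistct` is an R toolkit for that
analysis chain, aimed at imaging researchers who have 3D lesion
segmentations (NIfTI) and surgical-benefit adjudications and want a
tested, reproducible pipeline from voxels to diagnostic-performance
tables.

## What it computes

* **Lesion metrics** from a binary VOI on its native grid: volume
  (voxel count x voxel volume), longest transaxial diameter (maximum
  voxel-centre distance within an axial slice, maximised over slices),
  mean density in HU, and Dice overlap between observers' masks.
* **Response classification** between baseline and a reference scan,
  with inclusive thresholds on percentage change from baseline:
  * RECIST 1.1: PR at diameter change ≤ −30 %, PD at ≥ +20 %, CR on
    disappearance, SD otherwise;
  * volumetric: PR ≤ −66 %, PD ≥ +73 % — the RECIST thresholds mapped
    through isotropic (spherical) scaling, (1+d)³−1;
  * Choi: PR at diameter ≤ −10 % or density ≤ −15 %; PD at diameter
    ≥ +10 % with less than 15 % density reduction.
* **Diagnostic evaluation** of binarized response (CR/PR) against
  surgical-benefit labels: accuracy, sensitivity (benefit detection) and
  specificity, plus exhaustive reconstruction of 2x2 confusion tables
  from published marginal counts and whole-percent metrics
  (`reconstruct_table()`).
* **Agreement statistics**: Cohen's kappa, ICC(2,1) (two-way random,
  absolute agreement), exact Mann-Whitney and Fisher tests.
* **Shrinkage trajectories**: baseline-referenced change series,
  time-to-threshold, post-response stagnation, group medians with a
  Mann-Whitney comparison, and early prediction of benefit from the
  first interim scan.
* **Synthetic cohorts**: voxelized ellipsoidal lesions following a
  plateauing exponential volume decay
  v(t) = v0 (p + (1−p) e^(−t/τ)), with density decline, anisotropic
  shrinkage, observer-perturbed duplicate masks and benefit labels —
  the whole pipeline runs without any clinical data.

See `vignette("response-monitoring")` for the models, conventions and
design decisions.

## Worked example

An anisotropically shrinking lesion — the case where diameter-based and
volume-based criteria disagree:

```r
library(gistct)

g <- image_grid(c(96, 96, 96), spacing = c(1, 1, 1))
baseline <- render_lesion(9e4, g, axis_ratios = c(1, 1, 1.3), density_hu = 72)
follow   <- render_lesion(9e4 * 0.18, g,
                          axis_ratios = c(1, 1, 1.3) * 0.18^c(0, 0, 1),
                          density_hu = 48)

b <- observe_lesion(baseline$mask, baseline$ct, month = 0)
f <- observe_lesion(follow$mask, follow$ct, month = 6.7)
percent_change(b$volume_mm3, f$volume_mm3)    # -81.9
percent_change(b$diameter_mm, f$diameter_mm)  # -0.5
recist_classify(b, f)      # SD
volumetric_classify(b, f)  # PR
choi_classify(b, f)        # PR
```

The tumour lost 82 % of its volume entirely along the scanner's long
axis, so its transaxial diameter barely moved: RECIST calls it stable
disease while the volumetric and Choi criteria call it a partial
response. This is exactly the discordance pattern that motivates
volumetry for neoadjuvant GIST monitoring.

Reconstructing a published performance triple from marginals alone —
22 of 39 patients with surgical benefit, 18 RECIST responders, and a
printed 100 % metric (which forces an empty error cell):

```r
tabs <- reconstruct_table(c(22, 17), c(18, 21),
                          list(list(cell = "fp", value = 0)))
tabs[[1]]
#>               benefit no benefit
#> responder          18          0
#> non-responder       4         17
unlist(performance(tabs[[1]])[1:3])
#>    accuracy sensitivity specificity
#>          90          82         100
```

The unique consistent table gives 90 % accuracy; 82 % of benefit
patients were responders and every non-benefit patient was correctly
ruled out (the published labelling of the last two numbers is
transposed relative to the benefit-detection convention, so
`performance()` reports both orientations).

End-to-end on synthetic data:

```r
spec <- cohort_spec(seed = 4)                 # 19 benefit / 11 non-benefit
run_simulate(spec, "sim")                     # NIfTI scans + manifest.csv
run_assess("sim/manifest.csv", "sim/reports") # metrics, classifications,
                                              # performance, agreement,
                                              # trajectory summaries
```

A thin CLI over the same functions is installed at
`inst/cli/gistct.R` (`simulate` and `assess` subcommands).

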