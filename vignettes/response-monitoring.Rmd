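---
title: "CT-based response monitoring for neoadjuvant GIST: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CT-based response monitoring for neoadjuvant GIST: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gistct)
```

## The problem this package addresses

Patients with localised gastrointestinal stromal tumours (GIST) are often
given neoadjuvant tyrosine kinase inhibitors (TKI) before surgery, in the
hope that a smaller, better-demarcated tumour allows a less extensive and
less complex resection. Whether that surgical benefit materialises is
adjudicated by surgeons; whether it can be *anticipated* from routine
contrast-enhanced CT is a question about radiological response criteria.
`gistct` implements the full measurement-and-evaluation chain for that
question:

1. per-scan lesion metrics from a 3D segmentation (volume, longest
   transaxial diameter, mean attenuation in Hounsfield units),
2. response classification under RECIST 1.1, Choi, and volumetric
   criteria,
3. diagnostic evaluation of binarized response against surgical-benefit
   labels, including exact reconstruction of 2x2 tables from published
   marginal counts,
4. interobserver agreement (Dice, Cohen's kappa, ICC),
5. longitudinal shrinkage-trajectory summaries and early prediction, and
6. a synthetic voxelized-cohort generator so that all of the above is
   testable without clinical data.

## Lesion metrics and their conventions

A segmentation is a binary volume of interest (VOI) on a voxel grid with
known per-axis spacing in mm and an identified inferior-superior axis
(read from the NIfTI orientation header; axis 3 with a warning when no
orientation is stored).

* **Volume** is the tumour voxel count times the physical voxel volume.
* **Longest transaxial diameter** is measured strictly in-plane, per the
  RECIST recommendation to measure in the axial plane: within each
  transaxial slice the maximum Euclidean distance between tumour voxel
  *centres* (in-plane spacing applied), maximised over slices. There is
  no half-voxel edge correction: a single voxel has diameter 0, and a
  measured diameter can under-read a continuous object's extent by up to
  one in-plane voxel. The convention is unambiguous, is checked against a
  brute-force all-pairs oracle in the tests, and cancels out of
  percentage changes because baseline and follow-up are measured
  identically. Internally large slices are reduced to their convex hull
  before the pairwise search; the result is identical to the brute-force
  scan.
* **Mean density** is the plain arithmetic mean of the CT values over all
  VOI voxels — no HU trimming and no boundary erosion, since the
  criteria this package implements state no exclusion rule.
* **Dice similarity** between two masks of the same scan is
  $2|A\cap B| / (|A|+|B|)$, defined as 1 when both masks are empty
  (agreement on absence).

Measurements are made on the native grid of each scan; no resampling is
performed, and grids are only required to match between a CT volume and
its own mask (1e-3 mm spacing tolerance, which absorbs I/O round-trip
noise without hiding genuine mismatches).

## Response criteria

All changes are percentage changes from *baseline* — the analysis this
package supports compares the baseline scan with a chosen reference scan
(by default the last preoperative one), and trajectory plots are
baseline-referenced. Nadir-referenced progression and new-lesion rules
are deliberately out of scope: the intended cohort is single-lesion,
non-metastatic disease. All threshold comparisons are inclusive.

| Criterion  | CR | PR | PD | SD |
|------------|----|----|----|----|
| RECIST 1.1 | disappearance | diameter $\le -30\,\%$ | diameter $\ge +20\,\%$ | otherwise |
| Volumetric | disappearance | volume $\le -66\,\%$ | volume $\ge +73\,\%$ | otherwise |
| Choi       | disappearance | diameter $\le -10\,\%$ **or** density $\le -15\,\%$ | diameter $\ge +10\,\%$ **and** density $> -15\,\%$ | otherwise |

The volumetric thresholds are the RECIST diameter thresholds pushed
through isotropic (spherical) scaling, $(1+d)^3-1$: $-30\,\%$ diameter
becomes $-65.7\,\%$ volume and $+20\,\%$ becomes $+72.8\,\%$, i.e.
$-66\,\%/+73\,\%$ at whole-percent rounding. `volume_threshold_from_diameter()`
exposes the unrounded relation; classification uses the whole-percent
thresholds, which are the operational rule as published. Because of this
construction, RECIST and volumetric classifications agree whenever
shrinkage is isotropic (a property test verifies this away from the
rounding boundaries); they diverge exactly when shrinkage is anisotropic,
which is the clinically interesting case.

For Choi, PR is evaluated before PD. The PD clause's density condition
("less than 15 % density reduction") is therefore honoured literally: a
density responder whose diameter grows is PR, not PD. Choi's original
intratumoral-nodule progression clause is not implemented.

Rounding, where values are *reported*, is half away from zero to whole
percent. No rounding ever occurs inside classification.

## Diagnostic evaluation and table reconstruction

Response is binarized as CR or PR; the reference standard is the binary
surgical-benefit label. From the 2x2 table, sensitivity is defined here
as the proportion of *benefit* patients detected by the criterion,
specificity as the proportion of non-benefit patients correctly ruled
out. Published triples in this area are sometimes labelled in the
transposed orientation, so `performance()` returns both readings and the
JSON reports carry an orientation note rather than silently picking one.

`reconstruct_table()` addresses a reproducibility task: given only the
published marginals (how many patients benefited; how many were
responders) and the published whole-percent metrics, enumerate every
integer table consistent with the marginals and keep those matching the
constraints. Two useful facts follow directly from the arithmetic:

* any printed 100 % metric forces a zero error cell, which with these
  marginals pins the table uniquely;
* one printed companion metric can pin the table even when the other
  printed value is arithmetically impossible for *every* integer table
  on the marginals (no table on marginals (22,17) x (34,5) yields 96 %,
  since 21/22 rounds to 95; the printed 24 % alone, or equivalently the
  printed 64 % accuracy, selects (21,13,1,4)). The package reports what
  the unique table implies and leaves the discrepancy visible instead of
  absorbing it.

## Agreement statistics

* **Cohen's kappa** uses marginal-product expected agreement,
  $(p_o-p_e)/(1-p_e)$.
* **ICC** is the two-way random-effects, absolute-agreement, single-rater
  form, ICC(2,1), computed from the mean-squares decomposition
  $(MS_R - MS_E)\,/\,(MS_R + (k-1)MS_E + k(MS_C-MS_E)/n)$. The
  absolute-agreement form was chosen because systematic offsets between
  observers should count against reliability of a measurement that feeds
  thresholded criteria; the tests verify it against `aov()` mean squares
  to 1e-10.
* **Mann-Whitney U** returns an exact two-sided p by full enumeration of
  rank assignments when the pooled sample size is at most 12 (valid under
  ties), and a tie-corrected normal approximation with continuity
  correction otherwise. **Fisher's exact test** uses the two-sided
  point-probability method (sum of hypergeometric probabilities no larger
  than the observed table's). Both are cross-checked against independent
  routes (`wilcox.test`, `fisher.test`) in the tests.

## Trajectory analysis

`change_series()` yields baseline-referenced percentage changes per scan;
`time_to_threshold()` takes the first scan at or below a threshold, with
no interpolation between scans. The "first interim" scan is the first
scan after baseline that is not the final preoperative scan; patients
imaged only at baseline and preoperatively are excluded from trajectory
analyses. Quantiles use linear interpolation (R type 7); published work
rarely states its quantile convention, and the choice only shifts IQR
endpoints by fractions of a percentage point at these group sizes.

`stagnation_summary()` quantifies how little further shrinkage occurs
after an early response: for patients already at or below the threshold
at the first interim scan, the volume change from the first interim scan
to the next one, expressed by default as a percentage of the
*first-interim* volume. That denominator matches the clinical reading
("the already-shrunken tumour barely changed"); a `reference = "baseline"`
switch provides the alternative, since either reading is defensible.

`early_prediction()` classifies baseline against the first interim scan
and cross-tabulates against benefit — the "could we have known at three
months" question.

## The synthetic cohort generator

The generator exists so the entire pipeline can run, and be tested,
without any clinical data. It emulates the statistical structure the
analysis assumes, not CT realism.

**Volume model.** Remaining volume follows a plateauing exponential,
$v(t) = v_0\,(p + (1-p)\,e^{-t/\tau})$ — the minimal form consistent
with the fast-then-stagnant shrinkage pattern seen under effective TKI
therapy. It is generator-only; nothing in the analysis fits it.

**Parametrisation by what the scans show.** Rather than drawing the
asymptote $p$ and time constant $\tau$ directly, each patient's curve is
pinned through two drawn controls: the remaining fraction at the first
interim scan and at the final scan, from which $(p, \tau)$ are solved
(`uniroot` on the two model equations, with $\tau$ bounded so $p$ stays
positive). This makes cohort construction exact: benefit patients' final
reductions land inside the configured 66-85 % band (volumetric PR by
construction), non-benefit patients inside 10-45 % (SD), and exactly the
configured number of early crossers are at or below $-66\,\%$ at the
first interim scan. Drawing the asymptote itself would let the residual
exponential term leak final reductions across the 66 % boundary and make
those guarantees false.

**Defaults** encode the study conditions this package targets: 19
benefit / 11 non-benefit patients with interim imaging, 14 early
crossers; first interim scans at 2.6-3.5 months (benefit) and 2.0-2.8
months (non-benefit), a second interim at 6.0-7.2 months and the
preoperative scan at 8.5-9.5 months; baseline volumes log-uniform over
50-2000 mL (roughly 5-16 cm tumours); baseline densities 40-80 HU with
density responders (probability 0.95 in the benefit group, 0.5 outside
it) losing 20-45 % of baseline attenuation. Early crossers sit only a
small relative gap (1.5-8 %) above their final fraction at the first
interim scan, so the stagnation-phase residual shrinkage comes out at a
few percent with an IQR spanning roughly 2-8 %. Shrinkage is isotropic
by default (`anisotropy = c(1,1,1)/3`); concentrating the exponents on
the axial axis reproduces the volume/diameter discordance in which a
tumour loses 80 %+ of its volume while its transaxial diameter is
unchanged or even grows.

**Voxel realisation.** `render_lesion()` realises any requested volume
as an ellipsoid by the voxel-centre-inside test, with semi-axes scaled
so the analytic volume matches the request; at 1 mm isotropic spacing or
finer the voxelized volume agrees within about 3 % and the measured
diameter within one in-plane voxel. Rendering spacing is chosen per
patient so the lesion fits the grid with a margin, never finer than
1 mm for cohort rendering.

**Observer masks.** A second observer's delineation is emulated by
adding a smooth unit-variance random field (correlation length 3 mm) to
the mask's signed boundary distance and re-thresholding at zero — only
near-surface voxels can flip, and the expected Dice similarity decreases
monotonically with the amplitude (in mm). The signed distance uses an
in-package separable Euclidean distance transform (lower-envelope
algorithm), verified against a brute-force oracle.
`calibrate_observer_noise()` simulates the amplitude-DSC curve and
interpolates the amplitude for a target DSC such as 0.92, the level
reported for expert manual GIST delineation.

**Noise and determinism.** Optional multiplicative lognormal noise on
measured volumes (diameters scale coherently by its cube root) with
configurable sigma, default 0. All randomness flows from one spec seed
through fixed per-patient sub-seeds, so identical spec and seed give
bit-identical cohorts, including rendered voxels.

**What passing tests do and do not show.** The generator produces single
ellipsoidal lesions on empty backgrounds with exactly the decay structure
described above. Tests passing on such cohorts validate the measurement,
classification, evaluation and trajectory code paths; they say nothing
about segmentation quality, contrast-phase effects, scanner heterogeneity
in HU, irregular tumour shapes, or multi-lesion disease. The generator
also produces no progressive-disease trajectories by default; PD logic is
covered by direct unit tests instead.

## Numerical choices and degenerate inputs

* Threshold comparisons are inclusive; reported values are rounded half
  away from zero; classification never rounds.
* An empty mask yields an absent observation (volume 0, diameter 0,
  density undefined); mean density on an empty mask, percentage change
  on a zero baseline, ICC on constant input, and performance metrics
  with an empty group all raise named errors rather than returning NaN.
* Two empty masks have Dice 1; a single voxel has diameter 0.
* Grid matching uses a 1e-3 mm spacing tolerance; NIfTI round trips
  preserve voxels exactly and spacing to 1e-6 mm.
* Problem sizes in the test-suite simulations (cohorts of 30, grids up
  to 169^3 at 0.5 mm, 200-seed replications of the analytic generator)
  were chosen to give stable statistics while keeping a full run in the
  order of a minute.

## Known limitations

* Single-lesion bookkeeping only; no sum-of-longest-diameters across
  target lesions, no non-target or new-lesion rules.
* Baseline-referenced changes only; no nadir logic.
* Diameters are measured on the native grid with the voxel-centre
  convention; absolute diameters can under-read by up to one in-plane
  voxel (percentage changes are unaffected in expectation).
* The Choi density metric inherits all HU comparability caveats across
  scanners and contrast phases; the package measures, it does not
  harmonise.
* The generator's plateau model is a simulation device, not a fitted or
  fittable growth model.
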