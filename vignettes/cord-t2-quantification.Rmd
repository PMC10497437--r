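---
title: "Quantifying spinal cord T2 signal variability: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spinal cord T2 signal variability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordT2)
```

## The problem

Degenerative cervical myelopathy (DCM) produces focal hyperintensities in
the spinal cord on T2-weighted MRI. In clinical routine these "myelopathy
signs" are read subjectively and binarily — a segment is called T2-positive
or not — and such calls are rater-dependent. An objective alternative is to
quantify the T2 signal intensity (T2-SI) of the segmented cord itself.
The catch is that MRI intensities are arbitrary units: absolute T2-SI is
not comparable between scans or subjects. What *is* comparable is the
**variability** of the signal along the cord, normalized by its own mean.

`cordT2` implements this quantification end to end. Given a 3D T2-weighted
volume, a binary cord segmentation on the same grid, and the slice indices
of the vertebral body centers C2–C7:

1. **Slice-wise curve** (`extractSICurve`). For every axial slice the cord
   cross-sectional area (CSA, voxel count × in-plane voxel area, mm²) and
   the arithmetic mean of the intensities over cord voxels are computed.
   The sequence of slice means is the T2-SI curve. Slices without cord
   voxels are undefined (NA), never imputed as zero.
2. **Level subdivision** (`subdivideSegments`). The cord span is cut into
   the five disc levels C2/3 … C6/7, each running from the center of the
   upper vertebral body to the center of the lower one. Intervals are
   half-open, `[center(Ck), center(Ck+1))`, so they tile the C2→C7 span
   exactly and no slice is counted twice.
3. **Per-level statistics** (`segmentStatistics`). Over the defined slice
   means of one level: mean, SD, range (max − min), and the
   **T2 myelopathy index**

   $$\mathrm{T2\text{-}MI} = \frac{\mathrm{range} \times 100}{\mathrm{mean}} \;[\%],$$

   which is invariant under any positive rescaling of the volume — the
   property that makes it inter-individually comparable while raw a.u.
   values are not.

Around this core the package carries the full study machinery: multi-rater
consensus and agreement (`consensusRatings`, `percentAgreement`,
`fleissKappa`), age- and level-matched control construction
(`matchControls`), Mann-Whitney and exact binomial comparisons, and ROC
analysis with Youden and closest-to-top-left cutoffs (`rocAnalysis`,
`youdenCutoffs`, `closestTopLeftCutoff`).

## Statistical conventions

Several choices are deliberately fixed and worth stating:

- **SD over slice means, not voxels.** The variability parameters describe
  the T2-SI *curve*; SD and range are taken over the slice means within a
  level. The SD uses the n−1 denominator by default; `sdDenominator = "n"`
  toggles the population form.
- **Unweighted segment mean.** The per-level mean is the plain mean of
  slice means (not CSA-weighted), so mean, SD, range and T2-MI all refer
  to the same sequence of numbers.
- **Empty slices** inside a level are excluded from the statistics; if more
  than 20% of a level's slices are empty a classed warning is raised.
- **Reporting** is median (IQR) throughout, with type-7 (linear
  interpolation) quantiles; `percentAgreement` reports one decimal.
- **Mann-Whitney p-values** are exact (from the exact null distribution of
  U, equivalent to enumerating all labelings) whenever
  $n_x n_y \le 400$ and the pooled sample is tie-free; otherwise the
  normal approximation with tie and continuity correction is used. The
  switch trades exactness where it is cheap for reproducibility elsewhere.
- **ROC ties are surfaced.** `youdenCutoffs` returns *all* thresholds
  attaining the maximal J = sens + spec − 1 (co-optimal cutoffs are a real
  phenomenon in matched designs), in ascending order; the closest-top-left
  rule breaks its ties toward the smaller threshold. The AUC is computed
  both as the trapezoid under the empirical curve and as the midrank
  Mann-Whitney statistic $U/(n_1 n_0)$; the implementation asserts their
  agreement to 1e-12 on every call.
- **Matching** is deterministic greedy: within each level, cases in
  ascending age order each take the unused volunteer segment minimizing
  the absolute age difference, ties broken by the lower subject id. A
  volunteer may serve at several levels but each control *segment* is used
  once. Greedy is transparent and reproducible; it does not guarantee the
  globally minimal total age difference, which is acceptable for a
  matching whose only purpose is age comparability.

## The synthetic phantom

No public imaging accession exists for this quantification, so the package
ships a first-class generator (`generatePhantom`) whose defaults define the
study conditions used by the test suite:

| parameter | default | meaning |
|---|---|---|
| grid | 64 × 64 × 120 voxels | in-plane × in-plane × slices |
| spacing | 0.6 × 0.6 × 1.0 mm | reference acquisition voxel size |
| cord radius | 4 mm | analytic tube, slice axis = 3rd axis |
| baseline | 250 a.u. | cord intensity, the observed order of magnitude |
| CSF sheath | 420 a.u., 1.2 mm | T2-bright; makes the cord/CSF border a real hazard for intensity-based segmentation |
| background | 60 a.u. | surrounding tissue |
| landmarks | every 18 slices | each disc level spans 18 slices, enough for meaningful SD/range |
| noise | Rician, σ in a.u. | magnitude-MRI convention; a Gaussian flag exists for analytic tests |
| global scale | multiplicative | per-subject scanner-arbitrariness factor, applied to the whole magnitude image (signal *and* noise) |

Lesions are separable fields added to cord voxels: a Gaussian along the
cord axis (σ in slices) times a radial super-Gaussian
$\exp(-(r/R)^{2p})$ in-plane with $p = 1 + 9\,s$ for sharpness
$s \in (0,1]$ — $s = 1$ is near top-hat ("sharply delineated"), small $s$
an ordinary Gaussian ("blurry"). The sharp/blurry distinction is generated
but never classified. An optional central canal (off by default) adds a
thin CSF-bright tube on the cord axis; its geometry is a minimal stand-in
since no reference geometry is defined for it.

What the phantom does *not* emulate: anatomically shaped vertebrae and
cord curvature, bias fields and coil profiles, motion, partial-volume
averaging at the cord boundary, and real lesion morphology. Passing tests
on phantoms therefore validate the *quantification arithmetic and its
invariances*, not clinical performance: the clean geometric separation the
cohort tests achieve (AUC near 1) is expected to be far better than what
heterogeneous clinical data yield.

`segmentPhantomClassical` is a deliberately classical intensity-band +
connected-component + hole-filling segmenter provided so the pipeline can
be exercised without any external segmentation. It estimates the cord band
from the median of a central cylinder (hence scale-free), keeps the
plausibly sized component nearest the expected axis per slice, and fills
holes left by bright lesion cores. On noiseless phantoms it is exact; at
5% noise it stays at Dice ≈ 1, comfortably above the 0.91 floor used as
its benchmark. It is a phantom tool, not a clinical segmenter.

## The cohort replica

`runCohort(cohortConfig(...))` orchestrates the whole analysis at
synthetic scale. Patients carry one lesion each at a level drawn with
weights 6 : 15 : 22 : 6 over C3/4–C6/7 (the empirical distribution of
positive levels; C2/3 never carries one), volunteers none. Ages are
uniform in 40–80 years, global scales uniform in 0.7–1.3. Subjective
ratings are simulated from lesion truth: each of three raters flips the
truth with probability ε = 0.05 — a plumbing model, clearly non-anatomical;
note that ε = 0.05 yields three-rater unanimity around 86%, a deliberately
harsher disagreement regime than expert readers exhibit. Consensus is
strict majority. Matched pairs feed the group comparison (median/IQR,
Mann-Whitney per level and pooled) and ROC for SD, range and T2-MI; a
level with no consensus-positive segment is dropped from per-level strata.
With `lesionAmplitude = 0` no hyperintensity exists at all and the run
aborts at the ROC stage with a single-class-labels error — the documented
degenerate path. Everything derives from one seed; identical configs give
byte-identical report files.

Default problem sizes (30 + 30 subjects at 64 × 64 × 120; 32 × 32 × 72 for
the quick examples) keep a full replica in the tens of seconds while
leaving every level with double-digit slice counts.

```{r cohort, eval = FALSE}
res <- runCohort(cohortConfig(nCases = 30, nControls = 30, seed = 1))
auc(res$roc$t2_mi_percent)
youdenCutoffs(res$roc$t2_mi_percent)
```

## Numerical and degenerate-input choices

- Landmark centers are integers; fractional inputs round half-down so
  adjacent half-open intervals stay disjoint.
- 0-based slice indices everywhere; all intervals half-open.
- Dice of two empty masks is defined as 1 (vacuous agreement); the
  `CordMask` class forbids constructing an empty mask, so this arises only
  for raw arrays.
- Fleiss' kappa returns `NA` (an explicit undefined marker, not an error)
  when every cell is one category and chance agreement is 1.
- `rocAnalysis` refuses single-class labels; all-equal scores are legal
  and yield AUC 0.5 with a single defined cutoff.
- A non-positive segment mean makes T2-MI undefined and raises a classed
  error rather than returning a negative percentage.

## Known limitations

- The per-level mean is unweighted by CSA; a CSA-weighted variant would
  change T2-MI slightly where the cord tapers (flagged for sensitivity
  analysis, not implemented).
- The matcher is greedy, not globally optimal (see above).
- The phantom's geometric idealism means cohort-level acceptance numbers
  (AUC ≈ 1) sit above clinically reported discrimination; they verify the
  machinery, not the clinical effect size.
- Lesion boundary sharpness is generated but not scored; classifying
  sharp vs blurry demarcation is out of scope.
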