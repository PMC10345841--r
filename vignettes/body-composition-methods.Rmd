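---
title: "CT body composition at L3: models, segmentation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CT body composition at L3: models, segmentation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctbodycomp)
```

## The problem

A single axial CT slice at the third lumbar vertebra (L3) is the standard
imaging proxy for whole-body composition: the cross-sectional areas of
skeletal muscle and of the adipose depots there track whole-body fat mass
(FM) and fat-free mass (FFM). Converting those slice measurements into
kilograms requires calibration equations, and the calibrations in common
use were developed in predominantly normal-to-overweight (mostly
oncological) cohorts. `ctbodycomp` implements the measurement chain — HU
segmentation, tissue metrics, three linear mass models, and the agreement
statistics used to validate them against DXA — together with a synthetic
phantom/cohort generator that gives every stage a ground truth.

## Segmentation model and its assumptions

Pixels are classified by Hounsfield-unit windows applied inside spatial
compartments:

| tissue | HU window | compartment |
|---|---|---|
| skeletal muscle | [−29, 150] | abdominal wall band |
| subcutaneous fat (SAT) | [−190, −30] | subcutaneous zone |
| visceral fat (VAT) | [−150, −50] | visceral cavity |
| intramuscular fat (IMAT) | [−190, −30] | wall band |

All bounds are inclusive at both ends (the windows are quoted as closed
ranges, and inclusive is the common convention). The VAT window is a
subset of the SAT window, so HU alone cannot separate the depots:
classification is therefore *compartment-first, window-second*. The
compartments come from morphology only:

* **body** — largest connected component above −500 HU, hole-filled; a
  body touching the image edge is flagged as truncated.
* **subcutaneous zone** — non-muscle-window tissue connected to the skin
  surface.
* **wall band** — muscle-window components adjacent to the subcutaneous
  zone, plus enclosed non-muscle pockets smaller than `hole_max_mm2`
  (default 300 mm²), which is how fat infiltrating the muscle becomes
  IMAT territory. The visceral cavity is also enclosed by the wall but is
  orders of magnitude larger than the pocket cap, so it is never absorbed.
* **visceral cavity** — the remainder.

This morphological rule replaces the interactive/learned segmentation a
clinical tool would use; it assumes a closed muscle wall and a
subcutaneous fat layer reaching the skin. IMAT is given the SAT window
because no separate IMAT window is in standard use. The −500 HU body
threshold and the pocket cap are fixed, overridable constants.

## Tissue metrics

Areas convert as `pixels × row_spacing × col_spacing / 100` (mm² → cm²);
indices divide by height² (SMI = SMA/height², cm²/m²). Two choices were
genuinely open and are fixed as:

* **FAT(%) denominator** — the body-region area of the analysed slice(s):
  `FAT% = (SFA + VFA + IMAT)/body area × 100`. IMAT is counted in the fat
  share; it is fat, and excluding it would make FAT% depend on the wall
  geometry. The per-tissue columns let a user recompute any variant.
* **Multi-slice aggregation** — areas and percentages average across
  slices; mean HU is *pixel*-weighted (aggregate mean HU equals the mean
  over all pixels of all slices), not slice-weighted. The whole-region
  mean HU that feeds the density rule is aggregated the same way.

## The three mass models

Model 1 (`model1_fm`, `model1_ffm`) is the widely used area calibration
(FM = 0.042·FatArea + 11.2; FFM = 0.3·MuscleArea + 6.06). Model 2 is its
least-squares refit on a cohort spanning normal BMI to morbid obesity
(0.058/7.35 and 0.27/13.31). Both are affine in a cm² area.

The density-weighted model adds tissue *quality*. CT attenuation is
approximately linear in physical density near water, giving the rule
ρ = HU/1000 + 1 (`hu_to_density`; documented in kg/cm³ to match the
published equation — physically the magnitude is g/cm³, but the fitted
slope absorbs the unit scale, so the formula is implemented exactly as
printed). The derivation chains:

* V_total = Weight / ρ_ROI — body volume extrapolated from scale weight
  and the whole-region mean HU;
* V_fat = V_total · FAT(%)/100 — fat volume from the fat area share;
* M_fat ≈ V_fat · ρ_fat — mass restored through the fat density.

The calibrated form is FM = 0.0069·(Weight/ρ_ROI)·FAT(%)·ρ_fat + 4.53,
with FAT(%) kept on the 0–100 scale (the slope absorbs the factor 100),
and FFM = Weight − FM, an exact identity the tests hold to machine
precision. ρ_fat uses the pooled mean HU of all fat (SAT+VAT+IMAT) by
default — whether a fat-depot subset should be used instead is not
settled, so the argument is explicit. Published coefficients are the
defaults everywhere; `fit_linear` refits override them explicitly, never
silently.

The Cohen-style sample-size helper implements N = z²·s²/d² as printed,
plus the 35% inflation step (51 × 1.35 = 68.85). Note the published
worked example quotes S = 284 cm² and d = 4 kg and reports N ≈ 68;
direct evaluation of the formula with those numbers gives ~19,400 —
the units of S and d differ and the intended conversion is unstated, so
the helper makes no attempt to reproduce that 68.

## Agreement suite

Differences are `estimate − reference` (model minus DXA), so models that
underestimate show negative bias. Bland-Altman limits are
bias ± 1.96·SD(differences) with the n−1 SD denominator. The Pearson CI
uses the Fisher z transform. The error grid bins
|estimate − reference|/reference into contiguous bands <10%, 10–25%,
≥25% (the published banding leaves 20–25% unassigned; contiguous edges
are the only self-consistent reading, and the edges are configurable).
QQ pairing uses plotting positions (i − 0.5)/n. `summarize_table2`
emits the model × FM/FFM × slice-mode grid; the Pearson cell for the
density-weighted model's FFM is omitted by default because that FFM is
the weight complement, not a direct estimate (`show_derived_ffm_r`
restores it).

## What the synthetic generators emulate

The **phantom** is a concentric-ellipse torso: SAT ring, muscle wall,
and a visceral cavity lined with a thin visceral-fat layer (emulating
retroperitoneal fat) containing organ-like soft tissue, random VAT blobs
and a vertebral-body placeholder. Per-tissue HU are truncated normals
(±3 SD) centred inside each threshold window (muscle 40, SAT −100, VAT
−90, soft tissue 20, bone 400; SD 5 except bone 40) — intra-tissue HU
variability is not published for any cohort, so these are realistic
placeholders, not calibrated values. Because sampling stays strictly
inside the windows and the fat lining keeps organs off the muscle wall,
compartment derivation and segmentation are provably exact on phantoms;
that is the point — the phantom is an oracle, not an anatomy model. It
deliberately omits scanner physics (noise texture, beam hardening),
contrast phases, organ anatomy and window-overlapping tissue at
compartment borders, so pixel-perfect accuracy on phantoms bounds
correctness of the *logic*, not performance on real scans. The
translation-invariant stack option makes 1-slice and 16-slice analyses
provably identical, mirroring the qualitative single-slice-sufficiency
comparison.

The **cohort** generator draws weight (55–160 kg), height (1.50–1.90 m)
and fat percentage (18–55%) uniformly — spanning normal BMI through
morbid obesity like the 70-subject population the models target, with
n = 70 and 59% female as defaults. Whole-region mean HU is a two-point
fat/lean mixture at the subject's fat fraction (fat ≈ −95 HU, lean ≈ 35
HU), so heavier-fat subjects have lower whole-slice density, as in real
scans. Reference fat mass follows the density-weighted form with the
published coefficients plus Gaussian noise (default SD 3 kg, a plausible
DXA-vs-model residual scale), and FFM = weight − FM; the area form is a
config option. This makes parameter recovery the acceptance surface:
noise-free cohorts refit to the generating coefficients to numerical
precision, and at n = 70 with 3 kg noise the refit is unbiased within
Monte-Carlo error over 500 replicates. What generated-cohort agreement
does *not* show is how the models perform on real anthropometry — the
generative model is the density-weighted form itself, so its advantage
over the area models on these cohorts is by construction.

## Numerical and interface choices

* Coordinates are row-major with origin top-left; areas never depend on
  orientation. HU calibration is mandatory at read time
  (`decode_stored_values` applies slope/intercept); raw stored values
  never propagate. DICOM series are not parsed directly — convert to
  NIfTI upstream.
* One integer seed threads through every sampler via a state-restoring
  wrapper; no hidden global RNG state, and identical spec + seed gives
  byte-identical outputs (the pipeline manifest records MD5 checksums to
  make this checkable).
* Degenerate inputs: an absent tissue reports zero area and a flagged
  `NA` mean HU rather than propagating NaN; a constant sample in the QQ
  check sets a `degenerate` flag; fits refuse fewer than 3 points or a
  zero-variance predictor; a non-positive whole-region density (HU ≤
  −1000) is rejected as nonphysical.
* Problem sizes in the test suite (96×96-pixel phantoms at 2 mm, cohorts
  of 20–70, 500 Monte-Carlo replicates) keep the full suite to seconds
  while leaving all discretisation tolerances comfortably exercised;
  larger phantoms only tighten the geometric checks.

## Known limitations

Compartment morphology assumes a closed muscle wall — severe wall
defects (hernias) would leak the cavity into the subcutaneous zone. Bone
is a placeholder, not quantified. Muscle-group-specific areas are out of
scope (only pooled SMA is reported). Slice selection around L3 is the
caller's responsibility. The clinical agreement numbers published for
the 70-subject cohort cannot be reproduced here because that dataset is
not deposited; the validation suite instead proves the machinery on
synthetic ground truth.
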