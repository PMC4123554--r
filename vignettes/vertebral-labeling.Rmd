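---
title: "Template-based vertebral labeling: method and design notes"
author: "vertlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based vertebral labeling: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertlab)
```

## The problem and the model

Spinal cord MRI metrics are reported per vertebral level, so every
processing pipeline needs the map from position along the cord to vertebral
index. `vertlab` computes that map by detecting the intervertebral disks in
a one-dimensional intensity profile taken along the spine and counting
caudally from C2–C3.

The method rests on three modeling assumptions:

1. **Disks are a quasi-periodic intensity signal along the spine.** On
   T1-weighted images the disks are darker than the vertebral bodies, on
   T2-weighted images brighter; either way a profile along the column shows
   one extremum per disk. Because the profile follows the (shifted) cord
   centerline in 3D, curvature in both the anteroposterior and mediolateral
   directions is handled without selecting a sagittal plane.
2. **Intervertebral distances are stereotyped.** Adjacent-disk distances
   increase caudally and vary between adults by roughly a scale factor.
   A template of generic distances therefore predicts where the next disk
   must be, up to a per-subject ratio that the scan estimates as it goes.
3. **Local evidence can fail; the prior should then take over.** When a
   disk is obscured (implant dropout, degenerated disk, low SNR), its
   correlation score is low *relative to the scan's own history*, and the
   disk is placed at its template-predicted position instead. This is the
   mechanism that makes the labeling robust rather than merely accurate.

## Pipeline stages and their parameters

| parameter | default | units | role |
|---|---|---|---|
| anterior shift | 15 | mm | moves the sampling curve from the cord onto the column |
| patch extent (LR × AP) | 10 × 10 | mm | averages out within-column texture and cord/column distance variability |
| profile step | 1 | mm | arc-length sampling resolution |
| pattern width | 15 | mm | FWHM of the sinc whose 2n-th power matches a disk |
| pattern exponent n | 10 | — | kills side lobes; FWHM of the powered pattern ≈ 4 mm |
| search range | 0.2 | fraction | half-width of the local search, × scaled generic distance |
| fallback threshold | 0.4 | fraction | of the median of previously accepted correlations |
| ratio clamp | [0.7, 1.3] | — | admissible subject/template scale |
| min ratio span | 60 | mm | template span below which the ratio stays 1 |

The pattern is `sinc(x/width)^(2n)` sampled at 11 points, one per profile
step. Detection quality is flat across width 10–20 mm and n 8–12 (the
acceptance suite re-runs the full experiment at the corners of that range),
so these are not sensitive knobs.

**Correlation score.** The moving-window score is the Pearson correlation
between the 11-sample pattern and the profile window (both mean-centred,
unit-scaled). A normalized score is what makes the 40 %-of-median fallback
rule meaningful: raw dot products would scale with local intensity and the
median of the history would be uninterpretable.

**Contrast handling.** After detrending, a T2 profile is divided by its
maximum; a T1 profile is divided by the magnitude of its most negative
excursion and sign-flipped. Both contrasts then present positive unit
peaks, and a single detection path serves both. The normalized profile is
re-tagged with the positive-peak convention, which also makes normalization
idempotent.

**Peak-height equalization.** Before the sequential scan, a natural cubic
spline is passed through the profile's rough local maxima (prominence
≥ 10 % of the profile maximum, minimum separation 8 mm ≈ half the smallest
adult gap) and the profile is divided by it. This flattens the slow
intensity modulation across disks — in real data, coil sensitivity losses
that depress the lumbar peaks. The spline is floored at 5 % of the profile
maximum so undershoot between widely spaced knots cannot blow the quotient
up. With fewer than three usable maxima the spline is under-determined and
the step becomes a no-op with a warning.

## The sequential scan

From the first disk (C2–C3 found by correlation, or a user-designated
level and position when C2 is not in the field of view), the scan repeats:

1. *Predict*: `prob = position(last) + generic(i) × ratio`.
2. *Refine*: correlation argmax within ± 0.2 × generic(i) × ratio of the
   prediction. Ties go to the candidate nearest the prediction, then to the
   more rostral one; a flat window scores 0 and returns the prediction.
3. *Decide*: accept the refined position unless its score is below 40 % of
   the median of previously accepted scores; otherwise place the disk at
   the prediction (template fallback). Fallback steps are excluded from the
   score history — they carry no meaningful correlation.
4. *Rescale*: re-estimate the ratio, then continue until the template or
   the field of view is exhausted (two consecutive fallbacks past the
   caudal end truncate the scan).

**Ratio estimation policy.** The ratio is the cumulative detected span from
the first disk divided by the matching cumulative template span, clamped to
[0.7, 1.3]. Two refinements matter in practice:

* Only correlation-detected disks serve as anchors. A fallback position
  *is* the template's own prediction; feeding it back into the ratio would
  only reinforce whatever value the ratio already had.
* The ratio stays at its neutral value 1 until the anchoring template span
  reaches 60 mm (about three cervical gaps). The estimate's relative error
  is (localization error)/(span); with millimetre-scale localization error
  over a single 16 mm gap that is worse than the between-subject scale
  variability the ratio is meant to capture, so below the threshold the
  prior is the better estimator. Without this rule a single borderline
  acceptance at an artifact margin can corrupt the ratio while the scan is
  crossing the artifact on template predictions alone, and the compounded
  drift shifts every subsequent label by one level.

**First-disk gating.** "The most rostral local maximum of the correlation
profile" is ill-posed on noise: the normalized correlation is
scale-invariant, so a pure-noise window can correlate highly with the
pattern. A candidate maximum must therefore pass two gates: correlation
≥ 50 % of the global correlation maximum, and window peak-to-trough range
≥ 8 × the noise SD (estimated robustly as `mad(diff(profile))/√2`). The
amplitude gate is deliberately referenced to the noise floor and not to the
profile maximum: under an implant-like dropout the T1 normalization is
dominated by the artifact trough and genuine disk peaks sit at a small
fraction of the profile maximum.

## The distance template

A template row is one gap: upper/lower vertebral index (numeric scheme,
1 = C1 … 8 = T1 … 20 = L1), across-subject mean distance, sample SD (n − 1
denominator) and subject count. `buildTemplate()` pools hand-labeled (or
phantom ground-truth) disk positions from any number of subjects covering
possibly different contiguous ranges; `validateTemplate()` reports — but
does not reject — violations of the caudal-increase trend and relative SDs
above 20 % (the same fraction that bounds the search window, so a noisier
gap would outgrow its own search range). Templates round-trip through a
headered CSV.

The template shipped with the package is the phantom generator's own gap
layout (13 gaps, 16–28 mm, C2–C3 through T8–T9) — a synthetic fixture, not
population data. Study-specific templates (e.g. pediatric cohorts) are
built with `buildTemplate()`/`writeDiskTemplate()` and passed via
`templatePath`.

## What the phantom emulates, and what it does not

`generatePhantom()` renders, at 1 mm isotropic resolution by default: a
tube of vertebral-body signal bent sinusoidally in both transverse
directions (one gentle period over the field of view, amplitude 5 mm);
raised-cosine disks (FWHM 4 mm) at configurable arc-length positions with
caudally increasing gaps; polarity-switchable disk/body contrast (default
30 over noise SD 3, i.e. CNR 10); a cord cylinder 15 mm posterior to the
column axis; a smooth multiplicative low-order polynomial bias field
(default ± 20 %); additive Gaussian noise; and optionally a signal-dropout
slab covering named vertebral levels, disks included, with half-cosine
margins about 5 mm wide — susceptibility dropout has smooth edges, and a
hard step would manufacture a pattern-shaped decoy at the slab boundary
that no real artifact produces. Raised-cosine disks rather than hard blocks
keep the correlation landscape smooth and free of tied maxima. Identical
configurations and seeds give bit-identical volumes.

Deliberately **not** modeled: MR physics (no k-space, Rician noise, or
chemical shift), soft tissue other than column and cord, vertebral shape
(processes, endplates), scoliosis-grade curvature, and motion. Passing the
phantom experiments therefore demonstrates the algorithmic properties —
polarity handling, detrending, template rescaling, fallback behaviour,
parameter insensitivity — not performance on clinical data, where the
centerline quality and tissue heterogeneity add error sources the phantom
does not contain.

## Numerical choices and degenerate inputs

* **Detrending.** The baseline model is `a + b·s + c·sin(2πs/λ + φ)`,
  linear in its coefficients once λ is fixed; λ is chosen from a small grid
  (0.75–3 × the profile span, bounded below by 120 mm ≈ 4 × the largest
  adult gap so the sinusoid cannot absorb disk peaks) by the robust loss of
  an IRLS fit with soft-L1 weights. If every fit fails, a running-median
  baseline is used and a warning is raised.
* **Centerline extraction.** Per-slice intensity centroids are smoothed
  with a 7-slice running mean before arc-length resampling: voxelization
  jitters raw centroids by a fraction of a voxel, which inflates the
  cumulative arc length by ~0.3 % and would bias every caudal position
  systematically. Empty masks, single-slice masks and axial gaps over
  10 mm are rejected with the gap location.
* **Patch sampling.** Patch points outside the volume are dropped from the
  average, never zero-filled; a sample whose entire patch is outside is
  marked missing, and profiles with over 20 % missing samples are rejected.
* **Projection.** Disk positions live on the shifted curve; each is mapped
  to the foot of the perpendicular on the centerline polyline. Where the
  spine bends anteroposteriorly the foot shifts slightly along the curve —
  a geometric bias of up to ~1–2 mm at the default curvature that is part
  of the reported position error. Template distances are measured along
  the spine axis (the profile), not on the cord projections, precisely to
  avoid paying that bias twice per gap.
* **Labels.** A sample exactly at a disk position belongs to the rostral
  side; the region rostral of the first disk carries that disk's upper
  vertebra index and the region caudal of the last disk the next caudal
  index.

## Problem sizes

The test suite works mostly on a short-spine phantom (7 disks, 50 × 90 ×
170 mm) chosen so each volume renders in well under a second; the
validation experiments use the full default phantom (14 disks, C2–C3
through T8–T9, 64 × 96 × 360 mm), 8 volumes per contrast plus one
implant-artifact volume, which is the same experiment design
`scripts/acceptance.R` re-runs from scratch with per-volume seeds derived
from its `--seed` argument.

## Known limitations

* The first-disk step assumes C2 is in the field of view; otherwise the
  caller must supply the starting level, as in the original design.
* The template must cover every gap to be labeled; scanning past its
  caudal end stops the scan rather than extrapolating.
* Vertebral, not spinal (neurological), levels: the two differ
  systematically and no correction is attempted.
* The centerline extractor is a deliberately simple per-slice centroid
  tracker intended for cord masks; strongly non-convex or broken masks
  deserve a dedicated segmentation tool upstream, and externally computed
  centerlines are accepted as plain text for exactly that reason.
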