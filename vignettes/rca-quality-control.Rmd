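---
title: "Reverse classification accuracy for segmentation quality control"
author: "rcaqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse classification accuracy for segmentation quality control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcaqc)
```

## The problem

Automated segmentation pipelines in large imaging studies produce label
maps for thousands of scans, and a small fraction of them fail — badly
enough that downstream volume or thickness measurements would be wrong.
Visual inspection of every case does not scale, and once a method is
deployed there is no ground truth (GT) to compute a Dice coefficient
against. What is needed is a per-case estimate of segmentation quality
that requires no GT for the case under assessment.

`rcaqc` implements reverse classification accuracy (RCA) with a
single-atlas registration classifier for this purpose, in the reversed
registration direction. The intuition: if a segmentation of a test image
is good, then at least one atlas in a verified reference set — typically
the one most similar to the test anatomy — will, after registration onto
the test image, agree well with it. If no warped reference agrees, the
segmentation was probably poor.

## The procedure

Given a test image with its automatic segmentation under assessment and a
reference set of $N$ verified atlases (image + segmentation pairs):

1. every reference image is rigidly pre-aligned to the test image by a
   centre-of-mass (CoM) translation computed on min-shifted intensities;
2. a deformable registration refines each alignment (moving = reference,
   fixed = test image);
3. the resulting transform warps the reference *label map* onto the test
   grid by nearest-neighbour sampling — the test segmentation itself is
   never resampled, so no discretisation artefacts are introduced into
   the map being assessed;
4. each warped reference segmentation is scored against the test
   segmentation with the Dice similarity coefficient (DSC) and with
   mean, root-mean-square and maximum (Hausdorff) symmetric surface
   distances (MSD, RMSD, HD), per class, for the whole-heart (WH) union
   mask and as a class average (AV);
5. the best value over the reference set — maximum for DSC, minimum for
   distances, independently per (class, metric) slot — is the quality
   prediction. The winning reference per slot is recorded for audit.

The container classes are `Atlas` (verified pair), `RcaTestCase` (image,
segmentation under assessment, optional GT) and `RcaResult` (prediction,
best-reference map, full per-reference table). A predicted DSC can then
be thresholded (default: DSC $\ge 0.7$ is *good*, both boundaries taken
from the standard reporting convention; MSD $\le 2$ mm for the
surface-based criterion) to flag failed segmentations, and
`ConfusionStats` summarises validation runs with accuracy, TPR and FPR,
where the *positive* class is a *good* segmentation — this polarity
reproduces the usual high-TPR / near-zero-FPR reporting on
predominantly good cohorts and is a deliberate, documented choice.

## Metric definitions and numerical conventions

$\mathrm{DSC} = 2|A\cap B|/(|A|+|B|)$ on voxel masks. Two empty masks
score a *flagged* 1.0; an empty against a non-empty mask scores 0, so a
wholly missing class registers as failure rather than being silently
skipped. The surface of a mask is its set of foreground voxels with at
least one 6-connected background or out-of-grid neighbour; distances are
Euclidean between voxel centres in physical millimetres with anisotropic
spacing applied per axis. The directed distance from each surface voxel
of $A$ is its minimum distance to the surface of $B$; the symmetric
statistics pool the two directed lists (not the average of two directed
means — with pooling, MSD $\le$ RMSD $\le$ HD always holds, and HD is
identical whether defined on the pooled list or as the max of the two
directed maxima). Distances against an empty class are undefined and
propagate as `NA`, never as numeric sentinels; undefined predictions
classify as *poor* (conservative quality control). These voxel-centre
conventions were chosen because they are deterministic and checkable
against a brute-force all-pairs oracle to 1e-9, which the test suite
does on random masks; mesh-based surface extraction is out of scope.

Grid convention: 0-based voxel index $(i,j,k)$ has its centre at
`origin` $+ (i s_x, j s_y, k s_z)$ mm. Class codes default to
background/LVC/LVM/RVC = 0/1/2/3 (left-ventricular cavity, LV
myocardium, right-ventricular cavity); other encodings are remapped at
ingest via the class map of `readLabels()`.

## Registration backends

The registration stage of an RCA system is deliberately pluggable. Three
backends share one interface (`registrationConfig()`):

* `identity` — no registration at all (no CoM step either). Exists so
  the RCA aggregation logic is testable exactly: with the test atlas
  among the references, the prediction equals the true metrics.
* `translation_only` — CoM alignment only. Fast (seconds per batch) and
  surprisingly competitive on roughly-aligned cohorts.
* `deformable` (default) — a deterministic multi-resolution demons-style
  registration written for this package: the classic intensity-difference
  force $(F - W)\,\nabla F/(|\nabla F|^2 + (F-W)^2/K^2)$ with $K$ the
  mean voxel spacing, evaluated on min-max-normalised, lightly
  pre-smoothed images, with the accumulated displacement field
  Gaussian-regularised after every iteration. A gradient-magnitude floor
  suppresses forces in flat, noise-dominated regions. The field lives on
  the fixed (test) grid in mm.

Defaults: 3 pyramid levels (factor-2 block averaging, clamped so no axis
drops below 4 voxels), 50 iterations per level, regularisation sigma =
twice the voxel spacing per axis (so through-plane smoothing matches the
coarse slice direction of stack-of-2D data), per-iteration step capped at
one voxel. A demons-style scheme was chosen over a B-spline free-form
deformation because it needs no generic optimiser, is deterministic to
the bit for a fixed configuration, and its per-iteration cost is linear
in the voxel count — the right trade-off for a method whose job is
scoring, not atlas construction. The registration contract is
*no-worsening*: if the optimisation fails to improve the SSD over the
initial transform, the field is dropped, the transform is flagged, and
the per-reference row is retained (a failed registration must not mask
information from the other references — one good reference suffices for
a good verdict).

Rigid alignment is translation-only by design: a centre of mass defines
no rotation, and rotations are left to the deformable stage. CoM is
computed on min-shifted *intensities*, not on masks, since reference
masks are part of the answer, not the question. On images whose
background is noisy rather than dark, intensity CoM under-corrects
translations; the deformable stage absorbs the residual.

## The synthetic phantom cohort

Because the clinical cohorts behind this kind of validation cannot be
redistributed, the package ships a generator of cardiac-like phantoms
emulating stack-of-2D short-axis end-diastolic CMR: per slice, a
circular LV cavity, a surrounding myocardial annulus and a crescent of
RV cavity abutting it, with radii tapering toward the apex; anisotropic
voxels (default $64\times64\times10$ at $1.8\times1.8\times8$ mm,
matching population-imaging resolution; a higher-resolution
$1.25\times1.25\times2$ mm setting matches typical reference-set
acquisitions). Per-subject jitter perturbs position and sizes; images
are class-mean intensities (bright blood pools, intermediate myocardium)
plus Gaussian noise and a low-frequency bias field. Seeds are derived
hierarchically (suite → cohort → subject → degradation), so any subset
regenerates independently.

Segmentations "of varying quality" are emulated by explicit degradation
operators on the GT label map — in-plane boundary erosion/dilation,
whole-slice dropout, random patch relabelling, rigid translation and
class deletion — rather than by retraining a weak learner: the operators
give direct, monotone control over the realised quality. The suite
builder measures the real whole-heart DSC of every degraded map and
nudges the severity (up to three attempts) when a draw misses its
intended good/poor side of the DSC 0.7 boundary, so the realised quality
spectrum covers both sides of the threshold down to severely failed
cases, at roughly 60% good. Severity placements in the default menu come
from measured degradation ladders on default phantoms.

What the phantoms deliberately do not model: MR physics (k-space,
coils, banding), papillary muscles (assumed merged into the cavity class
upstream), RV myocardium (rarely annotated in short-axis segmentations),
4D motion, and the specific error patterns of any particular segmentor.
Passing the synthetic validation therefore demonstrates that the
pipeline's mechanics — registration, warping, scoring, aggregation,
thresholding — behave correctly and that predictions track true quality
under controlled degradations; it does not certify accuracy numbers on
any clinical dataset.

## Validation results computed by this package

The test suite and `scripts/acceptance.R` recompute, from scratch, on a
20-reference / 60-test suite with the default deformable backend: the
Pearson correlation between predicted and real whole-heart DSC and the
good/poor classification accuracy at DSC 0.7 (both expected $\ge 0.9$ at
this scale); the MSD-criterion accuracy at 2 mm; the prediction MAE; a
degradation-ladder check (real DSC strictly decreasing, Spearman rho
between severity and predicted DSC $\le -0.8$); and a
reference-set-size experiment (sizes 3/5/10/20 × 3 runs) in which mean
accuracy does not decrease with size and, over nested subsets, per-case
predicted DSC is non-decreasing — exactly, because a maximum over a
superset cannot shrink. The subset experiment reuses the per-(reference,
case) metric table computed once for the full set; filtering rows before
aggregation is provably identical to re-running RCA on the subset.
Problem sizes were chosen so the whole validation runs in minutes on one
CPU; nothing in the package states results it does not compute.

## Known limitations

* Predictions are a *best over references*: with few or unrepresentative
  references, quality is under- rather than over-estimated — the
  conservative direction for QC, but a bias nonetheless (visible in the
  size experiment at size 3).
* The demons backend assumes the two images share an intensity mapping
  (same modality and similar contrast); a mutual-information similarity
  would be needed across contrasts and is not implemented.
* Oblique NIfTI orientations are not resampled; rotations are discarded
  with a warning and the grid treated as axis-aligned.
* Runtime per case is linear in the reference-set size; pre-selecting
  references for speed is intentionally out of scope here.
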