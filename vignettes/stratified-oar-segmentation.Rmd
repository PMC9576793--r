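---
title: "Stratified organ-at-risk segmentation: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified organ-at-risk segmentation: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Radiotherapy planning for head-and-neck cancer requires contouring
dozens of organs at risk (OARs) on the planning CT. The OARs differ
enormously in how hard they are to segment: bony, high-contrast
structures (mandible, eyes) are easy; soft-tissue structures (parotid,
constrictor muscles) are low-contrast; and some structures (lens,
cochlea, pituitary) are so small or so faint that a whole-volume
segmenter rarely finds them at all. `stratseg` implements a stratified
pipeline built around that observation, together with the evaluation
machinery (overlap and surface-distance metrics, dose-volume
histograms, dosimetric difference statistics) needed to judge whether
contour differences matter for the delivered dose.

## The stratified pipeline

The 42 supported OARs are partitioned in `build_registry()` into
**anchor** (9), **mid-level** (19) and **small-and-hard, S&H** (14)
strata. Inference runs in three guided stages:

1. **Anchor branch.** A segmentation network maps the volume `X` to
   per-voxel class probabilities over background + 9 anchor classes.
2. **Mid-level branch.** The anchor foreground probability maps are
   concatenated to the volume as input channels (`1 + 9` channels),
   conditioning the harder soft-tissue segmentation on the reliable
   anchor layout.
3. **S&H branch, detection then zoom-in.** A heatmap-regression
   network (same `1 + 9`-channel input) predicts one Gaussian-shaped
   heatmap per S&H OAR; the peak voxel seeds a volume-of-interest
   (VOI) crop sized at **three times** the class's maximum per-axis
   extent; a final network segments the fine boundary from the cropped
   volume alone, and the VOI mask is pasted back.

The heatmap training targets are `exp(-||p(v) - p(c)||^2 / (2
sigma^2))` in physical millimetres around the organ centroid `c`
(`gaussian_target()`); sigma defaults to 3 mm, a scale comparable to
the S&H structures themselves. The organ "center" is the mask
centroid rounded to the nearest voxel. VOI windows are half-open,
clamped by shifting inward so the full window size is preserved
whenever the volume allows it.

## The searchable backbone

All branches share one encoder–decoder family (`build_backbone()`):
`levels` resolutions, two convolution blocks per encoder level, two in
the bottleneck, two per decoder level, skip connections by channel
concatenation, 2× max-pooling and nearest-neighbour upsampling, and a
linear 1×1×1 head. Every block is **searchable** among six composite
operators — conv → instance normalization → leaky ReLU with kernels

* `2D3`, `2D5`: in-plane 3×3 or 5×5 (through-plane extent 1),
* `3D3`, `3D5`: full 3D kernels,
* `P3D3`, `P3D5`: pseudo-3D factorizations, in-plane then
  through-plane.

During search each block computes the softmax-weighted mixture of all
six candidates (`gamma_weights()`, `mixed_block_forward()`); weights
and architecture logits are optimized by **first-order alternating
descent** on two disjoint case partitions (default 2:1), and the final
genotype takes the top-weight operator per block, ties resolved to the
lowest index in the fixed ordering. First-order alternation (rather
than second-order unrolling) is the cheap, standard choice and keeps
the desk-scale CPU budget realistic.

The whole stack — convolutions via chunked im2col + BLAS, instance
norm, activations, pooling, the mixture rule and its gradients — is
implemented in this package (R + RcppArmadillo); there is no
deep-learning framework behind it. Gradient correctness is covered by
finite-difference tests.

### Numerical choices

* Double precision throughout; instance-norm epsilon `1e-5`;
  leaky-ReLU slope 0.01; He-normal initialization.
* Zero "same" padding preserves spatial shape in every operator.
* Inputs are globally z-scored per volume.
* Segmentation losses: foreground-weighted cross-entropy (weight 3)
  plus soft Dice restricted to the classes present in the patch —
  absent-class Dice terms otherwise dominate small patches and
  suppress all foreground. Heatmap regression uses mean-squared error.
* Adam (`lr` 5e-3 default) with cosine decay over the iteration
  budget; 2-patch batches with one forced-foreground patch per step
  and the second patch alternating between a structure-centered hard
  negative and a uniform draw, mirroring nnU-Net-style sampling. The
  segmentation head starts from a background-prior bias (+2 logits on
  the background class): foreground is rare, so the early iterations
  should refine it rather than first learn that fact.
* Heatmap regression weights each voxel by `1 + 99 * target`: the
  Gaussian bump occupies a vanishing fraction of a patch, and
  unweighted mean-squared error converges to a near-zero map.
  Detection patches are jittered by up to half the patch so the
  target never sits systematically at the patch center (which would
  invite a position shortcut instead of appearance detection).
* Whole-volume prediction sweeps half-overlapping tiles of the
  training patch size and averages probabilities before the hard
  argmax. We initially used disjoint tiles; structures cut at tile
  borders lose the shape cues a patch-trained, instance-normalized
  network relies on, and measured whole-volume accuracy collapsed
  while in-patch accuracy was near-perfect. Overlapped averaging is
  the field-standard resolution and is deterministic.
* Ties: argmax takes the first (lowest-index) maximum everywhere —
  operator selection, peak extraction (lexicographically smallest
  (z, y, x)), and class argmax (background wins exact ties).
* Every supported OAR is a single connected organ, so class masks
  keep their largest 6-connected component after the argmax —
  standard postprocessing for single-structure classes; it is
  switchable off in `argmax_masks()`.

## The phantom generator

`generate_phantom()` synthesizes the study conditions at desk scale: a
64×96×96 volume at 1.5 mm isotropic spacing containing non-overlapping
ellipsoids — up to 9 anchor-like (radii 8–14 mm, contrast +300), 19
mid-level-like (5–9 mm, +100) and 14 S&H-like (2–4 mm, +30) — over a
zero background with Gaussian noise (sd 10). Placement is rejection
sampling (≤1000 attempts) so per-branch single-label ground truth is
well defined; everything is a pure function of (config, seed).

Two generator choices deserve emphasis:

* **Within-stratum class identity is carried by size.** Structure *k*
  of a stratum draws its semi-axes from the *k*-th sub-band of the
  stratum's radius range (30% guard spacing). Real organs are
  distinguishable by appearance and anatomical position; ellipsoids
  are not, and the instance-normalized operators deliberately discard
  absolute intensity, so a contrast ladder cannot carry identity —
  geometry can.
* **What the phantom does not emulate:** anatomical shape variation,
  CT artifacts, organ-position priors, inter-patient variability.
  Passing the micro-training tests therefore demonstrates that the
  losses, gradients, guidance wiring and VOI algebra work — not that
  clinical-grade accuracy is attainable; that requires real cohorts
  and full-scale training outside this package's scope.

`perturb_mask()` emulates inter-reader contour variation: the mask's
signed distance function is offset by a smooth random field (Gaussian
bumps, 8 mm correlation length) scaled so the mean absolute boundary
displacement equals the requested magnitude, then re-thresholded —
locally dilating where the field is positive and eroding where
negative. `generate_dose_grid()` provides an analytic stand-in for an
IMRT dose distribution: a Gaussian falloff (default sigma 20 mm)
around a target centroid with a configurable prescription (70 Gy) and
background level, optionally on a coarser grid (clinical dose grids
are 2–4 mm).

## Metrics and dosimetry

`dsc()`, `hausdorff()` and `asd()` operate in physical millimetres on
anisotropic grids. Surfaces are mask voxels with a 6-connected
background neighbour (or on the volume border); distances come from an
exact separable Euclidean distance transform and are validated against
an exhaustive all-pairs oracle in the tests (agreement to 1e-9).
Hausdorff is reported as the true maximum, with the 95th-percentile
variant emitted alongside. Empty masks: DSC is defined (two empty
masks agree perfectly, flagged), distance metrics raise — silent
sentinel values hide failures.

Dose statistics transfer contours to the dose grid by
nearest-neighbour resampling in physical coordinates (deterministic
and conservative). `diff_direct()` fixes the planning dose grid and
swaps contours; `diff_clinical()` evaluates a replanned (substitute)
dose grid with both contour sets — replanning itself is an input,
never computed here. Percentages are signed; summaries report the
signed mean, mean absolute value, and the fractions of OAR instances
exceeding 10% and 30%. Both statistics vanish identically when
substitute equals reference and are invariant to global dose scaling.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `levels`, `base` | 2, 8 | backbone depth and width; production-scale values are not part of the desk-scale mandate |
| `patch` | 32³ voxels | training patch and inference tile size |
| `iterations`, `lr`, `batch` | 200, 5e-3, 2 | micro-training budget |
| `sigma_mm` | 3 mm | Gaussian heatmap scale |
| VOI factor | 3× max extent | fixed by the method definition |
| `fg_weight` | 3 | cross-entropy foreground weighting |
| perturbation `corr_length_mm` | 8 mm | smoothness of emulated reader variation |

Problem sizes used by the test-suite and the acceptance script — one
64×96×96 phantom, 200/150 training iterations, 20-seed Monte-Carlo
loops, 100 random mask pairs up to 16³ — were chosen so a single CPU
completes each stage in minutes while every mechanism is still
exercised end-to-end.

## Known limitations

* The micro backbone (2 levels, 8 channels) and budgets demonstrate
  mechanism, not clinical accuracy; no attempt is made to reproduce
  cohort-level results, which require large clinical datasets and
  GPU-scale training.
* Cross-branch label conflicts are not fused: each branch is its own
  multi-class problem and output masks may overlap across strata.
* One shared zoom-in model serves all S&H classes (class-conditional
  output); per-OAR models are configurable in principle but cost 14×.
* Partial-label cohorts are supported only through per-run class
  restriction, not per-case loss masking.
* DICOM/RTSTRUCT ingestion is out of scope; NIfTI is the single
  interchange format.
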