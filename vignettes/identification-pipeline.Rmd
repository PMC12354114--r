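---
title: "Identifying unknown decedents by matching CT-slice feature sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying unknown decedents by matching CT-slice feature sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

When an unknown deceased person undergoes a postmortem CT examination
(virtual autopsy), any antemortem clinical CT of the head that exists in a
hospital archive is a potential identifier: the maxillary sinuses differ
between individuals in shape, size, symmetry and contour, and those
differences survive death. `sinusmatch` implements a fully automatable
pipeline that matches a postmortem CT slice against a database of feature
sets extracted from complete antemortem CT series, and returns a ranked
list of candidate identities. It is a screening tool: it narrows hundreds
of candidates down to a handful that a forensic expert then verifies
against proper reference material.

## The pipeline

Each CT slice is reduced to a *CV feature set* — keypoints plus
64-dimensional real-valued descriptors — in three stages:

1. **Preprocessing** (`preprocess_slice()`): min–max normalisation to
   8 bits, edge enhancement with a parameterised Sobel operator, and a
   small averaging filter. Edges are what carries the identity signal
   (sinus outlines, bone contours), so they are amplified before
   detection.
2. **Feature extraction** (`extract_features()`): a KAZE-style detector on
   a nonlinear-diffusion scale space. Nonlinear diffusion smooths
   homogeneous regions while leaving strong edges sharp, which keeps
   keypoints on anatomical boundaries precise across scales.
3. **Matching** (`score_pair()`): descriptors of a query set A and a
   reference set B are compared by squared Euclidean distance; matches
   survive Lowe's ratio test, unique (one-to-one) assignment, and RANSAC
   homography verification. The count of verified matches, run in both
   directions, gives the similarity score

   $$\mathrm{score} = \frac{m_{AB} + m_{BA}}{2\,|A|} \cdot 100\ [\%],$$

   which is 0% for unrelated images and exactly 100% when B is an
   identical copy of A.

For identification, every slice of every antemortem series is enrolled in
a database (`build_database()`); a query produces one score list per
postmortem slice, each list is reduced to one maximum per identity
(`filter_max_per_identity()`), and the per-identity rank statistics across
the query slices are consolidated (`consolidate()`) by one of two
strategies: *score-based* (best score first, rank counts as tie-breaks) or
*rank-based* (rank-1 frequency first, then top-10 frequency, then best
score). Ties that remain are broken by identity key so the output is a
deterministic total order. Within each list, competition ("1224") ranking
is used, so several identities can share rank 1 when scores tie.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `sobel_gradient` | 1.8 | centre weight of the edge kernel |
| `averaging_size` | 3 | box-filter side, in pixels |
| `octaves` × `layers_per_octave` | 4 × 4 | scale-space depth (16 evolution levels) |
| `diffusivity` | PM_G2 | conductivity g = 1/(1 + \|∇L\|²/k²) |
| `detection_threshold` | 0.001 | scale-normalised Hessian threshold (image in [0, 1]) |
| `descriptor_type` | KAZE | 64-d real-valued, squared-Euclidean matching |
| `lowe_ratio` | 0.6 | ratio-test threshold on squared distances |
| `ransac_reproj_threshold` | 2 px | homography inlier tolerance |
| `span_mm` | 7.5 | query slice window half-width |

These defaults are the operating point reported as optimal for
maxillary-sinus CT matching; they can all be overridden from a YAML
configuration file (`read_config()`). The slice window covers ±7.5 mm
around the slice with the largest sinus representation — 25 slices at
0.625 mm spacing, 7 at 2.5 mm. The central slice is supplied by the
caller; selecting it automatically is out of scope.

## Design choices in ambiguous territory

* **Stage order.** The procedural description of the preprocessing lists
  normalisation → edge enhancement → averaging; a summary figure elsewhere
  lists enhancement first. We follow the procedural order by default and
  expose `stage_order = "normalize_last"` for the alternative reading.
* **"Modified Sobel".** The exact modification is not published. We
  parameterise the classic kernel's centre weight by `sobel_gradient`
  (classic Sobel has 2, the default here is 1.8) and blend the gradient
  magnitude onto the image, `clip(img + λ·mag)` with λ = 1; a
  magnitude-only mode is available (`sobel_mode = "magnitude"`).
* **Ratio-test domain.** The matching metric is squared Euclidean
  distance, and the 0.6 threshold is applied to the squared distances as
  computed. `ratio_on_squared = FALSE` switches to plain distances for
  sensitivity checks. A second-nearest distance of zero (duplicate
  descriptors) rejects the match: the ratio is undefined and duplicates
  carry no discriminative information.
* **Geometric model.** RANSAC fits a planar projective transform
  (homography). Slices from different acquisitions of the same anatomy
  differ by in-plane rotation, translation, scale and mild
  perspective-like distortion; the homography covers all of these with a
  4-correspondence minimum, which is also the `min_matches_for_geometry`
  default. Fewer surviving matches than that count as zero matching
  points — unverifiable matches are not trusted. Hypotheses use a fast
  exact 4-point solver; the consensus set is refit once with the
  normalised DLT and kept only if it loses no inliers.
* **Detector scope.** No AKAZE binding exists in this R stack, so the
  detector is implemented here: Fast Explicit Diffusion cycles solve the
  nonlinear scale space (τ_max = 0.25, conductivity from the σ = 1
  smoothed gradient, contrast factor at the 70th percentile), octaves are
  downsampled by 2× block averaging, and detection takes spatial maxima of
  the σ⁴-normalised Hessian determinant, merged across levels by greedy
  non-maximum suppression with radius σ/2, sub-pixel refined by a
  quadratic fit. Descriptors are M-SURF-style: 20×20 samples at σ spacing
  rotated into the keypoint frame (dominant-orientation from a smoothed
  36-bin gradient histogram), 4×4 subregions accumulating
  (Σdx, Σdy, Σ|dx|, Σ|dy|), Gaussian-weighted and L2-normalised.
  The `detection_threshold` scale therefore matches the conventional
  AKAZE operating range but is not numerically interchangeable with other
  implementations.
* **Determinism.** Everything outside RANSAC is deterministic. RANSAC
  draws are seeded per (query, entry) pair from one global seed, so score
  lists and reports are bit-reproducible; repeated `query` runs write
  byte-identical CSVs.
* **Privacy.** The database stores feature sets and pseudonymised
  metadata only — no pixels, no raw patient IDs. Pseudonymisation is a
  keyed one-way digest (HMAC-SHA256), so re-identification requires the
  key held by the originating institution. At-rest encryption is
  encrypt-then-MAC (AES-256-CTR + HMAC-SHA256); a wrong key or a single
  flipped byte fails authentication outright. Encryption is optional and
  off in tests: it is a deployment property, not algorithmic content.

## The phantom generator

No clinical data ships with the package; `generate_cohort()` renders
synthetic axial head-CT-like slices instead. Each phantom identity has a
skull-like elliptical annulus (bone intensity), 2–4 air cavities with
smooth random closed outlines (8 radial control points, periodic spline) —
the sinus analogue — whose area follows a smooth per-slice z profile, so
neighbouring slices resemble each other the way real sinus anatomy does
and the ±7.5 mm window is meaningful. A seeded, blurred high-amplitude
texture field stands in for the fine structure of the facial skeleton
(trabecular bone, air cells, teeth): in real head CT the air-to-bone
intensity range compresses soft tissue into a few grey levels after 8-bit
normalisation, and the remaining contrast lives in exactly this kind of
bony detail. Perturbations model the postmortem failure modes: rotation
and translation (unfixed head position), `fov_scale` (whole-body field of
view rendering the head small), additive noise, an injury mask that
erases cavity structure, and partial z coverage.

What the phantoms do **not** emulate: scanner physics (beam hardening,
streaks), anatomically realistic morphology, inter-examination tissue
change, gantry tilt, or contrast media. Passing the synthetic
identification study therefore demonstrates that the pipeline's mechanics
are correct and that individual structure is recoverable under the
modelled perturbations — not that clinical identification rates transfer.

## Problem sizes and numerical conventions

The test suite runs the end-to-end study at desk scale: a 20-identity
cohort (160×160 px slices, 7 slices per series, 2.5 mm spacing) with one
mildly perturbed query per identity (rotation 5°, noise σ = 5 HU), plus a
6-identity cohort for the degradation ordering across none/moderate/severe
perturbation levels averaged over 5 seeds. Quantisation to 8 bits rounds
half away from zero; convolutions use reflect padding (no artificial
border edges, hence no spurious border keypoints); diffusion uses no-flux
boundaries; images smaller than 32 px on a side yield an empty feature set
with a warning rather than an error. Degenerate RANSAC geometry (collinear
correspondences) yields zero matching points with a warning.

## Known limitations

* Exhaustive descriptor search is O(|A|·|B|) per pair; fine at desk scale
  and for single-series queries, slow for archives of tens of thousands
  of slices without indexing.
* The detector is a faithful KAZE-style implementation, but keypoint sets
  are not numerically identical to any other AKAZE build; databases must
  be built and queried with this package (the parameter fingerprint guard
  enforces configuration consistency).
* Only uncompressed single-frame little-endian DICOM is read; enhanced
  multi-frame objects and compressed transfer syntaxes are out of scope.
* FOV-boundary masking (setting out-of-field grey values to air), which
  would suppress false matches along the field-of-view rim, is noted as
  future work.

## A minimal session

```{r example}
library(sinusmatch)

cohort <- generate_cohort(5, slices_per_series = 7, seed = 1,
                          out_dir = "cohort")
db <- build_database(cohort$dirs, key = "site-secret")
save_database(db, "am.cvdb", key = "at-rest-secret")

query <- read_dicom_series(cohort$dirs[2])
res <- run_query_report("am.cvdb", lapply(query, `[[`, "image"),
                        center_slice = 3, strategy = "rank_based",
                        out_csv = "report.csv", seed = 7,
                        db_key = "at-rest-secret",
                        sought = pseudonymize(cohort$metadata$patient_id[2],
                                              "site-secret"))
res$position   # 1-based rank of the sought identity
```
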