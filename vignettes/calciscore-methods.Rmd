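---
title: "Methods: volume-normalized calcification scoring from CTA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: volume-normalized calcification scoring from CTA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Arterial calcification of the abdominal aorta and its major branches is an
established cardiovascular risk marker. On non-contrast CT it is scored by
simple HU thresholding (the Agatston family of scores), but on
contrast-enhanced CT angiography (CTA) the contrast agent raises the lumen
to several hundred HU, so a fixed calcium threshold can engulf the whole
vessel. `calciscore` implements the post-processing and evaluation side of
an automated CTA calcification-scoring workflow: it consumes an artery
label map (1 aorta, 2 iliac, 3 mesenteric, 4 renal) and a binary
calcification mask — in practice produced by segmentation networks, here
also producible synthetically — and turns them into standardized,
volume-normalized burden scores with a full statistical comparison suite.

## The shortening algorithm

Patients differ in how much of each branch a segmentation covers, so raw
branch volumes are not comparable across patients. The shortening algorithm
standardizes geometry before any scoring:

1. Resample the label map to 1 mm isotropic spacing (nearest-neighbour for
   labels, so no new labels can appear).
2. Run connected-component analysis (CCA) on each side-artery label
   (6-connectivity throughout).
3. For each component:
   a. Define its *stump* as the intersection of the component with the
      twice-dilated aortic mask.
   b. Run CCA on the stump; sub-components farther than 2.5 cm from the
      largest sub-component become background; the rest are merged.
   c. Grow the stump by 25 single-voxel dilations, masking each
      intermediate result to the original component before the next
      iteration, then restore the artery label.
4. Cut the aorta 1 cm above the most superior side-artery voxel.

On the 1 mm grid, 25 dilations give the 2.5 cm standard branch length.
Growth is implemented as *iterative* dilate-then-mask rather than one
25-fold dilation masked once: only the iterative (geodesic) form measures
arc length along the vessel, which is what makes a curved branch end at
2.5 cm of vessel rather than 2.5 cm of straight-line distance. The test
suite holds this equal to an independent breadth-first-search distance
oracle on every fixture.

Choices the algorithm statement leaves open, fixed here once:

* **Structuring element.** All dilations use the 6-neighbour cross,
  consistent with the stated CCA connectivity. A 26-neighbour element would
  thicken stumps by up to two voxels at corners; the package exposes
  `connectivity` should that reading be preferred.
* **Islet distance.** "More than 2.5 cm apart" is measured as the minimal
  Euclidean distance between voxel centres of the sub-components on the
  1 mm grid; ties at exactly 2.5 cm are retained. Centre-to-centre and
  surface-to-surface distances differ by under one voxel diagonal, far from
  the decision boundary exercised in the tests (2.0 vs 3.0 cm).
* **Detached components.** A side-artery component that never touches the
  twice-dilated aorta has no stump; it is removed from the output and
  recorded in the provenance log. If *no* component survives, the aorta is
  passed through untruncated (there is no cut plane to define) and
  `truncate_aorta()` itself errors by default when called directly with no
  side arteries.
* **Axis convention.** Array axis 3 is superior-inferior with increasing
  index = superior; "1 cm above" is 10 slices at 1 mm, measured on voxel
  centres.
* **Order.** Components are processed label-then-size descending purely for
  deterministic logs; results are order-independent, and `shorten()` is
  idempotent (tested voxel-for-voxel).

## Threshold baselines

Two baselines bracket what global thresholding can do:

* `optimal_threshold()` — the idealized method: 101 candidate thresholds at
  1% intensity intervals across the ROI (the unshortened ground-truth
  artery region), each scored by Dice against the ground-truth
  calcification; the argmax is returned, ties broken toward the lower
  threshold (favouring sensitivity). Because it reads the ground truth it
  is an upper bound, not a clinical method.
* `apply_threshold()` with the fixed 470 HU constant — the clinically
  realistic method, the mean of per-case optima over a training set
  (`mean_optimal_threshold()`). It never inspects ground truth, and on
  cases whose lumen exceeds 470 HU it floods the whole artery — the failure
  mode `make_high_hu_case()` reproduces.

The candidate grid is interpreted as linear over the ROI's `[min, max]` HU
range; a percentile-spaced alternative is exposed via `strategy =
"percentile"` since the original statement does not fix the spacing rule.
The comparison uses `>=` at the threshold (boundary voxels included).

## Burden scoring

Per artery group, the main score is

\[ \mathrm{burden} = \frac{V_{\mathrm{calc}}}{V_{\mathrm{artery}}} \in [0, 1] \]

computed on the *shortened* label map: the denominator is the group's
standardized segment volume, and the numerator counts calcification voxels
inside that segment. Clusters (6-connected components of the calcification
mask) are assigned to the group with which they share the most voxels
(ties: aorta > iliac > mesenteric > renal; zero-overlap clusters are
discarded and counted). The numerator is then clipped to the group's mask,
which is what makes the `[0, 1]` bound provable rather than empirical. The
combined score pools volumes (`sum calc / sum artery`), so it is dominated
by the aorta and iliacs. Cluster count and mean cluster size (mm³, full
cluster volumes) are reported alongside; mean size × count equals the
group's assigned cluster volume by construction.

The assignment rule itself is a design choice — the source workflow needs
one but does not state it. Majority overlap with clipping was chosen
because it is deterministic, keeps the bound, and matches the stated intent
of normalizing away artery-segmentation variability.

## Agreement statistics

`agreement()` reports, for a ground-truth/predicted score vector pair:
Pearson r and R² (= r² for simple OLS), the OLS regression of prediction on
ground truth, Bland-Altman bias and 95% limits of agreement
(bias ± 1.96·SD of the differences, SD with the n−1 denominator), and a
two-sided paired t-test. Differences are oriented prediction − ground
truth. Degenerate inputs (zero variance, n < 3) yield `NA` rather than
errors so that one flat group cannot sink a batch table.

## The phantom generator

`make_phantom()` emulates the three inputs of a CTA case: a vertical
cylindrical aorta (radius 8 mm) with six straight orthogonal branches
(radius 3 mm, 60 mm long — two iliac, two mesenteric standing in for the
SMA and coeliac trunk, two renal), spherical calcified lesions clipped to
the artery, and three Gaussian intensity bands: background −50 HU, lumen
300 HU, calcification 900 HU, noise SD 20 HU. The bands deliberately
straddle the 470 HU clinical constant from both sides; setting the lumen
to 550 HU (`make_high_hu_case()`) crosses it and reproduces the
fixed-threshold failure. No published intensity statistics exist for the
source cohort, so these are one-time choices at typical CTA magnitudes,
not tuned values.

`make_cohort()` randomizes lesion load (Poisson counts per group, radii
1.5–3.2 mm), branch length (35–55 mm), attachment slice (±3 mm) and a
case-level lumen shift (SD 40 HU), and records a truth table computed by
`construction_truth()` — an independent geometric rule (branch kept up to
stump-depth + 25 voxels of axial projection from the aortic surface; aorta
kept to 10 slices above the highest kept branch voxel) that never calls
the shortening code. Lesions are placed within the first ~22 mm of each
branch so they always survive shortening; pipeline and truth calcified
volumes therefore agree exactly, and artery volumes agree up to a
one-voxel rim where the cylindrical surface meets the discrete dilation
front.

What the phantom does **not** emulate: partial-volume blur, beam
hardening, anisotropic acquisition, aneurysmal or stenotic morphology,
vessel tapering, and contiguous soft-tissue background. A green cohort
test therefore establishes the correctness of the *post-processing and
scoring arithmetic*, not segmentation performance on clinical images.

## Numerical conventions

* Voxel `i` spans physical `((i-1)s, i·s]`; its centre is `(i-0.5)s`.
  Resampling maps output voxel centres into input index space; the output
  grid is anchored at the input origin with shape `ceil(extent/target)`.
* Empty-vs-empty mask comparisons return all metrics = 1 with an
  `empty_both` flag (needed for calcification-free groups); a single empty
  mask gives Dice/Jaccard 0 and `NaN` for the ratio whose denominator
  vanished.
* A group with zero artery volume reports `NA` burden, never 0 — absence
  of vessel is not absence of disease.
* NIfTI-1 I/O is implemented in-package (no R NIfTI reader is available in
  the target environment): single-file `.nii`/`.nii.gz`, the common scalar
  datatypes, `scl_slope`/`scl_inter`, and axis-aligned sforms. Non-axis-
  aligned affines are rejected rather than silently reoriented. Round-trips
  are exact for label maps and float32-precision for HU volumes, and are
  cross-validated against an independent reader.

## Limitations

* The resampler assumes axis-aligned volumes; oblique acquisitions must be
  reoriented upstream.
* `construction_truth()` supports straight branches only; curved branches
  are available for geodesic-growth testing but not for cohort truth.
* Cluster counts/sizes are known to be less stable than the volume ratio
  (merging of adjacent lesions under 6-connectivity); the burden score is
  the primary endpoint here as in the source workflow.
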