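---
title: "Diameter-based estimation of ischemic lesion volume: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diameter-based estimation of ischemic lesion volume: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokevol)
```

## The measurement problem

Large initial lesion volume on diffusion-weighted imaging (DWI) is a common
exclusion criterion in acute stroke trials: infarcts above 70 ml or 100 ml
carry a worse prognosis and a higher risk of hemorrhagic transformation
under reperfusion therapy. The gold standard — manual delineation of the
infarct border on every slice, with volume obtained as voxel count times
voxel volume — is too slow for hyperacute triage. Two rapid surrogates need
only a ruler:

* **od-value.** On the slice showing the largest lesion extent, the reader
  draws the maximum lesion diameter $a$ and the maximal diameter $b$
  perpendicular to it (both in cm). Their product $od = a \times b$ is used
  two ways: directly against the cutoffs $od \ge 32$ (for >70 ml) and
  $od \ge 42$ (for >100 ml), and through the calibration polynomial
  $V_{od} = 1.1\,od + 0.03\,od^2$ ml, fitted previously on real infarcts.
  The polynomial is strictly increasing, so the cutoff rule is equivalent to
  thresholding $V_{od}$ at $V_{od}(32) = 65.92$ ml and
  $V_{od}(42) = 99.12$ ml — within 6% and 1% of the volumes being screened
  for, which is what makes the cutoffs work.
* **ABC/2.** The classical ellipsoid approximation
  $V_{ABC/2} = a \cdot b \cdot C / 2$, where $C$ is the cranio-caudal
  extent: the number of lesion-bearing slices times the slice thickness
  (cm). For a true ellipsoid with orthogonal full axes $A, B, C$ the exact
  volume is $\pi ABC/6 \approx 0.52\,ABC$, so the $/2$ slightly
  *under*-reports an ellipsoid (factor $3/\pi \approx 0.95$); on real,
  non-convex infarcts the diameter envelope overshoots the delineated
  volume by far more, and ABC/2 is documented to overestimate by up to
  about 30%.

This package implements both estimators, the caliper geometry behind them,
gold-standard voxel volumetry, and the diagnostic-accuracy evaluation
(sensitivity, specificity, accuracy, PPV, NPV with exact binomial CIs, the
rank-based C-statistic, and percent overestimation of the median volume),
plus a synthetic lesion-phantom generator so the whole chain is testable
against analytic ground truth.

## Caliper geometry on a voxel grid

All geometry is carried out in physical millimetres: anisotropic in-plane
spacing is applied to pixel indices *before* any hull or projection, and
results are reported in centimetres. Masks are `[row, col, slice]` arrays
with voxel-center physical coordinates and 1-based slice indices.

**Point set.** Each lesion pixel contributes its four corners. This
emulates an edge-to-edge electronic caliper: a single pixel has a positive
diameter (its diagonal), and a measured diameter spans the rendered lesion
boundary, not the centers of its border pixels. The corner convention
implies a small systematic overshoot relative to the underlying continuous
shape — about one in-plane pixel per diameter, direction-dependent up to
one pixel diagonal — which is visible in the phantom recovery results below.

**Maximum diameter $a$.** The maximum Feret (caliper) diameter: the largest
pairwise distance over the corner point set, computed exactly as convex
hull followed by the maximum over hull-vertex pairs. Only corners of
4-connected boundary pixels are expanded, which changes nothing (interior
pixels cannot support the hull) but keeps the point set small. A
brute-force all-pairs implementation (`feret_diameter_brute()`) is kept as
a reference path and is tested to agree exactly.

**Orthogonal diameter $b$.** The width of the projection of the corner
point set onto the axis perpendicular to $a$'s direction. Published
descriptions do not fix whether $b$ must intersect $a$; the projected-width
reading matches electronic-caliper practice and guarantees $b \le a$ by
Feret maximality (the implementation still asserts this). Disconnected
lesion fragments on a slice are measured as one point set — a reader spans
the full hyperintense region.

**Slice selection.** The per-slice maximum Feret diameter is computed for
every nonempty slice and the maximizing slice is selected, ties breaking to
the lowest index for determinism. $b$ is then measured on that same slice.
Slice count $C/\text{thickness}$ counts slices with at least one lesion
voxel; gaps are not interpolated. Slice thickness is read from the NIfTI
header (treated as center-to-center spacing) and can be overridden when a
catalog stores it separately.

## The synthetic phantom cohort

No real cohort images are distributable, so the generator produces 3D
phantoms whose ground truth is known analytically, emulating the reference
cohort's printed summary statistics:

* **Volume law.** True (envelope) volumes are log-normal, fitted by least
  squares to the 25th/50th/75th percentiles in log space so that the
  defaults reproduce a median of 26 ml with IQR 10.7–62.2 ml. Volumes are
  truncated to [0.5, 400] ml to keep phantoms clinically plausible. Fitted
  this way, `sdlog` ≈ 1.30 — a heavily right-skewed law, so cohort medians
  at n = 100 still fluctuate by several ml.
* **Shape.** Each lesion is an ellipsoid with major semi-axis $p$, in-plane
  minor ratio drawn from [0.4, 0.95], and through-plane ratio from
  [0.5, 1.1]; the through-plane range was set so that the median lesion
  spans roughly 8–11 slices, matching the reference cohort's median of 8
  (IQR 6–11) slices with restricted diffusion. Orientation is a random
  in-plane rotation: keeping the slice axis aligned leaves the equatorial
  cross-section analytic (in-plane full axes $2p$ and $2p u_1$), which is
  what parameter-recovery tests compare against. Full 3D Euler orientations
  are supported by the rasterizer for sensitivity work.
* **Irregularity.** A fraction (default 70%) of lesions get two surface
  perturbations, frozen into the spec at sampling time so rasterization is
  a pure function. *Roughness* multiplies the radial surface by
  $1 + \rho\,g(u)$ with $g$ a random combination of degree-2/3 Legendre
  modes — smooth, mean-zero over the sphere, so expected volume is
  preserved to first order. *Concavity* subtracts localized quadratic bites
  (four caps of 60° half-angle, depth scale drawn from [0.35, 0.65]),
  strictly inward. The depth default was derived analytically so that bites
  remove roughly 25–30% of the convex-envelope volume, the magnitude of
  envelope overestimation documented for real infarcts; it is the mechanism
  by which the cohort reproduces ABC/2's positive bias direction. Because
  the sampled log-normal volume is the *envelope* volume, the delineated
  (voxel) volume of a concave phantom falls below it by design, and the
  realized manual-volume median sits a few ml under the envelope target.
* **Rasterization.** A voxel is lesion iff its center lies inside the
  perturbed surface — the center-point test matching binary manual
  delineation (no partial volume). Grids default to 1 mm in-plane (the
  reference protocol's in-plane resolution is unpublished; this is an
  assumption exposed in the config) with per-patient slice thickness drawn
  from {2.5, 3, 4, 5} mm, sized automatically from the semi-axes plus the
  field's outward bound; a lesion touching the grid boundary is an error,
  never a silent truncation.

What the phantoms do *not* emulate: DWI intensities (masks only),
multifocal lesions, partial-volume effects at the lesion border, and the
gyral, territory-shaped geometry of real MCA infarcts. Passing tests
therefore demonstrate correctness of the measurement and evaluation
machinery and qualitative reproduction of shape-driven biases — not
quantitative transfer of accuracy figures to clinical data.

## Evaluation choices

* **Confidence intervals.** Exact Clopper–Pearson at 95% by default (the
  conservative standard for diagnostic studies), Wilson score as an
  alternative. Reconstructed intervals for the reference table agree with
  the printed ones to within rounding of the CI method, but are not
  asserted equal since the original CI procedure is unstated.
* **C-statistic.** Computed from midranks, which equals the pairwise
  definition $P(s_+ > s_-) + \tfrac12 P(s_+ = s_-)$ exactly, ties included;
  a brute-force pairwise oracle checks this on small inputs. Undefined
  (error) when only one class is present. Because the published C-statistics
  do not state which outcome or score they refer to, the evaluation reports
  all four score-by-threshold combinations rather than asserting one.
* **Classification strictness.** Ground truth and the ABC/2 rule use the
  strict comparison (`> 70 ml`, `> 100 ml`, as the thresholds are written);
  the od cutoff uses `>=` so that an od-value of exactly 32 or 42 counts as
  large — documented and configurable (`od_cutoff_inclusive`).
* **Marginal reconstruction.** With n = 238 and 49/37 positives, one-decimal
  sensitivity and specificity determine the integer `tp` and `tn` uniquely;
  the reconstructor searches all integer counts and errors on ambiguity.
  Reported percentages use round-half-away-from-zero, which is what the
  printed table uses (81.25 → 81.3).
* **Exclusions.** Patients with empty masks are flagged and excluded from
  evaluation with a recorded reason; the run manifest always satisfies
  `n_input = n_evaluated + n_excluded`.

## Problem sizes and numerical tolerances

The test suite and the acceptance workflow run the cohort analyses at
n = 238 (mixed shapes), n = 200 (concave cohort) and n = 100 (ellipsoid
recovery cohort), with phantom grids of order $10^5$–$10^6$ voxels —
sizes at which rasterization error is a fraction of a percent of analytic
volume (a 20 mm digital sphere at 1 mm isotropic is within 2% of
$\tfrac43\pi r^3$) while a full cohort still simulates and measures in well
under a minute. Geometric comparisons against analytic phantom axes use
tolerances of one to two pixel diagonals, the inherent scale of corner-set
digitization; exact-arithmetic identities (estimator formulas, hull vs
brute-force Feret, rank vs pairwise AUC) are tested to 1e-12.

## Known limitations

* The corner-convention overshoot means measured diameters on digitized
  phantoms run ~1 in-plane pixel above the generating continuous axes; at
  1 mm resolution roughly 95% of ellipsoid phantoms recover both axes
  within one pixel diagonal, with the remainder driven by the
  direction-dependent inflation of $b$.
* The od-to-volume polynomial and the 32/42 cutoffs are taken as given
  (they were calibrated on real infarct cohorts); no re-fitting is done,
  and their bias on phantoms reflects the phantoms' shape family, not the
  calibration cohort's.
* Accuracy figures computed on phantoms are systematically higher than on
  clinical data because phantom shape variability is narrower than real
  infarct morphology; the package's clinical claims are limited to the
  reconstruction of the published table from its marginals.
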