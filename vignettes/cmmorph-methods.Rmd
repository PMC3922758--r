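---
title: "Methods: landmark-based CM/SM morphometry in cmmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landmark-based CM/SM morphometry in cmmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmmorph)
```

`cmmorph` quantifies the conformation of the canine caudal cranial fossa and
craniocervical junction from a single midsagittal T1-weighted MRI slice. This
vignette is the package's own account of the model, the choices made where
the method leaves room, and what the synthetic-data tests do and do not show.

## Coordinate convention

All geometry lives in the 2-D midsagittal plane: x increases rostrally, y
increases dorsally, units are millimetres. "Most dorsal" always means maximal
y. Input files record coordinates in this frame; every line and angle output
is invariant under rigid motion, and angles also under uniform scaling, so
the convention matters only for the dorsal/ventral tie rules below.

## The measurement framework

Six landmarks are annotated per dog — A (dorsum of the spheno-occipital
synchondrosis), B (basion), C (rostral edge of the dorsal lamina of the
atlas), D (junction of supraoccipital bone and occipital crest), G (point
where the optic nerve deviates into its canal) and H (most caudal point of
the olfactory bulb) — together with polyline contours of the dorsal occipital
lobes and the dorsal cerebellum. A and H are required; any other landmark may
be absent, in which case only the variables that reference it are reported
missing (`NA`), never zero.

Three points are derived:

- **F**, the centre of the occipital-lobe circle. The criterion is the
  *minimum enclosing circle with centre constrained to the cranial base line*
  (the line through H and A, extended): the smallest circle centred on that
  line containing every occipital-contour vertex. The enclosing radius as a
  function of the centre position t is a maximum of convex functions, hence
  convex and unimodal, and the optimal projection lies inside the range of
  vertex projections; golden-section search on that bracket converges to
  |Δt| < 1e−9 mm. This criterion is unique and reproducible, and its diameter
  (the **F-diameter**) reflects the height of the rostral cranial cavity even
  when the rostral skull is outside the field of view.
- **E**, the most dorsal intersection of the cerebellar contour with the
  circle, from the per-segment quadratic; ties on y break toward larger x.
  Tangency counts. If the contour misses the circle entirely, a classed
  condition (`cmmorph_no_E`) carries the miss distance and the E-dependent
  variables become missing.
- **I**, where the circle meets the extended base line. Two intersections
  always exist (F is on the line); the package uses F − r·d (d the unit
  vector from H towards A) by default. The anatomical definition fixes only
  that I lies on the extended line, so the opposite intersection is available
  via `derive_point_I(..., which = "far")`.

The ten-line set is configurable. Seven lines are directly attested in the
framework (F-diameter, AB, AE, AH, BC, BD, FG); the default completes the
set with AC, AD and AI. Five angles are fixed: 1 = ABC, 2 = CAF, 3 = AID,
4 = AGH, 5 = AFG (vertex in the middle). Enclosure is evaluated at contour
*vertices* only — annotation density is the annotator's responsibility and
segments are not subdivided.

Numerical tolerances: golden-section at 1e−9 mm (so forward-constructed
geometries round-trip to well below 1e−6), geometric invariant checks at
1e−9, quadratic-discriminant tangency at 1e−9.

## Grading and cohort rules

SM grading follows the 2-mm transverse-diameter scheme: grade 0 no finding;
grade 1 a central canal dilation/syrinx under 2 mm or a pre-syrinx alone;
grade 2 a dilation/syrinx of 2 mm or more, or a pre-syrinx *with* central
canal dilation. The scheme's wording leaves the pre-syrinx-plus-narrow-
dilation combination ambiguous; `sm_grade()` grades it 2 because the scheme
lists that combination under syringomyelia proper, and this is flagged in
the function documentation. Age codes resolve the overlapping verbal
brackets as c = [1, 3), b = [3, 5], a = (5, ∞), matching "more than five".
CM grade is observer-assigned input; there is no numeric CM criterion to
compute.

The SM cohort rule: grade-0 dogs under exactly 3.0 years are excluded
(late-onset disease makes their clear status unreliable); grade-1 and
grade-2 dogs enter regardless of age; grade 2 is `SM_YES`, everything else
retained is `SM_NO`. Records missing grade or age are excluded with reason
`"missing metadata"`. Counts are conserved by construction and asserted.

## Discriminant analysis

Candidate variables are screened by classical one-way ANOVA (delegated to
`stats::lm`; no multiple-testing correction is applied across the 15
variables, deliberately mirroring standard practice for this screening
step). The stepwise canonical discriminant analysis uses Wilks'-lambda
partial-F entry and removal with the classic thresholds F-to-enter = 3.84
and F-to-remove = 2.71 — the era's statistical-package defaults; both are
arguments. Listwise deletion over the candidate set is applied once per
analysis and the dropped count is reported.

On the selected variables the within-to-between eigenproblem is solved via a
Cholesky reduction to a symmetric eigenproblem; coefficient vectors are
scaled so discriminant scores have pooled within-group variance exactly 1,
constants are −aᵀx̄ (grand mean over used cases), functions are ordered by
eigenvalue, and each function's significance is Bartlett's chi-square
approximation. The sign of each function is fixed by making its
largest-magnitude coefficient positive (a pure reporting convention; set
`sign_convention = "none"` to keep the raw eigenvectors).

Classification is nearest-centroid in discriminant-score space, which —
because the score space contains all centroid differences and has identity
pooled within-covariance — equals the full Mahalanobis rule; equal priors by
default (proportional available), exact ties to the lowest group index.
Leave-one-out cross-validation refits the *coefficients* without each record
but keeps the variable set from the full-data stepwise fit, the standard
behaviour of classical discriminant software; `strict_selection = TRUE`
redoes selection per fold for sensitivity analysis.

## ROC and cutoff analysis

The ROC is the empirical curve over all distinct thresholds; AUC by
trapezoid, which on that curve equals the rank statistic (concordant pairs
plus half ties), and the AUC p-value is the tie-corrected normal
approximation to the Mann–Whitney statistic (documented as approximate).
A score equal to the cutoff counts as positive. The cutoff grid runs in
0.1-mm steps from a 42.5-mm anchor (a first estimate from group mean
differences) extended to span the data; the reported optimum maximises
Youden's J by default, with the balanced (|sens − spec| minimising) optimum
always reported alongside because "optimal" is criterion-dependent.
Predictive values with empty denominators are `NA`, never 0.

## Reliability

`icc_2_1()` is the two-way random-effects, absolute-agreement,
single-measure ICC (Shrout–Fleiss (2,1)), computed from the two-way mean
squares, with the F-based Shrout–Fleiss 95% interval using a Satterthwaite
denominator df. The absolute-agreement form is the correct choice for
intra-measurer agreement on physical measurements, where a systematic shift
between sessions is real disagreement. Degenerate inputs (zero total
variance) yield an explicit "undefined" result rather than 0 or 1.

## Synthetic data: what it emulates, and what it does not

`gen_landmark_geometry()` is a forward construction: the base line is placed
(and, under jitter, perturbed) first, the circle centre and radius are then
defined *relative to the jittered frame*, the occipital contour is emitted
as vertices on that circle symmetric about the dorsal normal through F, and
C and G are placed in closed form so angles 2 and 5 hit their targets
exactly. The construction is therefore its own oracle: at zero jitter the
geometry module must recover the targets to 1e−6. Under jitter, contour
vertices slide tangentially along the ideal boundary; independent radial
noise on these extreme points would bias the enclosing-circle fit upward by
the expected maximum of the radial errors — a property of annotation noise,
not of the fit — and would make mean-recovery checks test the noise model
rather than the geometry.

`gen_measurement_table()` draws multivariate-normal measurement vectors per
group (non-conforming rows are redrawn), and `gen_study_table()` fixes the
study-shaped margins: 155 dogs, CM groups 31/32/92, SM grades 55/33/67 with
exactly 20 grade-0 dogs under three years, plus light missingness (five dogs
without the optic-canal variables fg/angle4/angle5, eleven without line AH).
Group mean shifts for the five informative variables are anchored on the 14
printed example dogs; the standard deviations (4.5 mm for the F-diameter,
2.5 mm for other lines, 7° for angles) were chosen once as realistic for
small-breed craniometry, where point-to-point distances vary substantially
with head size. These defaults are *illustrative*, not population
parameters: the synthetic population is Gaussian within group, has no
breed/scanner/rater structure, no correlated measurement error, and its
group separations are cleaner than clinical data. Passing recovery tests on
it therefore demonstrates correctness of the estimators, not expected
performance on real screening cohorts.

`gen_rater_data()` simulates y_ij = μ + s_i + r_j + e_ij with the subject
variance solved from the requested population ICC (rater SD fixed at 30% of
the error SD by default, scale anchored on a line-AE-like measurement).

## Problem sizes

The test suite runs the geometry-versus-grid-oracle comparison on 100 random
contours at a 1e−4-mm grid, discriminant recovery at 500 cases per group,
ROC convergence at 5 000 cases per class, and ICC recovery over 500
replicates of a 10 × 2 design; the full suite and the acceptance script each
complete in well under a minute on one CPU.

## Limitations

- The ten-line set is only partly attested; AC/AD/AI are package defaults
  and configurable.
- Point I's anatomical definition is under-determined; the choice is
  isolated behind an argument.
- Enclosure at vertices only: sparse contours can under-estimate the
  F-diameter.
- The stepwise thresholds, priors and LOOCV-without-reselection mode are
  conventions of classical discriminant software; alternative settings can
  change which variables enter on borderline data.
- XLSX input is not read directly; tables are consumed as CSV/TSV with a
  documented column layout.
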