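---
title: "Landmark and semilandmark morphometrics of molar outlines: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark and semilandmark morphometrics of molar outlines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molargm)
```

## The problem

Reindeer in Fennoscandia comprise two interbreeding subspecies — mountain
reindeer (*Rangifer tarandus tarandus*, including all domestic herds) and
wild forest reindeer (*R. t. fennicus*) — and telling them apart from
isolated archaeological teeth is a prerequisite for tracing the history of
Sámi reindeer herding. The occlusal outline of the lower molars carries a
taxonomic signal, but reindeer teeth are brachyodont: the enamel-dentine
junction that is digitised changes strongly as the tooth wears, and wear
also increases centroid size. Any analysis therefore has to be stratified
by tooth (m1/m2) and by ordinal wear class, with the under- and over-worn
extremes excluded because the landmark protocol cannot be applied to them
(classes 1–3 are analysable for m1, 1–2 for m2).

`molargm` implements the full analysis chain for this setting: TPS-file
input, Generalized Procrustes Analysis (GPA) with bending-energy sliding of
semilandmarks, tangent-space PCA, permutation-based shape variance
decomposition, size tests, allometry regression, canonical variate analysis
(CVA) with leave-one-out (LOO) cross-validation, neighbour-joining
phenograms from Mahalanobis distances, and linear discriminant assignment of
archaeological unknowns. A synthetic-data generator with known ground truth
stands in for the (unpublished) specimen data and drives the validation
suite.

## The superimposition model

Each specimen is a configuration of K = 75 points: 9 fixed landmarks at
curvature extrema of the enamel-dentine junction and 66 sliding
semilandmarks distributed along the 9 outline segments between them. The
per-segment allocation is configurable (`semilandmark_allocation()`);
by default the split is as equal as possible with the remainder given to the
longest segments by template arc length, since no canonical allocation
exists for this protocol.

GPA (`gpa()`) translates every configuration to a common centroid, scales it
to exactly unit centroid size, and iteratively rotates it to the consensus
(the normalised mean shape) until the consensus moves less than `tol`
(default 1e-6, maximum 100 iterations). Two modelling choices deserve
mention:

* **Unit-size normalisation, rotation-only fitting.** Every aligned shape
  has centroid size exactly 1; no per-specimen scale is fitted against the
  consensus. This keeps size strictly in the centroid-size variable and
  makes the aligned-shape invariants exact.
* **No reflections.** Molars are chiral; the optimal rotation is constrained
  to determinant +1. Mirroring a left to a right tooth must be an explicit
  data-preparation step, never a silent alignment choice.

### Sliding semilandmarks

Semilandmarks have no point-wise homology along the outline, so during
superimposition they are allowed to slide along their local tangent to
minimise the bending energy of the thin-plate spline (TPS) from the
consensus to the specimen. The bending energy is the quadratic form
`E(d) = d_x' B d_x + d_y' B d_y` where `B` is the K×K bending-energy matrix
of the consensus (kernel `U(r) = r² log r²`); `B` annihilates affine
displacement fields, so sliding only penalises genuine bending. All sliding
amplitudes are solved jointly from one linear system — the exact minimiser
of the quadratic restricted to tangential motion — so the energy can never
increase (`slide_semilandmarks()`).

Two numerical choices stabilise the outer iteration (slide → re-estimate
consensus → re-align, default 5 cycles or tolerance 1e-6):

* **Tangents are evaluated on the consensus inside `gpa()`.** If each
  specimen used its own outline chords, sliding against a re-estimated
  consensus would have a flat direction — a common slide of all specimens
  moves the consensus identically and changes no bending energy — and the
  iteration drifts slowly along the outline instead of converging. With
  consensus tangents the slide step is one common linear projection: the
  mean sliding displacement is exactly zero, the consensus cannot drift, and
  re-sliding an already-slid specimen is a no-op, so the iteration has a
  genuine fixed point. The standalone `slide_semilandmarks()` op defaults to
  the configuration's own chords (the more natural reading for a single
  pair of shapes) and accepts precomputed tangents.
* **Sliding is history-free.** Each cycle re-slides from the specimen's
  original digitised positions rather than compounding earlier slides. The
  converged shapes are then a deterministic function of the data and the
  final consensus — the same function `project_unknowns()` applies to
  archaeological specimens, which is what makes a training specimen project
  exactly onto its own scores.

An optional `tangent_mode = "projected_curve"` re-projects slid points onto
the piecewise-linear outline of the configuration (off by default: pure
linearised sliding).

## Statistics on shape

Aligned shapes are projected orthogonally onto the tangent space at the
consensus before any covariance-based statistic (`shape_matrix()`), the
standard small-variation treatment.

* **PCA** (`pca_shapes()`): components ordered by eigenvalue, sign fixed so
  the largest-magnitude loading is positive. `reconstruct_shape()` deforms
  the mean shape along a component, the usual visualisation of what a PC
  axis means anatomically.
* **Variance decomposition** (`variance_decomposition()`): the "% of shape
  variation explained" by wear, tooth, population or sex is a sequential
  (Type I) sum-of-squares decomposition of the Procrustes coordinates
  (Goodall-style), with the interaction last; significance by
  permutation of reduced-model residuals (Freedman–Lane) under a mandatory
  seed. This is implemented directly (and cross-checked against
  `vegan::adonis2` in the test suite) because the quantity reported is an
  SS share, not a Wilks statistic; a parametric MANOVA on retained PC scores
  (`manova_scores()`) is provided as a secondary route.
* **Size** (`size_tests()`): one-way ANOVA on log centroid size at the
  conventional 5% threshold, pairwise Wilcoxon rank-sum tests (exact when
  both groups have ≤ 25 members and no ties, mid-rank normal approximation
  with continuity correction otherwise) and Benjamini–Hochberg correction
  across all pairs.
* **Allometry** (`allometry_regression()`): multivariate regression of all
  shape variables on log centroid size; `R²` is the explained share of total
  shape variance and p comes from permuting sizes against shapes.

## Classification and phenograms

Before any CVA the score space is reduced to the smallest leading set of
components holding 95% of total variance (`retain_components()`), so that
near-null directions do not distort the cross-validated accuracy. `cva_fit()`
solves the between/within generalized eigenproblem (at most g−1 axes) and
reports Mahalanobis distances between group means under the pooled
within-group covariance; an ill-conditioned pooled covariance (condition
number above 1e10) is shrunk toward its diagonal with weight 1e-8, with a
warning. `loo_cross_validate()` refits the pooled-covariance linear
discriminant for every held-out specimen; priors are equal by default
(archaeological base rates are unknown), with a proportional option.

GPA and PCA are fitted once on the full training sample and only the
discriminant is refit per fold. This mirrors common geometric-morphometrics
practice but does leak alignment information across folds; the package
exposes all the pieces needed to refit the ordination per fold when a
stricter protocol is wanted.

Archaeological unknowns are projected into the modern shape space
(`project_unknowns()`): ordinary Procrustes alignment to the consensus,
the same sliding projection as training, tangent projection, then the
retained eigenvectors. Unknowns never influence the consensus or the
eigenvectors. `classify_unknowns()` returns posterior probabilities and
maximum-posterior assignments (ties flagged and broken toward the first
label in sorted order); `summarize_assignments()` tabulates counts and
percentages per site and tooth, keeping raw percentages alongside rounded
display values.

`neighbor_joining()` builds the phenogram from the Mahalanobis matrix with
the standard Saitou–Nei algorithm; ties in the Q-criterion break toward the
lowest index pair in sorted-label order, so trees are reproducible. Negative
branch-length estimates (possible on non-additive Mahalanobis input) are
clamped to zero for display with the raw values retained in the
`branch_log`. `write_newick()` quotes labels containing spaces.

## The synthetic-data generator

`simulation_design()` + `simulate_dataset()` emulate the structure the
analyses assume, with every magnitude in Procrustes units relative to a
unit-centroid-size template (`make_template()`, a bilobed molar-like closed
outline with landmarks at deterministic positions):

* wear is the dominant shape deformation (class magnitudes 0, 0.025, 0.05
  for classes 1–3) and multiplies centroid size up the wear ladder
  (factors 1.00, 1.04, 1.08) — worn brachyodont teeth expose a larger
  enamel-dentine junction;
* the two subspecies differ by a smaller mean-shape offset (±0.015 on a
  common axis) and forest reindeer are larger (base sizes 21 vs 19 mm);
* sex effects are weak (shape 0.002, size factor 1.03 for males);
* allometry is off by default (the analyses treat shape and size as
  uncoupled within wear classes);
* digitising noise is isotropic Gaussian per landmark (sd 0.0015), with an
  optional tangential-only mode for semilandmarks;
* individual size scatter is log-normal (cv 0.03).

These defaults are the package's fixed reference conditions: they produce
the qualitative structure the pipeline must recover (wear ≻ subspecies ≻
sex in explained variance, forest > mountain in size) at sample sizes a
museum study can reach. Effect directions are drawn orthogonal to the
similarity subspace of the template (translations, scaling, rotation) and
to each other, so planted effects can be neither created nor removed by the
superimposition — a requirement for honest parameter-recovery tests. Every
specimen receives a random rotation and translation so that alignment is
genuinely exercised, and a fixed seed makes the dataset byte-identical
across runs.

What the generator does *not* emulate: digitising error that is correlated
along the outline, missing or broken outline segments, operator effects,
between-population covariance structure beyond mean shifts, and measurement
units lost to scale-less archaeological photographs. Passing recovery tests
on synthetic data therefore validates the estimators under the stated
model, not the biological claims on any real assemblage.

## Validation scales and numerical conventions

The test suite and the acceptance script exercise the pipeline at sizes
chosen to keep a full run in minutes on one core while leaving the checks
statistically meaningful: oracle comparisons use 4–10 point toy shapes;
score-space classification checks use two groups of 100 with a planted
Mahalanobis separation of 2 over 50 seeds (expected LOO accuracy
100·Φ(1) ≈ 84.1%); variance-fraction recovery plants a 30% wear share at
n = 200 with the full 75-point protocol over 20 seeds; the null-allometry
calibration uses 200 seeds of 20 specimens on an 8-point template. The
planted-separation check is run in score space deliberately: with
isotropic full-rank digitising noise at K = 75, retaining 95% of variance
keeps on the order of a hundred near-noise components, and a plug-in linear
discriminant at n = 200 then sits measurably below the analytic two-class
error for estimation-dimensionality reasons that are well understood but
are not what the check is probing; a full-pipeline variant runs at a
smaller landmark protocol where the analytic error applies.

Other conventions: permutation p-values are `(1 + exceedances)/(n_perm + 1)`
and can never fall below `1/(n_perm + 1)`; all permutation routines take a
mandatory seed and restore the caller's RNG state; GPA convergence is
declared on the Frobenius displacement of the consensus; the final
superimposition is rotated to the consensus' principal axes with a
deterministic sign so results do not depend on specimen input order;
degenerate configurations (all points coincident), coincident TPS reference
points, and zero-length sliding tangents are hard errors naming the
offending specimen or point.

## Known limitations

* Linearised sliding can in principle move a semilandmark off its segment
  for very large deformations; the `projected_curve` mode bounds this but
  is not the default.
* The wear classes are modelled as a single deformation direction with
  class-specific magnitudes; real wear is more heterogeneous.
* LOO cross-validation shares the superimposition and ordination across
  folds (see above).
* TPS `CURVES=`/`POINTS=` records are not parsed; export flat landmark
  lists.
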