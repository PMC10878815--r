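---
title: "Methods: phylogenetic geometric morphometrics with quadmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic geometric morphometrics with quadmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

quadmorph implements the inference chain used to study macroevolutionary
drivers of shape in densely landmarked skeletal elements — the motivating
system is the avian quadrate, the bone that couples the mandible, palate
and jugal bar in the kinetic bird skull. The chain runs from raw landmark
constellations to Procrustes-aligned shapes, shape ordination,
lambda-rescaled phylogenetic regression, phylogenetic two-block partial
least squares, and landmark-scheme validation, together with a synthetic
shape-evolution generator that makes every stage testable without any
external data. This vignette explains the models, the tunable parameters,
the numerical choices, and what the synthetic tests do and do not show
about real data.

## Landmark model and superimposition

A *template* (`landmark_template()`, `make_template()`) describes the
landmarking scheme: fixed (discrete) landmarks, ordered runs of curve
semi-landmarks anchored on fixed points, patches of surface
semi-landmarks, and a partition of every point into one of six named
quadrate regions (otic process, orbital process + basiorbital fossa,
quadrate body, quadratojugal cotyle, mandibular process, pterygoid
condyle). The dense default scheme has 8 fixed + 509 curve + 797 surface
points; all counts are configurable, and the desk-scale analyses in the
tests use 8 + 60 + 60.

`gpa()` performs partial-Procrustes superimposition: translate each
configuration to the origin, scale to unit centroid size (sizes are
recorded first, in mm), and iteratively rotate onto the running consensus
with the optimal rotation constrained to determinant +1 — reflections are
disallowed because biological handedness is meaningful. Iteration stops
when the summed squared distance to the consensus changes by less than
1e-8 (cap 100 iterations, with a warning and a `converged` flag).

Because the iterative alignment is only defined up to a global rotation,
the final alignment is rotated to a canonical frame: the principal axes of
the consensus, with the sign of each of the first two axes chosen so the
largest-magnitude projected coordinate is positive and the third axis
completing a right-handed frame. The sign rule is computed from the
rotated data, not from eigenvector entries, which makes the output
invariant (to ~1e-12 in practice, 1e-9 asserted) under arbitrary
rotation, translation and scaling of the input configurations.

## Sliding semi-landmarks by minimum bending energy

Semi-landmarks have no point-for-point anatomical homology, so their
tangential position is treated as a nuisance parameter. Curve points slide
along the normalized chord between their two polyline neighbours; surface
points slide in the plane spanned by the first two principal axes of their
8 nearest neighbours in the consensus. The slide magnitudes minimize the
thin-plate-spline bending energy of the consensus-to-specimen deformation;
with the bending-energy matrix computed from the consensus this minimizer
has a closed form (a generalized-least-squares solve), which the tests
verify against a brute-force numerical optimizer on a small toy.

The 3-D thin-plate spline uses the kernel U(r) = −r, which is
conditionally positive definite of order one, so the bending-energy
quadratic form is positive semi-definite with the affine maps as its null
space; affine deformations cost exactly zero energy.

Two numerical choices matter here:

* **Re-projection with backtracking.** After sliding, curve points are
  projected back onto the specimen's original resampled polyline and
  surface points onto the plane through their 8-neighbour centroid, so
  points cannot drift off the anatomy. Projection is not energy-aware, so
  the slide vector is halved (up to 9 times) until the projected
  configuration does not increase bending energy; a fully backtracked
  point stays put. This guarantees the bending energy of the
  consensus-to-specimen deformation is non-increasing within and across
  sliding rounds, which the acceptance tests assert.
* **Degenerate tangents.** If slid points become coincident with their
  polyline neighbours, the tangent chord is undefined and the point simply
  does not slide in that round.

Sliding is toward the consensus, recomputed each outer round (5 rounds by
default, interleaved with re-superimposition), not toward a fixed
reference. A singular slide system is ridge-regularized (1e-8 on the
diagonal) with a warning. Bending energy is applied to all sliding points;
a per-point criterion switch is not implemented because the minimum
Procrustes-distance alternative was never needed in the analyses this
package supports.

## Shape space

`shape_pca()` eigendecomposes the covariance of the flattened aligned
coordinates (divisor n − 1, via SVD); axes are ordered by decreasing
eigenvalue and signed so each loading's largest-magnitude entry is
positive. Full score-space Euclidean distances equal Procrustes distances.
`warp_along_axis()` predicts the configuration at an empirical score
quantile (type-7 interpolation — the conventional R default; the choice
only matters at desk-scale n) and returns the thin-plate-spline map from
the mean shape, applicable to auxiliary points such as mesh vertices;
rendering itself is out of scope. `per_landmark_variance()` reports each
landmark's mean squared deviation from the consensus, raw and
log10-transformed with a floor of 1e-20 so invariant landmarks stay
finite. `phylomorphospace_scores()` reconstructs ancestral scores in
closed form under Brownian motion (equivalently, weighted squared-change
parsimony), handling polytomies directly; the implementation is verified
against an independent maximum-likelihood reconstruction.

## Phylogenetic regression (the PGLS engine)

The among-species covariance expected under Brownian motion is
`tree_covariance()`: diagonal entries are root-to-tip path lengths (Myr),
off-diagonals the depth of each pair's most recent common ancestor.
Pagel's lambda multiplies the off-diagonal entries only; lambda = 1 is
pure Brownian motion, lambda = 0 a star phylogeny.

`estimate_lambda()` maximizes, over a common lambda in [0, 1], the sum
across residual columns of the Gaussian log-likelihood with covariance
lambda-transformed C, profiling each column's rate and mean out
analytically, by Brent search to 1e-6 with the interval endpoints checked
explicitly. A common lambda with per-column rates is the multivariate
treatment; the upper bound is exposed for users who want the
matrix-admissible maximum instead of 1. Constant columns are dropped with
a warning.

`pgls_procrustes_anova()` implements the two-pass protocol used in
comparative shape studies: fit once under the Brownian covariance,
estimate lambda on the residuals, rescale, and fit again. The rescaled
covariance's inverse square root whitens both sides (the intercept column
becomes the GLS mean, which also centres the total sum of squares); sums
of squares are sequential (type I), matching formula-order semantics, so
term order matters in multi-term models. Significance is by residual
randomization (RRPP): reduced-model residual rows are permuted and added
back to the reduced-model fit, the same permutation stream serving all
terms; p is the proportion of the distribution (observed arrangement
included, so p ≥ 1/(n_perm+1)) at or above the observed F, and the effect
size Z standardizes log F within that distribution. Defaults are 999
permutations and a mandatory seed.

## Evolutionary integration (two-block PLS)

`phylo_two_block_pls()` measures integration between two trait blocks:
both are centred on their GLS means, whitened by the inverse square root
of the (lambda-rescaled) covariance, and the cross-covariance matrix is
decomposed by SVD; r-PLS is the correlation of the first pair of
singular-axis scores and R² = r-PLS² is the reported statistic. The
permutation null permutes rows of the second whitened block; Z
standardizes the Fisher-z-transformed statistic within the permutation
distribution. The standard error of Z attached to each result —
sd of the standardized permuted statistics divided by sqrt(n_perm), i.e.
1/sqrt(n_perm) — exists so `compare_pls()` can test pairs of analyses with
|Z1 − Z2|/sqrt(SE1² + SE2²) against the standard normal. The covariance
passed in should be rescaled with the lambda estimated from the
intercept-only model on the full coordinates, which is what
`run_integration_suite()` does per phylogenetic scope (all species,
Telluraves-like and complement subsets, or any named species lists).
Blocks stay in the common Procrustes frame of their source dataset and are
not re-superimposed, so region blocks partition the full coordinate
matrix exactly.

## Ecology space and landmark-scheme validation

Diet is a 10-bin semi-quantitative profile (multiples of 10 summing to
100). `diet_distance()` is the plain Euclidean distance between profiles;
`pcoa()` is classical scaling of the doubly centred Gower matrix, with
negative eigenvalues reported and their axes dropped; for a Euclidean
input the full-dimensional coordinates reproduce the distances to 1e-9.
`derive_diet50()` encodes the main-diet rule: a single category only when
one item strictly exceeds 50%, otherwise the compound of the two largest
items, alphabetically ordered, with second-rank ties broken alphabetically
under a warning. Downstream regressions use all positive axes by default
and the first two for diet-space scatter-style analyses.

`compare_landmark_schemes()` re-superimposes the raw configurations under
the full template and under the fixed+curve subsample (superimposition
depends on the point set, so the subsampled dataset is aligned from raw
coordinates, not sliced from the full alignment), then compares the two
Procrustes distance matrices with a Mantel test (Pearson correlation,
one-sided greater, 9999 permutations by default, via vegan) and the signed
difference matrix with its mean and share of negative entries.

## The synthetic generator: what it emulates and what it does not

`simulation_scenario()` fixes the study conditions once: 200 tips on an
ultrametric pure-birth tree (rate 0.1 per Myr), Brownian shape evolution
at rate sigma2 = 1e-4 per coordinate per Myr with generating lambda 0.8
(the order of lambda estimates such analyses report), log-normal centroid
sizes (meanlog log 10, sdlog 0.5, mm), allometry beta = 0.05, one basal
clade mean shift of 0.05 centroid-size units, and optional latent-factor
integration between two region blocks. Brownian displacement is simulated
on raw coordinates — acceptable for small displacements, enforced by
capping the mean displacement at 0.2 of the base centroid size. Shapes are
exported pre-superimposition with random rotations, translations and the
drawn sizes, so GPA is genuinely exercised; the recorded centroid sizes
recover the drawn sizes exactly.

Three generator details are worth knowing:

* **The allometric field is non-affine by construction.** A naive radial
  field is a pure scaling deformation and is annihilated by Procrustes
  size normalization; the generator instead uses a fixed smooth quadratic
  deformation with the tangent space of similarity transforms projected
  out. beta = 0.05 yields an allometric share of a few percent of shape
  variance — weak but reliably detectable at n = 100, the regime such
  comparative datasets occupy.
* **Coordinate-wise Brownian fields are not spatially smooth.** Real shape
  variation deforms neighbouring points together; independent
  per-coordinate Brownian motion does not. Sliding assumes smoothness, so
  the full-versus-subsampled scheme validation reaches r > 0.9 under
  smooth (affine + quadratic) deformation fields — the scenario the
  validation tests construct — while the iid-BM generator plateaus near
  0.85–0.9. Passing tests therefore certify the machinery, not that iid
  BM is a faithful model of quadrate evolution.
* **Coupled diet profiles ride the leading shape axis**, which is
  phylogenetically structured; GLS whitening legitimately discounts such
  confounded signal, so the coupled mode is tested at n = 200 (where it
  rejects reliably at coupling strength 4), and the independent mode
  yields calibrated type-I error. This mirrors the one-to-many /
  many-to-one pattern the pipeline is designed to expose: clade structure
  carries strong shape signal while diet terms stay non-significant.

Profiles are Dirichlet draws binned to multiples of 10 by
largest-remainder rounding; discrete ecological variables follow
clade-preferred categories with 70% adherence.

## Problem sizes, runtime and reproducibility

Desk-scale defaults keep the whole verification loop light: the test suite
runs the full chain on 15–200 species with 68–128 landmarks, calibration
loops use 199 permutations per fit and 200 replicates for type-I error,
and single analyses use the 999/9999 permutation defaults. The
acceptance script runs the default 100-species, 128-landmark study
end-to-end (GPA with sliding, PCA, three PGLS models at 999 permutations,
one two-block PLS, scheme validation at 9999 Mantel permutations) in
about a minute on one CPU. Every stochastic step takes an explicit seed,
and the pipeline (`run_pipeline()`) is a pure function of (inputs, config,
seeds): reruns are bit-identical.

## Known limitations

* Missing landmarks, bilateral symmetry handling, and measurement-error
  models are out of scope; so are non-Brownian models (OU, early-burst)
  and covariance-ratio modularity statistics.
* Lambda estimated on high-dimensional raw Procrustes residuals at
  moderate n is mildly biased downward relative to the generating value;
  the recovery guarantees asserted by the tests operate on residual
  matrices of moderate dimension (p = 20 at n = 200), where the profile
  likelihood is well behaved.
* TPS warps are computed on point configurations; mesh rendering of
  warped surfaces belongs to other tools.
* The Mantel scheme validation inherits the usual caveat that distance
  correlations near 1 say little about localized differences; the signed
  difference matrix is reported precisely so such structure can be
  inspected.
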