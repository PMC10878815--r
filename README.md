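# quadmorph

Phylogenetic geometric morphometrics for densely landmarked skeletal
elements, built around the avian quadrate — the bone that links the
mandible, the palate (via the pterygoid) and the jugal bar in the kinetic
bird skull. The package is for comparative morphologists who want to ask,
across a clade-wide sample, how much of a bone's shape variation is
explained by ecology, by allometry, by phylogeny, and by integration with
neighbouring bones — and to verify every stage of that inference chain on
synthetic data first.

## What it implements

Shapes are k landmark points in 3-D per species: fixed anatomical
landmarks, curve semi-landmarks, and surface semi-landmarks, each point
assigned to a named anatomical region.

* **Superimposition** — generalized Procrustes analysis (translation,
  unit-centroid-size scaling, rotation without reflection, iterated to a
  canonical principal-axis frame), with curve and surface semi-landmarks
  slid by the minimum-bending-energy criterion: slide magnitudes are the
  closed-form minimizer of the thin-plate-spline bending energy of the
  consensus-to-specimen deformation,

  E(V) = Σ_d V_dᵀ B V_d,  B = upper-left block of L⁻¹, U(r) = −r,

  followed by re-projection onto the anatomy.
* **Shape space** — PCA of the aligned coordinates, shape prediction at
  score quantiles via thin-plate-spline warps, per-landmark Procrustes
  variance, and ancestral scores for phylomorphospaces (closed-form
  Brownian-motion reconstruction).
* **Phylogenetic regression** — Procrustes ANOVA under generalized least
  squares with residual randomization (RRPP): the phylogenetic covariance
  C (shared branch lengths) is rescaled by Pagel's lambda estimated on the
  model residuals by profile likelihood, both sides are whitened by
  C_λ^(−1/2), sums of squares are sequential, and p/Z come from permuting
  reduced-model residuals (999 permutations by default).
* **Integration** — phylogenetic two-block partial least squares: r-PLS is
  the correlation of the first singular-axis scores of the whitened
  cross-covariance; effect sizes Z (Fisher-z standardized against the
  permutation null) are comparable across analyses with a normal-theory
  pairwise test.
* **Ecology space** — Euclidean distances between 10-bin semi-quantitative
  diet profiles, principal coordinates analysis, and the main-diet rule
  (single category only above a strict 50% majority, compound of the top
  two otherwise).
* **Scheme validation** — full versus fixed+curve-only landmark schemes
  compared by Mantel tests between Procrustes distance matrices and by the
  signed difference matrix.
* **Synthetic generator** — quadrate-like parametric base shapes evolving
  by Brownian motion along a pure-birth tree with tunable phylogenetic
  signal, allometry, clade shifts, latent-factor integration between
  regions, and coupled or independent diet profiles, exported
  pre-superimposition so the whole chain is exercised.

## Worked example

Simulate a 50-species study with latent integration between the otic and
mandibular regions, align with sliding, and run the core analyses:

```r
library(quadmorph)

scenario <- simulation_scenario(
  n_tips = 50, n_curve = 30, n_surface = 30,
  integration = list(pair = c("otic_process", "mandibular_process"),
                     strength = 0.5),
  seed = 42
)
dataset <- simulate_dataset(scenario)

aligned <- gpa(dataset$configs, slide = TRUE, template = dataset$template)
aligned
#> Aligned shapes: 50 specimens, 68 landmarks
#> Centroid size range: 2.308 - 37.72

shape_pca(aligned)
#> Shape PCA: 50 specimens, 49 axes
#> Leading axes (% variance): 31.12, 13.38, 10.33, 5.46, 4.01

C <- tree_covariance(dataset$tree)
Y <- shape_matrix(aligned)
d <- data.frame(csize = as.numeric(aligned$centroid_size))
fit <- pgls_procrustes_anova(shape ~ log10(csize), d, C, Y = Y,
                             n_perm = 999, seed = 1)
fit
#> PGLS Procrustes ANOVA (lambda = 0.7301232, 999 permutations)
#>           term  lambda df         SS         MS       R2      F      Z     p
#> 1 log10(csize) 0.73012  1 0.00093082 0.00093082 0.059568 3.0404 2.6926 0.012

pls <- phylo_two_block_pls(
  subset_block(aligned, dataset$template, "otic_process"),
  subset_block(aligned, dataset$template, "mandibular_process"),
  lambda_transform(C, fit$lambda), n_perm = 999, seed = 2
)
pls
#> Phylogenetic 2B-PLS: r-PLS = 0.9108 (R2 = 0.8296), Z = 12.1514, p = 0.001 (n = 50, 999 permutations)
```

Reading the output: quadrate size explains about 6% of shape variance
here and the association is significant after phylogenetic correction
(lambda ≈ 0.73 estimated from the residuals); the two regions that share
a latent Brownian factor integrate strongly (R² ≈ 0.83, p at the
permutation floor). `run_pipeline()` wraps the same chain — including the
diet space, a formula battery, the internal-integration suite and the
landmark-scheme validation — behind one YAML-configurable, fully seeded
call that writes delimited tables and a run manifest.

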