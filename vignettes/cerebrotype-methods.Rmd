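---
title: "Methods: multi-level cerebellar ecomorphology with cerebrotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-level cerebellar ecomorphology with cerebrotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cerebrotype)
```

`cerebrotype` implements a multi-level comparative analysis of cerebellar
architecture against an ecological predictor — here, locomotor mode — at
four levels of organisation: organ shape (3D landmark geometric
morphometrics), organ size (volumetric allometry), cellular layout
(Purkinje-cell scattering through the molecular layer), and gene
expression (ortholog FPKM matrices). All four levels share one
phylogenetic backbone, and a synthetic-data generator reproduces the
statistical structure of each level so that the entire pipeline can be
exercised and calibrated without any imaging or sequencing data.

This vignette is the package's methodological record: the models, the
tunable parameters and their defaults, the numerical choices, what the
generator does and does not emulate, and the known limitations. It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Shape: Procrustes superimposition and ordination

Landmark configurations (p landmarks × 3 coordinates per specimen, in
micrometres) are superimposed by generalized Procrustes analysis (GPA):
each configuration is centred, scaled to unit centroid size
(CS = the square root of summed squared landmark distances to the
centroid), and rotated onto the running consensus; the consensus is
re-estimated until its root-mean-square change falls below `1e-10`
(at most 100 iterations). Fitting rotations are proper — reflections are
excluded, since landmarks are biologically homologous — behind a
configurable flag. Original centroid sizes are retained separately for
allometric regression.

Two numerical choices deserve note:

* **Rotational gauge.** The GPA fixed point is unique only up to a global
  rotation. The implementation canonicalizes the output frame (the
  consensus is aligned to its principal axes with a deterministic sign
  convention and right-handed third axis), which makes GPA exactly
  idempotent: re-running it on aligned output reproduces the coordinates
  to machine precision.
* **Tangent-space regime.** Procrustes statistics are linear only for
  small shape variation. The synthetic generator keeps group effects and
  noise at a few percent of centroid size (see below); configurations
  with shape differences comparable to the shape itself would leave this
  regime, and estimated effect magnitudes would compress.

Shape PCA is an eigendecomposition of the specimen covariance of the
flattened aligned coordinates, without phylogenetic correction — matching
the ordinations the analysis visualizes; phylogeny enters only in the
statistics. Component signs follow the convention that the
largest-magnitude loading is positive. Between-group PCA computes axes
from the covariance of group mean shapes and projects all specimens onto
them; group mean confidence ellipses are bootstrap ellipses of the group
mean (default 68.27% coverage, 5000 replicates). Mean-shape deviation
maps thin-plate-spline–warp a mesh registered to the overall mean
configuration towards each group mean (3D biharmonic kernel
U(r) = r, exact at landmarks and exact for affine maps) and report
per-vertex displacement. Because the 3D kernel grows with distance, the
displacement field is meaningful inside the landmark hull; far outside it
the affine extrapolation dominates.

## Phylogenetic statistics

All generalized least squares (GLS) steps use the Brownian-motion tip
covariance `C` (shared root-to-MRCA path lengths) and the symmetric
inverse square root `P = C^(-1/2)` from its eigendecomposition rather
than a Cholesky factor: the symmetric root is rotation-invariant and the
difference is a rotation that leaves every statistic unchanged (asserted
by test).

* **Phylogenetic signal** is the multivariate generalisation of
  Blomberg's K: the ratio of observed to Brownian-expected signal, equal
  to 1 in expectation under Brownian motion and exactly 1 on a star tree
  for any data. Significance comes from permuting data across tips.
* **Regression and ANOVA** use distance-based PGLS: responses and design
  are premultiplied by `P`, the model is fitted by least squares, and
  significance comes from residual-randomization permutation (RRPP) of
  the reduced model's residuals (intercept-only for the overall test;
  1000 permutations by default, 99 in the calibration simulations).
  Pairwise post hoc comparisons are Euclidean distances between
  GLS-estimated group means, each referred to its own RRPP null,
  reported unadjusted (with a Benjamini–Hochberg flag available).
  Permutation p-values use the (b+1)/(B+1) estimator with ties counted
  conservatively.
* **Convergence** is measured by the distance-based C1–C4 statistics:
  the fraction (C1) and amount (C2) of the maximum past phenotypic
  distance between focal lineages that evolution has closed, scaled by
  the total change along those lineages (C3) or within their clade (C4).
  Ancestral states are joint maximum-likelihood estimates under Brownian
  motion (equivalently, branch-length-weighted squared-change parsimony;
  they match `phytools::fastAnc` to 1e-10 in the tests). The null is
  Brownian simulation with the rate matrix estimated from phylogenetic
  independent contrasts.

A limitation worth stating plainly: D-PGLS assumes the residual
covariance is proportional to `C`. Non-phylogenetic noise (e.g.
digitisation error) is amplified by `C^(-1/2)` on short terminal
branches, and in simulation this inflates type-I error well above the
nominal level. The calibration suite therefore defines its null
configurations as pure-Brownian data, and real analyses should average
replicate landmarking sessions (supported by `average_replicates()`)
to suppress measurement error before the GLS stage.

## Volumetrics: allometry lines, the homogeneity gate, Johnson–Neyman

Log cerebellar volume is regressed on log whole-brain volume (natural
logs; the base only shifts thresholds) per locomotor mode under a
Pagel's-λ GLS model, `V(λ) = λC + (1-λ)diag(C)`, with λ estimated by
restricted maximum likelihood. REML is used instead of ML because the ML
profile is biased at comparative sample sizes and measurably inflated the
slope-homogeneity F test in null simulations; with REML the test is
within the binomial confidence band of its nominal level.

The pipeline applies an explicit decision gate, recorded in the report:
slope homogeneity across modes is tested by an F test of the
mode × covariate interaction at the fitted λ. If homogeneity is rejected
**and** the fitted λ is negligible (< 0.1), mode pairs are compared by
the Johnson–Neyman procedure — the region of covariate values where the
two lines differ significantly, obtained as the roots of the quadratic
`(Δb² − t²·var(Δb))x² + 2(Δb·Δa − t²·cov)x + (Δa² − t²·var(Δa))`,
with `t` the two-sided critical value at n − 4 degrees of freedom (two
lines, two parameters each; configurable). Degenerate quadratics are
resolved by sign analysis, intervals are intersected with the observed
covariate range, and the boundaries match a 1e-6-step grid scan of the
t-statistic in the tests. Otherwise the common-slope phylogenetic ANCOVA
fit is reported. The cerebellum-to-brain volume ratio (in percent) is
additionally analysed with the univariate D-PGLS/RRPP machinery.

## Cellular layout: scattering statistics and positioning patterns

Each labelled Purkinje cell contributes its distance from the inner
granule-cell-layer border, normalised by the local molecular-layer
thickness to a depth percentage (0 = GCL border, 100 = pial surface).
Species are compared with the Kruskal–Wallis rank test (tie-corrected;
exact enumeration of all group-label assignments replaces the chi-square
approximation automatically when the pooled sample size is at most 10)
followed by Dwass–Steel–Critchlow–Fligner pairwise tests: the
standardized two-sample rank-sum statistic, scaled by its exact
tie-corrected variance `n·m/12·[(N+1) − Σ(t³−t)/(N(N−1))]`, referred via
√2·|z| to the Studentized range distribution with k groups.

Positioning patterns are derived from the pairwise matrix by a rule that
has no single canonical definition, so the package makes an explicit,
documented choice: species pairs that are *not* significantly different
(p ≥ α, default 0.05) are joined by an edge, and patterns are the
connected components of that graph — deterministic and order-independent,
unlike clique-finding. When the non-significance graph is not transitive
the result is flagged, since membership then chains through intermediate
species. Patterns are labelled I, II, … by ascending median depth, and a
confirmation Kruskal–Wallis test between the resulting patterns is
re-run. Cells are pooled per species across individuals.

## Expression: filtering, clustering, AU support, enrichment

Ortholog FPKM matrices are filtered to genes exceeding 0.5 FPKM in at
least one species (strictly above; a gene at exactly the threshold is
removed). For the gene-axis heat-map analysis rows are z-scored (constant
rows are zeroed and flagged) and clustered with Euclidean distance and
average linkage, cut at k = 3; for the species-axis dendrogram, raw
filtered FPKM profiles are compared by Pearson correlation (distance
1 − r). Average linkage is the heat-map default; the choice, like the
transform, is configurable.

Support for the species dendrogram comes from multiscale bootstrap:
genes are resampled with replacement at scales r ∈ {0.5, …, 1.4}
(1000 replicates per scale), the per-node bootstrap probability BP(r) is
the fraction of replicates containing the identical tip set, and
z(r) = Φ⁻¹(1 − BP(r)) is fitted as v√r + c/√r by weighted least squares
and extrapolated to the approximately unbiased support
AU = 1 − Φ(v − c). Scales where BP is exactly 0 or 1 carry no
information and are excluded; a node within 20/B of saturation at every
scale has no usable curvature signal and is reported at the resolution
limit 100·(1 − 1/(2B)) (flagged "saturated"), and a node never observed
at any scale gets AU = 0 with a flag. Mid-support nodes retain an
irreducible seed-to-seed variability of roughly 2–3 percentage points at
1000 replicates; the repeatability test asserts a median per-node spread
below 3 points across seeds.

GO enrichment is the upper-tail hypergeometric probability per term with
Benjamini–Hochberg adjustment across terms; reported hits require
adjusted p < 0.01 and at least ten annotated genes in the query set (the
"ten genes" rule is interpreted as query-set counts, configurable).
No GO-graph propagation is performed: terms are taken as annotated.

## The synthetic-data generator

The generator's defaults are the study conditions: 40 species, 61
whole-brain landmarks plus 5 cerebellum-interface extras, 7 locomotor
modes, 630 one-to-one orthologs across a 10-species expression panel,
250–750 cells per species. One integer seed drives everything;
sub-streams are derived per generator by reading the seeded
Mersenne–Twister stream itself (arithmetic on the seed value composes
badly with R's seed scrambling and measurably correlated "independent"
streams during development).

* **Tree** — pure birth, depth scaled to 1: parameter-free; a
  user-supplied Newick can replace it.
* **Landmarks** — base shape + Brownian deviations on the tree +
  mode-specific fixed displacement + allometric term × log-CS deviation +
  i.i.d. noise, then scaled to a lognormal species size. The effect
  scales are deliberately small relative to centroid size
  (`bm_rate = 5e-4`, `noise_sd = 0.005`, `mode_effect = 0.015` — three
  times the noise — `allometry_coeff = 0.25`, which puts the allometric
  share of shape variance near 10%): this keeps configurations in the
  Procrustes tangent-space regime, where generating displacement
  magnitudes are recoverable from group mean shapes (within 15% in the
  tests) and detection power for the 3×-noise mode effect exceeds 80%.
* **Volumes** — per-mode lines in log-log space with Pagel's-λ residual
  structure. Defaults give the limbless-burrower mode a steeper slope
  (1.2 vs 1.0) and lower intercept, crossing inside the observed range so
  the homogeneity gate rejects and the Johnson–Neyman branch runs, and
  λ = 0, emulating the negligible volumetric phylogenetic signal that
  licenses the Johnson–Neyman procedure in the first place. Null
  calibration of the *phylogenetic* ratio ANOVA instead uses λ = 1
  residuals, which that test presumes.
* **Cell depths** — Beta-distributed depth percentages per archetype,
  stored as raw distance/thickness pairs whose ratio reproduces the draw.
  The Beta is a choice (bounded support matches the 0–100% scale); the
  four archetypes (mean%, concentration) are I (12, 60) ordered
  monolayer, II (28, 20) ordered multilayer, III (38, 12) scattered
  multilayer, IV (50, 2) totally scattered — increasing in both median
  and dispersion, and mutually separable at the generated cell counts,
  matching the premise that the four positioning patterns are genuinely
  statistically distinct.
* **Expression** — log-normal FPKM. Archetype-1 genes are highly
  expressed everywhere and load **positively** on a shared per-species
  factor (SD 0.5); archetype-2 genes are lowly expressed and load
  **negatively**; archetype-3 genes shift coherently between limbless
  (modes 1–4) and quadrupedal (modes 5–7) species by `expr_effect = 2`
  log units. The species factor exists because pure level differences
  vanish under the row z-scoring the heat-map clustering uses; with it,
  the z-scored matrix shows the up-regulated, down-regulated and
  group-differential bands the analysis expects, the k = 3 cut recovers
  the archetypes (mean adjusted Rand ≥ 0.9 in the tests), and the species
  dendrogram is mode-dominated rather than tree-dominated when the
  archetype-3 effect is large. One GO term ("locomotory behaviour") is
  preferentially assigned to archetype-3 genes.

What the generator does **not** emulate: real brain geometry (the base
shape is random), landmarking replicates (one configuration per species
by default; replicate sessions are supported but optional), read-level
RNA-seq (FPKM only), within-species individual variation in cell depths
(cells are pooled per species), and non-Brownian evolutionary processes.
Passing tests therefore demonstrate statistical correctness and
calibration of the machinery under its stated assumptions, not that any
particular biological dataset satisfies those assumptions.

## Problem sizes and reproducibility

The calibration suite runs 200 null replicates per test at B = 99
permutations and n = 40 species with 12-landmark configurations; the
recovery suite uses 200 replicates for the Brownian-K and power checks,
100 for λ recovery, depth-archetype recovery and gene-archetype ARI; the
bootstrap-support runs use 630-gene matrices at 1000 replicates per
scale. These sizes were chosen so each property is measured with useful
precision while the whole suite stays interactive. Every stochastic
step takes an explicit seed, every simulation-based result in this
vignette is recomputed by `tests/testthat/` or `scripts/acceptance.R`,
and `run_pipeline()` reports are byte-identical given the same
configuration and seed.
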