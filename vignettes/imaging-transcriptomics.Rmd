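---
title: "Linking regional brain phenotypes to gene expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking regional brain phenotypes to gene expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regiontx)
```

# The analysis

Imaging-transcriptomics studies ask which genes, and which classes of
genes, have cortical/subcortical expression patterns that track a spatial
brain phenotype — here, a case-control difference map (for example a
voxel-wise magnetic-susceptibility contrast between patients and
controls). `regiontx` implements the full chain as composable stages:

1. **Voxel-wise group inference.** Subject volumes are smoothed (3 mm FWHM
   by default), and an OLS model `value ~ intercept + group + age + sex`
   is fit at every in-mask voxel; the group-contrast t-map is enhanced
   with threshold-free cluster enhancement (TFCE) and assessed by
   permutation with family-wise error (FWE) control over the maximum
   statistic (5000 permutations by default).
2. **Parcellation.** The TFCE map is averaged within the regions of a
   volumetric atlas (83 regions by default, mirroring the
   Desikan–Killiany parcellation used with regional expression matrices),
   giving the regional phenotype $y \in \mathbb{R}^R$.
3. **Spatial nulls.** Surrogate regional maps preserving the spatial
   autocorrelation of $y$ (1000 by default) calibrate all downstream gene
   statistics against the smoothness of the map itself.
4. **PLS gene ranking.** Partial least squares regression of the z-scored
   $y$ on the z-scored regions-by-genes expression matrix $X$ yields
   per-gene component weights; each gene's aligned component-1 weight is
   divided by its standard deviation across surrogate-map refits to give
   a per-gene $Z$ statistic, whose descending order is the gene ranking.
5. **Enrichment.** Preranked GSEA (weighted Kolmogorov–Smirnov running
   sum, gene-label permutation null, sign-classed NES, GSEA-style FDR)
   tests functional gene-set collections and cell-type-specific sets
   derived from FPKM tables by the specificity index (SI) with
   permutation p-values (pSI), thresholded at 0.001.

Every input can be simulated with known ground truth by the
`gen_*` generators, so the whole chain is testable end to end without any
external data.

# Models, assumptions, key parameters

## Voxel model and TFCE

The cohort model assumes independent Gaussian voxel noise after
smoothing, linear covariate effects, and a constant group shift inside
the affected tissue. TFCE integrates cluster extent and height,

$$\mathrm{TFCE}(v) = \int_0^{h_v} e_h(v)^{E}\, h^{H}\, dh,$$

with the literature-standard $E = 0.5$, $H = 2$ and 26-connectivity
(`tfce_params()`). Because $e_h(v)$ — the size of the suprathreshold
component containing $v$ — is piecewise constant in $h$, changing only
where $h$ crosses a voxel height, the integral has a closed form on each
interval. `tfce_enhance()` therefore evaluates it **exactly** by default,
via a single union-find sweep over voxels sorted by height with lazy
per-cluster accumulators. This removes the step parameter `dh` and its
discretization error entirely (a conventional midpoint-step approximation
remains available by setting `dh`). The exact sweep is also faster than
stepping, which matters in the permutation loop. Positive and negative
contrasts are enhanced in separate one-sided passes, so the output is an
odd function of the t-map and both contrast directions are available by
negation.

Inference uses Freedman–Lane permutation: the data are residualized on
the reduced model (intercept + covariates), residual rows are permuted,
and the full model is refit, which is the standard scheme for
nonparametric GLM inference with nuisance covariates. The FWE-corrected
p-value compares each voxel's |TFCE| with the permutation distribution of
the maximum, with the `(1 + k)/(n_perm + 1)` estimator, so p-values are
floored at `1/(n_perm + 1)`.

Smoothing renormalizes by the smoothed mask (dividing the smoothed masked
volume by the smoothed mask indicator), so out-of-mask zeros never bleed
into in-mask values and constants are preserved exactly at mask edges.

## Surrogate maps

`generate_surrogates()` uses variogram matching, the standard construction
for parcellated volumetric data: each surrogate is a random permutation of
the observed regional values, smoothed with a row-normalized exponential
kernel over centroid distances at the bandwidth (grid: 10%–90% of the
maximum centroid distance) whose variogram best matches the empirical
variogram after an affine least-squares fit; white noise is re-injected
according to that fit's intercept and the result is affinely rescaled to
the observed mean and SD. Only centroid geometry is used, as nothing finer
is available at region level. The per-surrogate fidelity (Pearson r
between surrogate and empirical variograms) is returned, and is high
(median ≳ 0.95 in the test suite) whenever the phenotype's variogram
actually carries structure over the sampled distance range; on
short-range or white phenotypes the variogram is flat and the fit statistic
is uninformative — the surrogates then simply behave like permutations,
which is the correct null in that regime.

## PLS and the gene Z statistic

With univariate $y$, NIPALS PLS1 gives component-1 weights proportional to
$X^\top y$ — the vector of gene–phenotype covariances (correlations, after
z-scoring). This closed form is used as the oracle in the test suite and
makes the ranking interpretable: component 1 orders genes by how strongly
their expression tracks the phenotype, while the surrogate-derived
denominator discounts genes whose spatial profile makes high chance
correlations likely. Variance explained is reported for the response by
default (incremental $R^2$ of $y$ on the orthogonal score sequence), with
the X-variance decomposition also emitted, since "variance explained" is
ambiguous between the two in common usage.

**Weight alignment.** PLS components carry an arbitrary joint sign: negating
a weight vector together with its scores leaves the fit unchanged.
`align_weights()` pins the convention to the validated outcome — genes with
large positive aligned weight have expression *positively* correlated with
the phenotype — by flipping the weights when the component scores correlate
negatively with $y$. (Stated as a flip rule on the score–phenotype
correlation, conventions in the literature are inconsistent; we enforce the
outcome, which `validate_ranking()` checks directly by univariate
regression of the top and bottom genes on the phenotype.)

The Z denominator is the SD of the aligned weight across PLS refits on the
surrogate maps. A region-resampling bootstrap is exposed as an alternative
denominator (`gene_z_scores(..., null = "bootstrap")`), but the spatial
null is the primary definition: it asks "how variable would this gene's
weight be against maps with the same smoothness but no gene–phenotype
correspondence", which is the calibration that matters for spatially
autocorrelated data. Ties in Z are broken lexicographically by gene symbol
for determinism. Genes dropped for zero variance are excluded from both
the ranking and the enrichment universe.

## GSEA

`gsea_preranked()` implements the classic weighted running-sum statistic
(`p_weight = 1`), a gene-label permutation null per set size, p-values
from the same-sign null tail, NES as ES divided by the mean |null ES| of
the same sign, and the standard NES-based FDR. Defaults (1000
permutations, set sizes 10–500) follow the conventions of the widely used
preranked-GSEA implementations. The permutation unit is gene labels
because no sample-level data exists at this stage. Term-redundancy
pruning (`prune_redundant()`) is greedy by significance with a Jaccard
gene-overlap threshold (0.7): this deliberately replaces
ontology-graph semantic similarity — which would pull in an ontology
dependency and a DAG — with a dependency-free overlap criterion; it
behaves the same on near-duplicate sets but cannot recognize conceptually
similar sets with disjoint genes.

## Cell-type specificity

For each target type $A$ and each other type $B$, genes are ranked by the
fold change $(\mathrm{FPKM}_A + 1)/(\mathrm{FPKM}_B + 1)$ (the
pseudo-count of 1 FPKM guards zeros; average ranks on ties); SI is the
mean of the five ranks, so a perfectly specific gene has SI = 1 and
exchangeable genes average $(G+1)/2$. SI is invariant to global rescaling
of FPKM.

**Permutation unit for pSI.** The null permutes the *sample-to-cell-type
assignment* and recomputes type means and SI. This is the exchangeability
unit that matches how the tables arise (grouped RNA-seq samples): under
the null it reproduces the observed SI distribution exactly, so pooled
p-values are uniform, while genuine specificity is destroyed by
scattering a gene's high samples across pseudo-types. The alternative of
shuffling gene labels within each type column of the mean matrix was
rejected on measurement: the shared target-column value correlates a
gene's five comparison ranks, which simultaneously fattens the null's
lower tail (destroying sensitivity at the 0.001 threshold) and
miscalibrates the pooled p-values. Null SI values are pooled across
genes, types and permutations, giving p-value resolution
$1/(6\,G\,n_{\mathrm{perm}})$, so the 0.001 threshold is resolvable with
100 permutations at desk scale.

A structural property worth knowing: SI is rank-based, so $k$ genes
co-specific to the same type necessarily occupy ranks $1..k$ and the
weakest of them has SI near $k$. With $G = 2000$ the pooled-null 0.001
quantile sits near SI ≈ 20–25, which bounds the size of a marker panel
that can be fully recovered at that threshold. The synthetic generator
therefore plants compact panels (10 genes per type by default),
representing unambiguous marker genes; larger panels would confound
generator design with method sensitivity.

# The synthetic-data generator

`gen_atlas()` builds Voronoi parcellations around random seed voxels;
`gen_cohort()` draws two groups with unit-variance Gaussian voxel noise, a
planted standardized mean difference (Cohen's d) in chosen regions, age ~
uniform(45, 75) years and sex ~ Bernoulli(1/2) with configurable linear
slopes (defaults 0.02/year and 0.2, modest relative to unit noise);
`gen_expression()` builds coupled genes as
$\rho\, z(y) + \sqrt{1-\rho^2}\,\eta$ with $\eta$ drawn from an
exponential-covariance Gaussian process over centroid distances (range 5
grid units by default), so surrogate calibration has genuine spatial
structure to preserve; `gen_celltype_fpkm()` draws log-normal FPKM
(per-gene baseline meanlog ~ N(2, 1), sdlog 0.5) and multiplies planted
genes by `fold` in their type, in three independently seeded series
emulating independent published datasets.

What the generator does *not* emulate: MRI susceptibility physics and
units, registration error, probe-level microarray structure, donor
effects, or realistic gene–gene co-expression modules. Passing tests
therefore demonstrate that the statistical machinery is correct and
calibrated under its stated assumptions — not that those assumptions hold
in any particular real dataset.

# Numerical and design choices

- **Exact TFCE integral** (above): no `dh` tuning, no discretization error,
  odd symmetry and $\lambda^{H+1}$ scale equivariance hold exactly.
- **Seeds.** Every stochastic stage takes an explicit integer seed;
  `run_all()` derives stage seeds from one top-level seed by a fixed
  splitting rule (`split_seed()`), and all generator functions restore the
  caller's RNG state. Reruns are byte-identical.
- **Degenerate inputs.** Zero-variance genes are dropped with a warning and
  excluded everywhere downstream; regions with no in-mask voxels
  parcellate to `NA` with a warning; gene sets equal to, or disjoint from,
  the universe are rejected; a zero score–phenotype correlation keeps the
  weight sign and warns.
- **Identifiers.** Region ids and gene symbols ride along in every table;
  joins are by key, never by position.
- **Problem sizes in the test suite.** The end-to-end synthetic runs use a
  16³ grid, 20 subjects per group, an 83-region atlas, 2000 genes with
  50 + 50 planted at $\rho = \pm 0.8$, 200 surrogates, and 100–500
  permutations per permutation test; FWE calibration uses 100 replicate
  null cohorts at 200 permutations. These sizes give stable Monte-Carlo
  verdicts for every property while a full run of `run_all()` stays under
  ten seconds.

# A minimal run

```{r example, eval = FALSE}
library(regiontx)
res <- run_all(pipeline_config(seed = 1), out_dir = "run1")
head(res$ranking)                    # gene, aligned weight, Z, rank
subset(res$enrichment, padj < 0.05)  # recovered gene sets
```

# Limitations

- Regional surrogates use centroid distances only; maps whose
  autocorrelation is not a function of centroid distance (e.g. strong
  hemispheric asymmetries) are matched only approximately.
- The Jaccard pruning is not a semantic-similarity "simplify"; ontology
  structure is out of scope.
- The pSI threshold interacts with marker-panel size as described above;
  comparing panel sizes across studies requires comparing universes.
- Real AHBA preprocessing (probe selection, donor normalization) is
  upstream of this package: the expression matrix is ingested as given.
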