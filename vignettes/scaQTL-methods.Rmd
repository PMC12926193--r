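---
title: "Models and methods in scaQTL"
author: "scaQTL authors"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Models and methods in scaQTL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

scaQTL maps chromatin accessibility quantitative trait loci (caQTLs) from
single-cell ATAC-seq fragment counts, without collapsing cells into
pseudobulk for the primary model.  The package covers the full analysis
arc: a generative simulator for multi-donor single-cell count data, a
grade-of-membership topic model of continuous cell states, topic-derived
cell trajectories, the single-cell Poisson mixed-effects (sc-PME) caQTL
model with donor-genotype permutation calibration, dynamic
(genotype-by-cell-state) interaction tests, cross-study RE2 meta-analysis,
and approximate-Bayes-factor colocalization with GWAS/eQTL summary
statistics.

This vignette documents the models, the tunable parameters and why their
defaults are what they are, the numerical choices, and the limits of what
the synthetic-data experiments can show.

# The sc-PME model

For one peak and one SNP, the per-cell fragment count $y_i$ of cell $i$ is
modelled as

$$y_i \sim \mathrm{Poisson}(\mu_i), \qquad
\log \mu_i = o_i + \beta g_{d(i)} + X_i \gamma + a_{d(i)} + b_{\ell(i)},$$

where $o_i$ is the log library size offset (total unique fragments),
$g_{d(i)} \in [0,2]$ the genotype dosage of cell $i$'s donor, $X_i$ a row
of z-scaled fixed covariates, and $a_d \sim N(0, \sigma_a^2)$,
$b_\ell \sim N(0, \sigma_b^2)$ donor and library random intercepts.  The
per-allele log-rate effect $\beta$ and its Wald test are the caQTL
statistics.  In a full-scale analysis the covariates are the top genotype
PCs, top latent-embedding dimensions, TSS enrichment, mitochondrial
fraction and log10 unique fragments; on synthetic data the three QC
covariates suffice because the generator plants no PC or embedding
structure.

Two estimation routes are implemented:

* **`method = "glmer"`** fits each peak-SNP model with `lme4::glmer`
  (`family = poisson`).  `nAGQ = 0` is the fast zero-quadrature setting
  appropriate for large scans; `nAGQ = 1` is the Laplace approximation.
* **`method = "pql"`** (the default for scans) estimates the variance
  components once per peak from the genotype-free null model
  (`scpmeNull()`, via `glmer`) and then solves, for each SNP, the
  penalized iteratively-reweighted least squares problem with
  $(\sigma_a^2, \sigma_b^2)$ held fixed.  Because the null model does not
  involve genotype it is shared across all SNPs of a peak *and* across all
  permutations, which makes permutation calibration experiments an order
  of magnitude cheaper.

On null simulations at the package's default study scale (40 donors,
~4,000 cells, sparse counts), the PQL Wald p-values are very close to
uniform — the test suite checks the rejection rate at $\alpha = 0.05$
against its binomial interval — and empirically slightly better
calibrated than the `nAGQ = 0` `glmer` route, whose z-scores are mildly
inflated at this scale.  The PQL route is therefore the default for
calibration-sensitive scans; the `glmer` route remains the reference for
single fits and for the dynamic likelihood-ratio tests, which compare two
nested `glmer` fits.  With variance components pinned at zero the PQL
solver reduces exactly to the Poisson GLM, which the test suite checks
against `stats::glm`.

**Significance calling.**  Within each peak, SNP p-values receive a
Bonferroni correction for the number of SNPs tested; the lead SNP
(smallest p, ties broken by distance to the peak center, then
lexicographic SNP id — the tie-breaks are this package's convention) is
extracted per peak; Storey q-values are computed over the lead
Bonferroni-adjusted p-values; peaks with $q < 0.1$ are significant
caQTLs.  The mapping window is $\pm 125$ kb around the peak center (a
250 kb window), and SNPs need at least 4 minor-allele dosage counts
across donors.  The minor-allele filter is applied to all scans, and
repeated-visit deduplication (keep the visit with more cells, ties to the
earlier visit) is available for pseudobulk aggregation.

**Permutation calibration.**  `permuteAndCalibrate()` shuffles whole
genotype rows across donors (preserving within-donor LD, destroying all
genotype-phenotype links) and reruns the scan.  Two fractions are
reported at the 0.1 level:

* the fraction of peaks whose **lead-SNP Bonferroni-adjusted p** falls
  below 0.1.  For $m$ independent SNPs per peak this has null expectation
  $1 - (1 - 0.1/m)^m \approx 1 - e^{-0.1} = 9.52\%$, slightly less under
  LD; a calibrated model should put it near the nominal level.
* the fraction of peaks with **Storey $q < 0.1$**.  Under a complete null
  an FDR procedure makes essentially no discoveries, so this is expected
  near zero — it confirms FDR control but is uninformative about
  calibration level.

The first fraction is the calibration diagnostic; on the default
synthetic conditions (~300 QTL-bearing peaks, ~300 matched controls, 40
donors, ~4,000 cells, 8 SNPs/peak) it sits near 10% for both groups,
within binomial sampling error of the nominal level.

# Dynamic caQTLs

A dynamic caQTL is a variant whose effect changes along a continuous cell
state.  For a lead SNP and a topic loading $t_i$, the full model adds
$\theta t_i + \delta g_i t_i$ and the reduced model only $\theta t_i$;
both are `glmer` fits compared by a 1-df LRT.  The test is invariant to
affine rescaling of $t$ (the main effects absorb location and scale), and
a constant $t$ is reported as statistic 0 with $p = 1$ and a
non-convergence flag rather than an error.  Because only lead SNPs are
tested, q-values are computed within each (cell type, topic) stratum and
then multiplied by the number of topics tested for that SNP — a
Bonferroni adjustment over topics — with adjusted $q < 0.01$ declared
significant.  The per-cell-type topic eligibility map ships as
`dynamicTopicMap()`.

# Topic model

The topic model is a Poisson non-negative matrix factorization
$Y \approx L F^T$ of the cells-by-peaks count matrix, fitted by
multiplicative EM updates (`n_main = 100`) followed by cyclic
coordinate-descent refinement (`n_refine = 200`): projected
single-variable Newton steps per factor column with step halving, so the
objective is monotone through both phases (the EM phase is monotone by
construction; the refinement enforces it by backtracking).  Updates stop
early when the relative objective change drops below `1e-10`.  The exact
coordinate-descent variant is asserted through objective monotonicity, not
iterate identity.

`expandAndRefit()` implements the incremental-K ladder: existing factor
columns are propagated and padded with uniform columns ($1/K_{new}$ for
loadings, $1/n_{peaks}$ for factors), then refit with `n_main` EM updates
and two consecutive runs of `n_refine` coordinate updates.  Columns keep
their positions, so topic $i$ remains comparable across the ladder.
`downsampleForFit()` reproduces the subsampling rule used before fitting:
sample a target number of cells, then rescue any peak left with all-zero
counts by appending a cell where it is non-zero, so the fitted factors can
be projected to the full matrix (`projectLoadings()`, independent per-cell
convex problems solved by EM).  `toMultinomial()` converts to topic
proportions $Q$ (rows sum to 1) and peak scores $\Phi$ (columns sum to 1)
via $u_k = \sum_j F_{jk}$.

The peak "score" used for top-peak selection and gene scores is the
$\Phi$ column — the per-topic peak probability; sample SD is used for the
per-gene Z-scores across topics.  Both are conventions this package fixes
explicitly because "score" admits either the raw or the normalized factor.
Topics tracking technical variation are flagged by absolute Spearman
correlation of loadings with QC covariates above 0.3 — a pragmatic
threshold of this package, not an established constant.

**Gene scores.**  Peak-level scores are aggregated per gene: body-overlap
peaks sum directly; peaks whose center lies up to 5 kb upstream of the
TSS (strand-aware) are weighted by $w(d) = e^{-d/5000}$.  The kernel is
exponential by default (matching the exponential-weighting gene-activity
strategy the scheme is modelled on) with a `power` alternative
($w(d) = (1+d/5000)^{-1}$) exposed for comparison.  The aggregation is
linear in the peak scores.

# Trajectories

A trajectory is simply the rank-percentile of a (possibly reversed) topic
loading scaled to $[0, 100]$ on a masked cell set, with a minimum-loading
filter for cells whose loading is estimation noise.  Rank scaling (rather
than min-max) makes the trajectory invariant to any strictly monotone
transform of the loadings, which the tests assert.  Composition,
binned-feature, and Spearman summaries operate on percentile bins; empty
bins propagate as `NA`.  The quintile differential-activity test compares
all first-quintile cells (cases and controls alike) against case cells in
the higher quintiles by Wilcoxon rank-sum with BH correction — the
rank-sum test is this package's choice; ties in quintile assignment are
resolved by stable rank.  The topic-phenotype association is a
mixed-effects logistic LRT (`loading + MTratio + nFrags + (1|donor)`
against the covariate-only null), with cells below loading 0.01 removed;
when the donor variance is zero it reduces to the ordinary logistic LRT,
which is tested.

# Meta-analysis

Cross-study effects are combined by inverse-variance fixed effects and by
the Han–Eskin RE2 statistic: the likelihood ratio of
$(\hat\mu, \hat\tau^2)$ against $(\mu, \tau^2) = (0, 0)$, maximized by a
50-point log-spaced $\tau^2$ profile grid with golden-section refinement.
The null distribution is the asymptotic mixture
$\tfrac12\chi^2_1 + \tfrac12\chi^2_2$; tabulated small-sample corrections
are not implemented, so p-values are anti-conservative for very few
studies — acceptable here because calibration claims rest on simulation,
not on small-sample exactness.  $S \ge z_{FE}^2$ always (the alternative
nests the $\mu$-only model), and the statistic is verified against an
independent 2-D grid-search oracle.  Allele harmonization flips swapped
codings, resolves strand flips, and drops strand-ambiguous (A/T, C/G)
mismatches.

# Colocalization

Per-SNP Wakefield log approximate Bayes factors
($\mathrm{labf} = \tfrac12[\log(1-r) + r z^2]$, $r = W/(W+se^2)$) are
combined over the five single-causal-variant hypotheses in log space.
The H3 sum $\sum_{i \ne j} BF^{(1)}_i BF^{(2)}_j$ is computed exactly by
leave-one-out log-sum-exp rather than the difference
$S_1 S_2 - S_{12}$, which cancels catastrophically when one SNP dominates
both traits.  Priors default to $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$;
the effect prior variance is $W = 0.15^2$ for quantitative traits and
$0.2^2$ is the conventional case-control choice.  Eligibility requires
strictly more than 150 shared SNPs with both traits' lead SNPs among
them.  GWAS loci are defined greedily: the genome-wide smallest p below
$10^{-7}$ seeds a locus, SNPs within 1 Mb of the lead are removed, and
the process repeats; the removal radius and the reported window are
separate parameters because "within 1 Mb" admits either a 1 Mb or a
$\pm$1 Mb reading.  The PP4 threshold for calling a locus colocalized
defaults to 0.75 and is always explicit in the output.

**Sharing.**  A caQTL significant in one cell type ($q < 0.1$) counts as
shared with another only when the other type's q clears the stricter
threshold $0.1/(n_{types} - 1)$ — 0.025 for five cell types — a
Bonferroni correction of the primary level over the other types.
Pairwise sharing is also quantified by Storey's $\pi_1$ on the second
type's p-values of the first type's significant peaks.

# The synthetic-data generator

`simulateCaqtlData()` draws data from exactly the generative form the
sc-PME model assumes: Poisson counts with
$\log \mu_{ic} = \log s_i + \log \sum_k l_{ik}\phi_{ck} + \beta_c g +
\delta_c g\, t_i + a_d + b_\ell$.  Its defaults are the study conditions
used throughout the tests and the calibration analysis:

| parameter | default | rationale |
|---|---|---|
| donors | 40 | a realistic single-cell cohort size; donor-level genotype effects need tens of donors |
| studies / libraries | 3 / 2 per study | mirrors a three-cohort harmonized design |
| cells per donor | 80–120 | ~4,000 cells total, enough for per-cell modelling at desk scale |
| peaks | 600, 50% with caQTL | ~300 QTL-bearing plus ~300 candidate controls |
| SNPs per peak | 8 | exercises Bonferroni and lead selection without dominating runtime |
| MAF | U(0.05, 0.5) | common variants, as after a MAC filter |
| LD $\rho$ | 0.5 (latent AR(1)) | mild local LD with monotone decay |
| $\beta$ SD | 0.5 | log-rate effects of realistic magnitude (|effect| mostly < 1.5-fold per allele) |
| dynamic fraction / $\delta$ SD | 0.2 / 0.5 | a minority of caQTLs state-dependent |
| $\sigma_{donor}, \sigma_{lib}$ | 0.2, 0.1 | donor variation dominates library variation |
| depth | lognormal(log 10^4, 0.5) | typical scATAC fragment counts per cell |
| per-peak rate | U(0.05, 0.5) per 10^4 depth | realistic sparsity (~70–90% zeros per peak) |
| topics | 4, Dirichlet(0.3) | few, well-separated states with single-topic-dominant cells |

LD is a thresholded AR(1) Gaussian copula on the latent haplotype scale —
real LD is empirical and block-structured, but any monotone-decay model
exercises window logic, Bonferroni behaviour and lead-SNP tagging.  QC
covariates are drawn jointly with depth (correlation 0.5) so covariate
adjustment is non-trivial.  All sub-generator seeds derive from a single
master seed by fixed offsets, so a `SimConfig` determines every draw
bit-for-bit.

What the generator does **not** emulate: fragment-level structure,
doublets, batch effects beyond library intercepts, overdispersion beyond
the donor/library random effects, cell-type-discrete populations (states
are continuous mixtures), empirical LD blocks, or peak-sparsity
distributions matched to any particular tissue — the per-peak sparsity is
a tunable, since no reference distribution is fixed.  Passing tests
therefore certify the statistical machinery under the model's own
assumptions, not robustness to the full messiness of real scATAC data.

# Numerical choices and problem sizes

* PQL inner loop: tolerance $10^{-8}$ on coefficient change, max 50
  iterations; variance components floored at $10^{-8}$ (a zero component
  becomes an effectively infinite ridge, i.e. the random effect drops
  out).
* NMF: factors floored at $10^{-15}$ to keep multiplicative updates away
  from absorbing zeros; refinement steps backtrack (halving) until the
  objective does not decrease.
* RE2: $\tau^2$ grid of 50 log-spaced points spanning
  $[10^{-8}, 100 \max se_s^2]$, then golden-section refinement.
* Storey q-values: smoother over $\lambda = 0.05, \dots, 0.95$,
  cubic-spline df 3, evaluated at $\lambda = 0.95$, clipped to $(0, 1]$;
  fewer than 20 p-values falls back to $\pi_0 = 1$ (BH) with a warning.
* Calibration analyses run at 600 peaks x ~4,000 cells x 8 SNPs/peak
  with 1 permutation in the test suite and 3 in the acceptance script;
  recovery analyses use 100 replicates of a 40-donor x 100-cell peak;
  the dynamic-LRT type-I experiment uses 500 replicates of a 30-donor x
  15-cell peak.  These sizes were chosen as the smallest at which the
  binomial/Monte-Carlo error of each check is meaningfully smaller than
  the effect being asserted.

# Known limitations

* PQL standard errors ignore uncertainty in the variance components and
  are conservative when a real donor-level effect is absorbed by the null
  model's donor variance; for effect-size inference the `glmer` route is
  preferable, and the two are cross-checked in the tests.
* The RE2 p-value uses the asymptotic mixture null (see above).
* The colocalization model assumes a single causal variant per trait per
  region; no LD-aware or multi-causal extension is provided.
* Trajectories are definitionally topic loadings — no principal curves or
  graph pseudotime.
* The Wald z of `glmer` at `nAGQ = 0` is mildly anti-conservative at
  ~40 donors; use the PQL route (or permutation-based empirical p-values,
  `empiricalSignificance()`) when tail calibration matters.
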