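---
title: "Methods: regional structure-function coupling and its heritability"
author: "scfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional structure-function coupling and its heritability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scfc)
```

This vignette is the package's account of its statistical machinery:
the models it fits, the assumptions they carry, the parameters a user
may want to change, what the synthetic-data generator does and does not
emulate, and the numerical choices that were genuinely open.

## 1. Regional coupling

For subject-level SC and FC matrices on the same parcellation, the
coupling of region $i$ is the Spearman rank correlation between the SC
row $i$ and FC row $i$ over the $n-1$ off-diagonal entries. Choices and
their reasons:

* **Spearman, not Pearson.** SC weights from tractography are
  non-negative, heavily skewed and zero-inflated; rank correlation is
  invariant to any strictly monotone rescaling of either profile, which
  is the property the measure is meant to have.
* **Average ranks for ties.** Sparse SC rows contain many zeros. Any
  tie rule other than average ranks breaks monotone invariance, so
  average ranks are used everywhere, and the brute-force test oracle
  ("average-rank then Pearson") pins this down.
* **Undefined values stay undefined.** A region whose SC row is all
  zeros (or any row with fewer than 3 usable partners) gets `NA` with
  the partner count recorded. Substituting 0 would bias network
  summaries toward zero; downstream code excludes `NA`s listwise and
  reports exclusion counts.
* **Variants.** Within-network and between-network coupling restrict
  the partner set by the region's network label; single-hemisphere
  coupling restricts by hemisphere; the distance-partialled variant
  rank-transforms the two profiles and the Euclidean centroid distance,
  residualizes the profile ranks on the distance ranks by least
  squares, and correlates the residuals ("partial Spearman" read as
  partial correlation on average ranks — the conventional
  interpretation). Euclidean centroid distance is used; geodesic
  distance is a plausible alternative the input format cannot support.
* **Repeated FC measurements** are averaged entrywise on the
  correlation scale before coupling for all analyses *except*
  heritability, which uses each measurement separately — the
  within-subject spread across measurements is exactly what identifies
  the measurement-error variance.

Small networks deserve caution: a region in a 22-region network has 21
within-network partners, so its within-network coupling is noisy, and
regions alone in a partner set are flagged rather than computed.

## 2. Reliability

Agreement between two regional maps (test vs retest, original vs
replication group means; one point per region) is summarized by the
Bland–Altman bias $\bar d = \frac1n \sum d_i$ and limits of agreement
$\bar d \pm 1.96\, S_d$ with $S_d$ the $n-1$-denominator standard
deviation of paired differences — a 95% prediction interval for a new
difference under approximate normality. Differences are second argument
minus first (retest − test); the convention is documented because only
the signed bias depends on it. A Pearson agreement correlation with a
one-sided permutation $p$ accompanies the plot.

## 3. Regional covariate models

Per region, the Fisher $z = \operatorname{atanh}(\rho)$ transform of
coupling is regressed by OLS on an intercept plus ten covariates: age,
sex (female = 0, male = 1), years of education, total cognition score,
intracranial volume, in-scanner motion, and the four interactions
age×cognition, sex×cognition, education×cognition, ICV×motion.
Decisions:

* **Interactions are products of uncentered main effects** (a `center`
  flag is provided; centering changes only the interpretation of main
  effects, not the model fit or interaction tests).
* **Two-sided $p$-values** on $t = \hat\beta/\mathrm{se}$ with
  $n - 11$ degrees of freedom, since associations of either sign are of
  interest.
* **FDR per covariate across regions** (Benjamini–Hochberg at
  $\alpha = 0.05$): each covariate produces its own 392-region
  significance map, so multiplicity is controlled within a map. Pooling
  across covariates would be the stricter alternative; the per-map
  convention matches how such maps are reported and is applied
  uniformly.
* **Numerics.** Covariates are used on their natural scales (ICV is
  order $10^6$ mm³), so $(X^\top X)^{-1}$ is computed from the QR
  factorization of $X$, never from raw cross products, and the design
  is rejected as rank-deficient with the offending columns named.
* Handedness is recorded in the cohort table but not part of this
  design; it enters only the heritability models below.

## 4. The variance-components model

The heritability model for one regional phenotype stacks all subjects
and repeated measurements:

$$y_{ij} = x_{ij}\beta + g_i + c_i + e_i + \epsilon_{ij}$$

with additive genetic effect $g \sim N(0, \sigma^2_A K)$, common
(family) environment $c \sim N(0, \sigma^2_C \Lambda)$, unique subject
environment $e \sim N(0, \sigma^2_E I_{n_\mathrm{subj}})$ and
measurement error $\epsilon \sim N(0, \sigma^2_M I_{n_\mathrm{total}})$,
so that

$$\operatorname{cov}[y] = \sigma^2_A\, T K T^\top + \sigma^2_C\, T
\Lambda T^\top + \sigma^2_E\, T T^\top + \sigma^2_M\, I.$$

$K$ has 1 for MZ co-twins, $1/2$ for DZ co-twins and full siblings, 0
across families; $\Lambda$ is 1 for subjects sharing parents. Both get
unit diagonals — the original definitions only specify off-diagonal
entries, and unit self-similarity is the only choice yielding a valid
covariance. The subject-level effect $e$ carries a subject-sized
identity and the measurement-level $\epsilon$ a measurement-sized one;
this is the only dimensionally consistent reading and is what makes
$\sigma^2_E$ and $\sigma^2_M$ separable once subjects have repeated
measures.

**Heritability** is reported on the stable part of the variance:
$h^2 = \sigma^2_A / (\sigma^2_A + \sigma^2_C + \sigma^2_E)$. Measurement
error is excluded from the denominator deliberately: $h^2$ is then the
heritability of the trait, not of one noisy scan of it.

### Fitting

Restricted maximum likelihood, with fixed effects profiled out by
generalized least squares:

* **Parameterization.** Variances are optimized as $\log\sigma^2$ with
  a bounded quasi-Newton search (L-BFGS-B), which enforces
  non-negativity by construction rather than by post-hoc clipping; the
  lower bound sits ~9 orders of magnitude below the phenotype variance,
  and estimates pinned there are snapped to exactly zero and flagged as
  boundary solutions.
* **Multi-start.** Three starts — equal split, measurement-dominant,
  genetic-dominant — because boundary optima (a variance at 0) are
  common and a single interior start can miss them. Convergence is
  declared when the restricted log-likelihood improves by less than
  `tol` (default $10^{-8}$; the dense-oracle comparison in the tests
  runs both sides at $10^{-12}$).
* **Block factorization.** The covariance is block-diagonal over
  families, and families with identical (kinship pattern, measurement
  counts) have *identical* blocks, so each likelihood evaluation
  computes one Cholesky factor per unique pattern and whitens all
  families in that group in a single triangular solve. This is exact —
  no approximation — and is what makes per-region fits at 941 subjects
  × 4 measurements take well under a second, so the test suite can
  afford 20-replicate recovery experiments and 50-region sweeps.
* **Identifiability.** With one measurement per subject, $TT^\top = I$
  and $\sigma^2_M$ is inseparable from $\sigma^2_E$: the model drops
  $\sigma^2_M$ with a warning (this is the situation for SC node
  strength, which has a single measurement). With an all-singleton
  pedigree ($K = \Lambda = I$) the A/C/E split is unidentified; the
  total inter-subject variance is still estimated (reported in the
  $\sigma^2_E$ slot) but $\sigma^2_A$, $\sigma^2_C$ and $h^2$ are
  returned as `NA` with an `ace_inseparable` flag. A pedigree with only
  one level of within-family kinship (only MZ pairs, or only DZ/sib
  pairs) cannot separate A from C and is flagged, though the fit
  proceeds.
* **Standardization.** Regional phenotypes are z-scored across all
  stacked measurements before fitting (`standardize`), which fixes the
  variance scale without changing $h^2$ (a scale-free ratio). Whether
  covariates should also be standardized is immaterial to the variance
  components; node-strength covariates are z-scored for conditioning.
* **Covariates.** Age, sex and handedness in every model; SC and FC
  node strength are added for the coupling model (as region-matched
  fixed effects), so coupling heritability is not just node-strength
  heritability in disguise.
* No standard errors on $h^2$ are produced by default; medians and
  interquartile ranges across regions are the intended summaries, and a
  family-level bootstrap can be layered on by resampling pedigrees.

Regions whose phenotype contains undefined values are skipped with a
message rather than imputed.

## 5. Network statistics

Regional maps are summarized per network by median and quartiles using
**midpoint interpolation** (the quantile at fractional position
$(n-1)p$ is the mean of the two bracketing order statistics) — the rule
is test-pinned because quantile conventions differ. Pairwise network
contrasts use the pooled-variance unpaired $t$ (Welch available behind
a flag); the $t$ matrix is antisymmetric with an undefined diagonal.

One-sided $p$-values come from shuffling the region-to-network labels:
$p = (1 + \#\{t^\mathrm{null} \ge t^\mathrm{obs}\})/(1 + B)$, which is
valid (never 0) and deterministic given the seed. Defaults are
$B = 1000$ for map-level contrasts and $B = 10000$ for correlations
between regional maps. Label permutation ignores spatial
autocorrelation and is therefore **anti-conservative on smooth maps**;
the functions accept externally generated surrogate maps (e.g.
variogram-matched spatially autocorrelated nulls) through a
`surrogates` argument, and the permutation null is the self-contained
default, not a claim that regional maps are exchangeable.

## 6. The synthetic-data generator

The generator exists so every stage has inputs with known ground truth.
What it emulates, and how the defaults were set:

* **Pedigree**: 116 MZ pairs, 61 DZ pairs, 455 full siblings, 132
  singletons (941 subjects) — the composition of the young-adult twin
  cohort this methodology targets. Twin pairs form their own families;
  full siblings are grouped into sibships of 2–4 (uniformly at random
  given the seed; only the total sibling count is externally
  specified, so the sibship-size law is a configurable default, and the
  resulting family count is reported rather than pinned).
* **Covariates**: age $\sim N(28.67, 3.70^2)$ truncated to $[22, 37]$;
  P(male) $= 441/941$; education, cognition, ICV, motion and
  handedness from plausible young-adult ranges. Covariates are mutually
  independent and independent of family structure — real cohorts have
  ICV–sex and motion–age correlations the generator does not reproduce,
  so passing tests say nothing about confounding patterns in real data.
* **Phenotypes** are drawn *exactly* from the variance-components
  model: subject effects from the family-block multivariate normal
  (Cholesky per block), measurement error i.i.d. per scan. The
  closed-form MZ/DZ intraclass correlations (e.g.
  $(\sigma^2_A + \sigma^2_C)/(\sigma^2_A + \sigma^2_C + \sigma^2_E +
  \sigma^2_M/m)$ for MZ pairs with $m$-measurement means) are the
  Falconer-style checks the tests verify empirically.
* **Connectome pairs**: SC entries are zero-inflated log-normal
  (non-Gaussian, as tractography weights are), FC entries share a
  Gaussian-copula latent correlation $r$ with the SC latent scores and
  are mapped monotonically into $(-1,1)$. For continuous margins the
  population Spearman of a bivariate normal copula is
  $\rho_S = \frac6\pi \arcsin(r/2)$; a tie mass $p_0$ at zero
  attenuates this, so the calibration inverts the exact
  censored-margin expression (a one-dimensional quadrature) and reduces
  to the classical relation at density 1. Targets of $\pm 1$ map to
  $r = \pm 1$ and give coupling exactly $\pm 1$ only when the SC row is
  tie-free (density 1). Entries shared by regions with different
  targets use the mean of the two targets, so strongly heterogeneous
  target maps are matched approximately, not exactly. The generator
  produces no BOLD-like temporal autocorrelation and no
  distance-dependent tractography bias — the distance-partialled
  variant is validated against algebraic oracles, not against a
  simulated distance confound.

Every generator is a pure function of its arguments and seed: the
caller's RNG state is saved and restored, and identical calls are
bit-identical.

## 7. Problem sizes used in testing

The test suite and acceptance script choose sizes where Monte-Carlo
error is small relative to the tolerance being asserted: oracle
equivalence on 12-region fixtures (exact, 20 replicates); twin
correlations at 2000 pairs (±0.03 band, MC SE ≈ 0.013); heritability
recovery at the full 941-subject composition with 20 replicates for the
mean and three 50-region sweeps for the rank-correlation property
(a single sweep's rank correlation has sampling spread of several
hundredths because the A/C contrast rests on 177 twin pairs); FDR and
permutation calibration at 200–500 replicates. The pipeline smoke test
runs a deliberately small study (24 regions, 44 subjects) because it
checks orchestration, not statistics.

## 8. Known limitations

* Label permutation as the default null is anti-conservative under
  spatial autocorrelation (see §5); supply surrogate maps for
  spatially honest inference.
* The kinship kernel covers MZ/DZ twins, full siblings and singletons
  only; half-siblings or parent-offspring structures are rejected at
  the pedigree boundary rather than silently mismodelled.
* Heritability estimates at a few hundred twin pairs have substantial
  sampling error, and $\hat h^2$ for phenotypes with a true variance
  component near zero piles up at the boundary; flags mark boundary and
  identifiability conditions, but interpretation remains the user's.
* Subgroup filters that split twin pairs demote the remaining twin to
  full sibling (`subset_pedigree()`), which preserves all pairwise
  kernel entries among retained subjects but changes the label
  semantics; filters aligned with family structure are preferable.
* The package starts from connectivity matrices: no image processing,
  tractography, or time-series cleaning is performed or emulated.
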