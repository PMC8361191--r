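# scfc

Regional structure–function coupling of brain connectomes, and how
heritable it is.

## The problem

A brain region's *structural connectivity* (SC) profile is its row of a
weighted white-matter connection matrix; its *functional connectivity*
(FC) profile is its row of a matrix of Pearson correlations between
regional resting fMRI time series. How tightly the two profiles align —
the region's **SC–FC coupling** — varies across the brain, differs
between people, and those differences are partly genetic. This package
implements the full analysis for researchers who have per-subject SC/FC
matrices (or want to study the methodology on simulated ones):

* **Coupling**: per region *i*, the Spearman rank correlation between SC
  row *i* and FC row *i* over the n−1 off-diagonal entries
  (self-connection excluded), with within-network, between-network,
  distance-partialled and single-hemisphere variants, plus SC/FC node
  strength.
* **Reliability**: Bland–Altman bias d̄ = (1/n)Σdᵢ and limits of
  agreement d̄ ± 1.96·S_d (S_d with n−1 denominator), and agreement
  correlations with permutation p-values.
* **Association**: per-region OLS of Fisher-z coupling on age, sex,
  education, cognition, ICV and motion plus four interactions (10
  covariates), with Benjamini–Hochberg FDR at α = 0.05.
* **Heritability**: a repeated-measures variance-components model

      y_ij = x_ij β + g_i + c_i + e_i + ε_ij
      cov[y] = σ²_A·TKTᵀ + σ²_C·TΛTᵀ + σ²_E·TTᵀ + σ²_M·I

  with pedigree-derived kinship **K** (1 MZ, ½ DZ/full sibling, 0
  unrelated) and shared-environment **Λ** kernels, fitted by restricted
  maximum likelihood; the *non-transient heritability* is
  h² = σ²_A / (σ²_A + σ²_C + σ²_E), the genetic share of stable
  between-person variance with measurement error removed.
* **Network statistics**: per-network medians/quartiles, pairwise
  unpaired t contrasts and one-sided permutation p-values.

A synthetic-data module generates pedigrees (default: 116 MZ pairs, 61
DZ pairs, 455 full siblings, 132 singletons — 941 subjects), covariates,
exact ACE-model phenotypes and SC/FC matrix pairs whose population
regional coupling equals a chosen target, so the whole pipeline runs and
is testable with no restricted-access data.

## Worked example

```r
library(scfc)

ped    <- generate_pedigree(family_composition(20, 20, 40, 10), seed = 1)
cohort <- generate_covariates(ped, seed = 2)
truth  <- true_variances(0.4, 0.2, 0.4, 0.25)
phen   <- simulate_ace_phenotypes(ped, truth, cohort,
                                  n_measurements = 4, seed = 3)

d   <- stack_phenotype(phen, region = 1, cohort = cohort)
fit <- ace_reml(value ~ age + sex, d, ped, standardize = TRUE)
fit
#> Call: ace_reml(formula = value ~ age + sex, data = d, pedigree = ped,
#>     standardize = TRUE)
#> Variance components (ReML)
#>   measurements: 520, subjects: 130, families: 63
#>   additive genetic   (A): 0.3291
#>   common environment (C): 0.1314
#>   unique environment (E): 0.2348
#>   measurement error  (M): 0.2722
#>   heritability h2 = 0.4733
#>   restricted log-likelihood = -551.6766 (converged)
```

The four variances decompose the (z-scored) phenotype: genetic,
family-shared environment, subject-specific environment, and
within-subject scan-to-scan error, estimable because each subject is
measured four times. Here `h2 = 0.4733` says ~47% of the *stable*
between-person variance is genetic (the generating truth was
0.4/(0.4+0.2+0.4) = 0.4; a 130-subject pedigree estimates it with wide
sampling error — at the 941-subject default composition the estimates
concentrate around the truth, which is what the acceptance script
measures).

Coupling on simulated connectomes:

```r
parc <- default_parcellation(50)
pair <- simulate_connectome_pair(parc, target_coupling = 0.3,
                                 sc_density = 0.3, seed = 1)
cp   <- regional_coupling(pair$sc, pair$fc[[1]])
cp
#> Regional coupling (whole_brain), subject sim: 50 regions, 0 undefined
#>   mean 0.271, range [0.004, 0.556]
```

An end-to-end run (simulate → couple → reliability → GLM → heritability
→ network statistics) from one config:

```r
run_pipeline(list(seed = 1,
                  simulate = list(n_regions = 24, n_mz_pairs = 6,
                                  n_dz_pairs = 4, n_full_sibs = 12,
                                  n_singletons = 6)),
             out_dir = "scfc_run")
```

which writes coupling/strength phenotype tables, `reliability.json`,
`glm.tsv`, `h2.tsv`, `netstats.json` and a `summary.json` under a run
directory named by the config hash and seed.

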