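Package: scfc
Title: Regional Structure-Function Coupling and Its Heritability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies regional coupling between brain structural and
    functional connectomes as the per-region Spearman rank correlation of
    corresponding connectivity profiles, with within-network,
    between-network, distance-partialled and single-hemisphere variants.
    Provides test-retest and out-of-sample agreement statistics
    (Bland-Altman limits of agreement), mass-univariate regional models of
    coupling against demographics and cognition with false-discovery-rate
    control, and a repeated-measures variance-components model (additive
    genetic, common environment, unique environment, plus intra-subject
    measurement error) fitted by restricted maximum likelihood to estimate
    the heritability of stable, non-transient inter-subject variation.
    A synthetic-data module generates twin/sibling pedigrees, covariates,
    variance-component phenotypes and connectome pairs with known ground
    truth so the whole pipeline is testable without restricted-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
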