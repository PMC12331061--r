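Package: faersignal
Title: Disproportionality Signal Detection and Time-to-Onset Analysis for
    Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for FAERS-style spontaneous report
    databases: reads the quarterly '$'-delimited ASCII tables (DEMO, DRUG,
    REAC, THER, OUTC), deduplicates case versions by the FDA
    keep-latest-(FDA_DT, PRIMARYID) rule, selects primary-suspect reports for
    a target drug, and builds drug-event 2x2 contingency tables at the
    MedDRA preferred-term and system-organ-class levels. Implements four
    disproportionality statistics with their conventional signal thresholds:
    the reporting odds ratio (ROR), the proportional reporting ratio (PRR)
    with Yates-corrected chi-square, the Bayesian confidence propagation
    neural network information component (IC, Bate and Noren variants), and
    the multi-item gamma Poisson shrinker (MGPS) empirical Bayes geometric
    mean (EBGM) with a marginal-maximum-likelihood fitted two-component
    gamma mixture prior. Time-to-onset is modelled with a Weibull
    distribution (failure-type classification from the shape parameter) and
    compared between sexes with a Wilcoxon rank-sum test. A synthetic
    FAERS-like data generator with planted signals, duplicate case versions,
    demographic missingness and Weibull onset times provides ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    fitdistrplus,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
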