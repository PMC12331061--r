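---
title: "Methods: disproportionality screening and time-to-onset modelling in faersignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening and time-to-onset modelling in faersignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## Scope and data model

`faersignal` screens a spontaneous-report database for adverse-event
signals of one *index drug* against the background of all other drugs, and
models the time from treatment initiation to event. The input is the FAERS
quarterly-file dialect: `'$'`-delimited ASCII tables DEMO (one row per
report version), DRUG (drug rows with role codes), REAC (MedDRA preferred
terms, PTs), THER (therapy episodes) and OUTC (outcome codes). Two
properties of this data shape every design choice below:

* **No denominators.** Nothing is known about patients who took the drug
  and reported nothing, so all inference is *within* the report database
  (disproportionality), and the onset-time curve is a distribution of
  reported onsets, not a survival estimate.
* **Pervasive incompleteness.** Sex and age are missing in the large
  majority of reports, dates may be partial (`YYYY` or `YYYYMM`), and the
  same case is resubmitted repeatedly with a shared CASEID.

## Deduplication and cohort construction

Versions of a case are collapsed by the FDA-recommended rule: for each
CASEID keep the version maximising FDA_DT, breaking ties by the largest
PRIMARYID — implemented as a lexicographic maximum, so the operation is
deterministic and idempotent (`deduplicate_cases()`). The index cohort is
the set of deduplicated reports where a DRUG row matches the drug-name
pattern (case-insensitive substring over `drugname` and `prod_ai`) *and*
carries the primary-suspect role `PS`; name matches in concomitant roles do
not qualify. No fuzzy name normalisation is attempted.

## Contingency tables

The counting unit is the unique (report, PT) pair. A report mentioning
three PTs contributes three events; repeated mentions of one PT in a
report count once. For PT *p*, `a` is the number of index reports
mentioning *p*, `b` the remaining index pairs, `c`/`d` the analogues for
all other reports, and `E = (a+b)(a+c)/N`. SOC-level tables are sums of
member-PT pair counts without re-deduplication, so SOC "case counts" are
event counts — the convention that makes SOC proportions sum to 100% of
all events. The comparator is the full ingested corpus minus the index
reports; no stratification of expected counts by age, sex or year is
applied.

## The four statistics

* **ROR** `= ad/bc` with the Woolf interval on the log scale. Tables with
  a zero cell receive the Haldane–Anscombe `+0.5` on all four cells for
  ROR and PRR only; the Bayesian estimators handle zeros natively and are
  left exact.
* **PRR** `= [a/(a+b)]/[c/(c+d)]` (Evans formulation, comparator = other
  drugs) with its delta-method interval, plus the χ² statistic with the
  Yates continuity correction computed on the *uncorrected* counts and
  clamped at zero. The classical criterion "PRR ≥ 2 and χ² > 4" was
  defined with Yates in the early pharmacovigilance literature, so Yates
  is the default; the uncorrected statistic is available via
  `yates = FALSE`.
* **BCPNN IC.** Two documented variants are computed side by side.
  The *Bate* variant places the standard Beta posteriors (prior constants
  α₁ = β₁ = γ₁₁ = 1, α = β = 2) on the joint and marginal reporting
  probabilities. We evaluate the **exact** posterior mean and variance of
  `IC = log2(p_xy/(p_x p_y))` using digamma/trigamma identities for
  moments of log-Beta variables, rather than the historical
  log-of-expectation approximation: the exact moments are what a
  Monte-Carlo simulation of the same posterior converges to, which makes
  the estimator testable against sampling to within Monte-Carlo error.
  `IC025 = E(IC) − 2√V(IC)`. The *Norén* variant is the later shrinkage
  form `IC = log2((a+½)/(E+½))` with the closed-form credibility bound
  `IC − 3.3(a+½)^{−1/2} − 2(a+½)^{−3/2}`.
* **MGPS EBGM.** The relative reporting rate λ of each cell is modelled as
  `a | λ ~ Poisson(λE)` with mixture prior
  `p·Gamma(α₁, β₁) + (1−p)·Gamma(α₂, β₂)` (shape/rate). The five
  hyperparameters are fitted by maximising the marginal (negative-binomial
  mixture) likelihood over **all drug–event cells of the corpus with
  a ≥ 1**, starting from the classical initialisation
  (0.2, 0.1, 2, 4, 1/3). The optimisation runs on log/logit-transformed
  parameters under box bounds (|log parameter| ≤ 12, |logit weight| ≤ 7):
  when one mixture weight approaches a boundary the other component
  becomes unidentified, and unbounded optimisers then leave it at
  arbitrary values; the bounds, plus one restart on a "false convergence"
  stop, keep the fit well-behaved. Non-convergence is reported via a
  `converged` flag and a warning, never an error. EBGM is the posterior
  geometric mean evaluated in closed form with digamma functions; EBGM05
  solves `CDF(q) = 0.05` of the posterior gamma mixture by root-finding.

A pair is a *signal* only when all four criteria hold (`PRR ≥ 2` and
`χ² > 4`; ROR lower bound > 1; `IC025 > 0`; `EBGM05 > 2`) and the pair has
at least `min_cases = 3` reports — the conventional minimum for
spontaneous-report signals. Which IC variant feeds the combined rule is
configurable (`ic_variant`); the default is Norén, whose observed-to-
expected shrinkage form is the current practice in large databases. No
multiple-testing adjustment is applied: the screen is the four-criteria
rule itself, and its operating characteristics are validated empirically
(below) rather than controlled analytically.

## Time to onset

Onset is `event date − earliest complete therapy start date` in whole
days. Partial or missing dates on either side exclude the report (with a
tally — attrition is part of the result), negative intervals are excluded
and tallied, and day-0 onsets are set to 0.5 days so the Weibull
likelihood (support t > 0) is defined; the half-day value is configurable.
Partial dates are never imputed.

The Weibull fit maximises the log-likelihood over (log α, log β) with
BFGS; 95% intervals are Wald intervals on the log scale from the observed
information, which keeps all bounds positive. The reported median and IQR
are empirical statistics of the data — for a Weibull(187.21, 0.73) the
*fitted* median would be `α(ln 2)^{1/β} ≈ 113` days, which is a different
quantity and is not reported as the cohort median. The failure-type label
is a total function of the shape interval: upper bound < 1 → early
failure, lower bound > 1 → wear-out, otherwise random failure.

The binned onset distribution uses 0–30, 31–60, 61–90, 91–180, 181–360
and >360 days. Only the first, fifth and last of these edges are forced by
common reporting practice; the intermediate edges follow the usual
time-to-onset convention and are configurable. The cumulative curve is the
empirical CDF of reported onsets — with no at-risk denominators a survival
estimator would be meaningless.

Sex comparison uses the Wilcoxon rank-sum test on the full onset
distributions (not a median test). With ≤ 10 records per group the
two-sided p-value is computed by exact enumeration of all
`choose(n, n₁)` rank assignments using midranks, so ties are handled
exactly; larger samples use the normal approximation with tie and
continuity correction. The switch at 10 keeps enumeration
(≤ 184,756 assignments) instantaneous.

## The synthetic generator

`generate_faers_dataset()` emulates the features of a single-drug FAERS
cohort that the pipeline must survive: duplicate case versions differing
only in FDA_DT and PRIMARYID (strictly increasing, so keep-latest
semantics are observable); sex missing at 83% and age at 85% by default;
events as independent Bernoulli draws per (case, PT) with marginal rates
summing to 3.5 expected events per case (a 1/√rank decay over a 50-PT
synthetic vocabulary); planted signals that multiply the reporting
probability of chosen PTs by λ among index cases only, so the generative
relative reporting rate is known exactly; onset times drawn from
sex-specific Weibull laws — by default shape 0.73 for both sexes with
scales 234 d (female) and 140 d (male), i.e. the early-failure pattern
with a sex shift around a 187-day overall scale; therapy start dates
truncated to `YYYY`/`YYYYMM` in 10% of cases and event dates missing in
35%, exercising partial-date exclusion; about 60% serious reports with
FAERS outcome codes. Identical seed and configuration give byte-identical
files. The PT vocabulary and PT→SOC map are synthetic (`pt_001`,
`soc_01`, …) because MedDRA is licensed; analyses of real extracts must
supply their own map.

What the generator deliberately does **not** emulate, and what passing
tests therefore do not demonstrate about real data: correlated events
(PT co-occurrence is independent given the drug), drug–drug confounding,
country- or reporter-specific reporting propensities, secular reporting
trends, masking of one signal by another, or misspelled drug names. The
generator validates the *machinery* — estimators, rules, accounting — not
the epidemiology of any real cohort.

## Validation design and problem sizes

The test suite validates every estimator against an independent route:
ROR/PRR/χ² against hand-evaluated formulas; Bate IC against Monte-Carlo
sampling from its posterior (10⁶ draws per cell on a 12-cell grid, within
3 Monte-Carlo standard errors); EBGM and EBGM05 against quadrature of the
unnormalised posterior density to 10⁻⁶ relative accuracy; the Weibull MLE
against an independent fitting package; the large-sample Wilcoxon against
the reference implementation and the small-sample path against exhaustive
enumeration. Operating characteristics are measured on generated corpora:
200 simulated cohorts of 397 onset times from Weibull(187.21 d, 0.73)
(mean shape error and interval coverage), and 20 corpora of 20,000 cases
with three planted λ = 10 signals (all planted PTs flagged, zero
background PTs flagged in the reference runs). These sizes keep the full
suite under a minute of compute while leaving Monte-Carlo margins that are
small relative to the tested tolerances.

## Known limitations

* Disproportionality measures association within a reporting database,
  not incidence or causation; all the usual FAERS caveats (underreporting,
  notoriety effects, confounding by indication) apply to any real-data use.
* The MGPS fit is unstratified; in heterogeneous databases stratified
  expected counts can change EBGM materially.
* The exact enumeration Wilcoxon is limited to 10 per group by design;
  permutation p-values for intermediate sizes are not implemented.
* The pipeline returns plot-ready tables (binned distribution, ECDF) but
  does not write image files.
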