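# faersignal

Disproportionality signal detection and time-to-onset analysis for
spontaneous adverse-event reports in the FAERS dialect.

## The problem

Spontaneous-report databases such as the FDA Adverse Event Reporting System
(FAERS) collect millions of individual case safety reports but have no
denominators: there is no count of patients exposed and unharmed. Safety
screening therefore relies on *disproportionality*: a drug–event pair is
interesting when the event is reported for the drug more often than the
drug and event margins would predict under independence. `faersignal`
implements the full screening pipeline for one target drug against the rest
of the database:

1. **Ingestion** of the quarterly `'$'`-delimited ASCII tables (DEMO, DRUG,
   REAC, THER, OUTC), keeping partial dates raw rather than guessing.
2. **Deduplication** by the FDA rule: of all versions sharing a CASEID, keep
   the one maximising (FDA_DT, PRIMARYID).
3. **Primary-suspect selection**: reports where a DRUG row both matches the
   drug-name pattern and carries the `PS` role code.
4. **Contingency construction** at MedDRA preferred-term (PT) and
   system-organ-class (SOC) level, counting unique (report, PT) pairs, with
   a user-supplied PT→SOC map (MedDRA is licensed and is not shipped).
5. **Four disproportionality statistics** per 2×2 table
   (`a, b, c, d` with `N = a+b+c+d`, expected count `E = (a+b)(a+c)/N`):
   - reporting odds ratio `ROR = ad/bc` with Woolf interval
     `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`;
   - proportional reporting ratio `PRR = [a/(a+b)] / [c/(c+d)]` with its
     log-scale interval and the Yates-corrected χ²;
   - BCPNN information component, both the Bate variant (exact posterior
     moments of `log2(p_xy / p_x p_y)` under the standard Beta priors) and
     the Norén variant `IC = log2((a+½)/(E+½))` with its credibility bound;
   - MGPS `EBGM = exp(E[ln λ | a])` under a two-component gamma mixture
     prior on the relative reporting rate λ, fitted by marginal maximum
     likelihood over **all** drug–event cells of the corpus, with `EBGM05`
     the posterior 5th percentile.
6. **Combined signal rule**: a pair with at least 3 reports is flagged only
   when *all* criteria hold: `PRR ≥ 2` and `χ² > 4`; ROR lower 95% bound
   `> 1`; `IC025 > 0`; `EBGM05 > 2`.
7. **Time to onset**: days from THER therapy start to DEMO event date
   (partial dates excluded and tallied, day-0 mapped to half a day),
   summarised by Weibull maximum likelihood. A shape β with upper
   confidence bound below 1 indicates a decreasing reporting hazard
   ("early failure"); sex differences are tested with a Wilcoxon rank-sum
   test, exact by enumeration in small samples.
8. **Descriptives**: the "Table 1"-style cohort summary with explicit
   "Not specified" rows, since demographic missingness in FAERS is itself
   a finding.

A synthetic FAERS-like generator (`synthetic_config()`,
`generate_faers_dataset()`) produces schema-valid quarterly files with a
ground-truth ledger — planted signals with known relative reporting rate,
duplicate case versions, configurable missingness, Weibull onset times —
so every stage is testable end to end without downloading anything.

## Worked example

```r
library(faersignal)

res <- run_pipeline(list(
  simulate = list(n_reports = 5000,
                  planted_signals = c(pt_045 = 6, pt_050 = 12),
                  seed = 1),
  output_dir = "faers_report"))

res$top_by_frequency[, c("label", "a", "ror", "prr", "chi2", "ebgm", "ebgm05")]
#>    label   a   ror   prr chi2 ebgm ebgm05
#> 1 pt_050 246 14.53 12.92 1034 5.39   4.85
#> 2 pt_045 121  5.01  4.77  225 3.28   2.82

res$tto$fit
#> Weibull time-to-onset fit
#>   n = 296 records; empirical median 148.50 d (IQR 46.00-315.50)
#>   scale alpha = 225.62 d (95% CI 194.08-262.28)
#>   shape beta  = 0.799   (95% CI 0.732-0.871)  -> early failure
```

The corpus of 5,000 cases (5,749 report versions; 749 duplicates removed)
contains two planted signals on the index drug and both — and only both —
are flagged by the combined rule. The ROR of `pt_050` (14.5) exceeds its
generative relative reporting rate of 12 slightly because the odds ratio
inflates over the rate ratio at non-rare event probabilities, while the
shrunk EBGM sits closer to the corpus-wide prior. The 296 reports with
complete therapy-start and event dates give a Weibull shape below 1: the
reporting hazard declines with time on drug, i.e. most adverse events are
reported early in treatment. The output directory holds the same results
as CSV plus `manifest.json` with the seed and every attrition count;
rerunning the same configuration reproduces the files byte for byte.

For real FAERS extracts, point `input_dir` at a directory of quarterly
files, supply `drug_patterns` and a `pt_to_soc` CSV (columns `pt`, `soc`)
derived from a licensed MedDRA distribution.

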