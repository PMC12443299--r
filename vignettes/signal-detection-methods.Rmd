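---
title: "Disproportionality signal detection: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection: models, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous adverse-event reporting systems such as FAERS collect safety
reports for all marketed drugs, with no denominator of exposed patients.
Signal detection therefore asks a relative question: is event *E* reported
**disproportionately often** among the reports that name drug *D*,
compared with reports for all other drugs? The unit of analysis is the
2×2 "four-grid" table for one drug–event pair:

|                 | event *E* | other events | total |
|-----------------|-----------|--------------|-------|
| drug *D*        | a         | b            | a+b   |
| all other drugs | c         | d            | c+d   |
| total           | a+c       | b+d          | N     |

`faersignal` builds these tables from raw quarterly report files and
screens them with four disproportionality statistics whose *joint*
exceedance defines a signal. A signal is a hypothesis for pharmacological
follow-up, never proof of causation.

## The five statistics

All ratio statistics are computed in log space and exponentiated last;
intervals are Wald intervals on the log scale.

* **ROR** (reporting odds ratio): $(a/c)/(b/d)$, with
  $SE(\ln ROR) = \sqrt{1/a + 1/b + 1/c + 1/d}$ and 95% CI
  $\exp(\ln ROR \pm 1.96\,SE)$.
* **PRR** (proportional reporting ratio): $[a/(a+b)]\,/\,[c/(c+d)]$, with
  $SE(\ln PRR) = \sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)}$.
* **Pearson χ²**: $N(ad-bc)^2 / [(a+b)(c+d)(a+c)(b+d)]$, **without**
  Yates continuity correction. The uncorrected form is the one that
  reproduces the published reference rows this package checks itself
  against; Yates would shift the large-count rows by about 0.1%.
* **EBGM**: the relative reporting ratio $aN/[(a+b)(a+c)]$, i.e. the
  observed count over its expectation under independence. This is the
  *crude* ratio: no gamma-Poisson (MGPS) shrinkage is fitted. That choice
  is deliberate — the reference tables this package reproduces satisfy
  $IC = \log_2 EBGM$ row for row, which only holds for the crude form
  (a shrunk EBGM would be pulled toward 1 at small counts, e.g. for a
  seven-report PT). The lower bound is
  $EBGM05 = \exp(\ln EBGM - 1.645\,SE)$ with the same $SE$ as the ROR.
  The 1.645 multiplier (a one-sided 5th percentile) rather than 1.96 is
  again fixed by the reference rows: the published EBGM05 values (e.g.
  78.59 for a table with EBGM 82.41 and $SE \approx 0.0289$) are
  consistent only with 1.645. Both multipliers are exposed
  (`ebgm_z` argument).
* **IC** (BCPNN information component): point estimate
  $\log_2\!\big(aN/[(a+b)(a+c)]\big)$, identical to $\log_2 EBGM$ by
  construction. The lower credibility bound `ic025` is Bayesian:
  $E(IC) - 2\sqrt{V(IC)}$ with the Bate et al. (1998) posterior moments
  under priors $\alpha_1=\beta_1=\gamma_{11}=1$, $\alpha=\beta=2$, and
  $\gamma$ tied to the margins so the prior IC is centred at zero (see
  `?ic_stat` for the expressions). Published IC lower bounds in this
  domain are frequently not reproducible from any single documented
  formula; this package therefore implements the standard Bayesian bound
  with fully documented priors and does not attempt to imitate any
  particular implementation's bound.

**Thresholds.** The combined criterion (`evaluate_signals()`) requires,
simultaneously: $a \ge 3$, $ROR \ge 3$ with CI lower limit $> 1$,
$PRR \ge 2$ with CI lower limit $> 1$, $IC025 > 0$, and $EBGM05 > 2$.
Requiring all four algorithms to agree trades sensitivity for a low
false-positive rate; the null-calibration study below quantifies this.

**Zero cells.** No automatic continuity correction is applied: a zero
cell produces an `NA` statistic with a reason flag, and flagged rows can
never be signals but remain visible in exports. A Haldane–Anscombe
`+0.5` switch exists (`haldane = TRUE`) for users who prefer finite
estimates; it is off by default so that defaults stay auditable.

## From raw files to tables

* **Dialect.** Quarterly `$`-delimited `DEMO/DRUG/REAC/OUTC` files, one
  header line, post-2012 column names (`primaryid`, `caseid`,
  `caseversion`). Legacy files carrying `isr` are accepted by treating
  ISR as the version id. Unparseable rows are counted in the run log,
  never silently dropped.
* **Deduplication.** A case may be submitted repeatedly as updated
  versions. For each `caseid` exactly one version is kept: maximal
  `caseversion`, ties broken by latest receipt date, then lexicographically
  largest `primaryid`. The rule is idempotent, never invents records, and
  the retained version's drug/event/outcome mentions replace all others.
* **Drug-name normalization.** Names arrive as free text (brands,
  misspellings, study codes). Matching against the synonym dictionary is
  case-insensitive after trimming surrounding whitespace/punctuation and
  collapsing internal whitespace. Unmatched mentions are flagged and
  counted, not guessed.
* **Ages** are converted to years from the FAERS unit codes
  (`YR/MON/WK/DY/HR`). `DEC` is ambiguous in legacy documentation and is
  deliberately read as years, with a counter in the log; converted ages
  ≥ 150 become missing. Age bands in summaries are `<65`, `65–75`
  (lower-inclusive, so exactly 75 falls in `≥75`), `≥75`, unknown.
* **Counting unit.** Cells count (case, PT) *pairs*, with a PT repeated
  inside one case counted once (`dedup_within_case`, switchable).
  Event-level counting is the only unit consistent with published
  SOC-level totals that far exceed the case count; within-case
  de-duplication is the conservative reading and the one the synthetic
  generator's closed-form expectations assume.
* **Target side.** A case is on the target side only when the target
  ingredient is its *primary suspect* (role `PS`); cases naming it as
  secondary suspect/concomitant/interacting stay in the comparator
  (`ps_only = FALSE` switches to any-role). Introducing a third
  "excluded" class would change the margins in ways the screened
  statistics do not model.
* **SOC aggregation** uses one primary SOC per PT (multi-axial MedDRA
  membership would double-count pairs); PTs missing from the vocabulary
  accumulate in an explicit `"unmapped"` bucket so conservation
  `Σ SOC = Σ PT` always holds. MedDRA itself is licensed content and is
  not shipped; the vocabulary loader takes any two-column PT→SOC table.
* **Outcomes.** When a case carries several outcome codes, descriptive
  summaries count it once under the most severe, with precedence
  `DE > LT > DS > CA > RI > HO > OT` (death … other). Exclusive
  categories are what make the summary percentages sum to 100; the exact
  order is this package's convention, and `outcome_mode = "multi"`
  counts every code instead.

## The synthetic report generator

Real FAERS extracts are huge, unversioned, and carry licensed
vocabulary, so validation runs on a generator
(`synthetic_config()` / `generate_faers()`) whose ground truth is known
exactly:

* each case draws one primary-suspect drug uniformly from `n_drugs`;
* its number of reaction PTs is zero-truncated Poisson with mean
  `background_rate` (default 2 PTs per report, a typical spontaneous-
  report multiplicity);
* each PT slot is categorical over `n_events` terms, uniform except that
  a planted signal (drug $g$, event $e$, ratio $\lambda$) tilts the
  weight of $e$ to $\lambda$ for cases whose suspect drug is $g$. The
  planted $\lambda$ is thus the true reporting-rate ratio the four
  statistics estimate;
* a `duplicate_fraction` of cases is emitted twice: the later version
  carries the authoritative content and an earlier version misses one PT,
  which makes "keep latest" observably different from "keep first";
* a `variant_fraction` of drug mentions is written as a brand name,
  a misspelling, or a decorated string, all covered by the emitted
  dictionary, so normalization is testable against truth;
* demographics (sex, age band, reporter, country, outcome) follow the
  category frequencies of a typical spironolactone reporting cohort:
  slight female majority, strong elderly skew, health-professional
  reporters in the majority, US the largest single country, and
  hospitalization the leading serious outcome (see
  `default_demographics()`).

`expected_cell_counts()` gives the exact closed-form expectation of every
cell: with $K$ zero-truncated Poisson($\mu$) and per-slot probability $q$,
the probability that an event appears in a case is
$1 - (e^{-\mu q} - e^{-\mu})/(1 - e^{-\mu})$, and each cell is a sum of
such inclusion probabilities. Duplicates and name variants cancel out of
the expectations because deduplication retains the canonical content and
the dictionary resolves every variant.

What the generator does **not** emulate: correlated co-prescription,
pharmacologically structured event profiles, secular reporting trends
across quarters, or free-text noise beyond the dictionary's variants.
Passing the validation suite therefore demonstrates correctness of the
counting and inference machinery under a known model — not performance on
the full messiness of real reports.

## Operating-characteristic studies

Two properties are checked on every run of the test suite, using the
generator's *table-level* Monte Carlo path (`simulate_pair_tables()`):
each replicate draws the four cells of one pair from a multinomial with
probabilities proportional to the closed-form expectations and total
size equal to the expected pair count. This is the sampling distribution
the file-level pipeline produces for a pair (with the total pair count
held at its expectation) and costs microseconds per replicate; the
file-level path (generate → read → deduplicate → normalize → count) is
exercised end-to-end in the integration tests at smaller scale.

* **Null calibration.** With every $\lambda = 1$ (20 drugs, 40 events,
  20,000 cases, so $E[a] \approx 56$ per table), the 95% ROR interval
  covers 1 in about 95% of 1,000 replicates, and the combined
  four-algorithm criterion flags essentially none of them (the ROR ≥ 3
  requirement alone sits more than seven null standard errors away).
* **Parameter recovery.** Planted $\lambda \in \{5, 20, 100\}$ are
  recovered by EBGM within ±25% in well over 95% of 100 replicates. The
  study designs keep the planted pair a small share of both margins
  (drug share $\lambda/n_{drugs} \le 5\%$ and event tilt
  $\lambda/n_{events} \le 5\%$), because the crude observed/expected
  ratio estimates $\lambda$ only up to factors of
  $1 + (\lambda-1)(p_g + w_e + \ldots)$ — with a dominant drug the
  planted pair contaminates its own expectation denominator, exactly the
  regime in which published EBGM values fall far below the matching ROR.
  Cohort sizes are set from the closed form to give $E[a] \approx 300$
  pairs, where the ±25% window sits more than 2.5 coefficient-of-
  variation units from the estimand.

## Reconstructing published rows

Published signal tables print, per term, the count `a` and the point
estimates of ROR, PRR and EBGM to two decimals. These over-determine the
hidden cells: eliminating $d$ between the ROR and PRR equations gives
$b = a(PRR-1)/(ROR-PRR)$ *independently of* $c$; $c$ then follows in
closed form from the EBGM equation and $d = ROR\,bc/a$. `solve_counts()`
rounds the analytic solution and refines over a small integer
neighborhood, minimizing the maximum relative deviation of the three
recomputed statistics (ties toward smaller cells, so the solver is
deterministic). When the printed precision cannot separate two of the
ratios the corresponding margin is only bounded below, and the solver
falls back to a documented large-margin family that reproduces the
printed values exactly in the limit.

This turns a printed table into an executable check: recomputing the
*independently printed* quantities — CI bounds, χ², IC, EBGM05 — on the
reconstructed cells must agree with print. The bundled transcription of
55 reference rows all reconstruct with point-statistic residuals below
0.05%. Two honest caveats, visible in `check_goldens()` output rather
than hidden: rows whose printed ROR equals their printed PRR leave `b`
(hence χ² and the CI widths) unidentified at printed precision; and a
few printed interval bounds are not reproducible from *any* integer
table (the worst needs a non-integer comparator count), indicating
rounding inside the original computation. The quantities used as
headline checks are all from well-identified rows and agree to within
0.15%.

## Worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(
  n_cases = 20000, n_drugs = 100, n_events = 500,
  planted_signals = data.frame(drug = 1, event = 1, lambda = 100),
  duplicate_fraction = 0.1, variant_fraction = 0.2, seed = 23)
gt <- generate_faers(cfg, "quarter_dir")
run <- detect_signals("quarter_dir", "24Q3", "DRUG_0001")
head(run$pt[, c("pt", "a", "ror", "ror_lo", "prr", "chi2",
                "ic", "ic025", "ebgm", "ebgm05", "combined")])
run$cohort
```

The planted pair appears at rank 1 by ROR with `combined = TRUE`; the
run log reports the stage counts (rows read, cases after deduplication,
unresolved names, unmapped PTs) that make the cleaning auditable.

## Known limitations

* The EBGM here is the crude relative reporting ratio; users wanting
  shrinkage estimates at very small counts should fit MGPS elsewhere —
  adding it would break the $IC = \log_2 EBGM$ identity the reference
  tables exhibit.
* Wald intervals are first-order; at $a \lesssim 5$ their coverage is
  approximate (the null-calibration study runs at $E[a] \approx 56$).
* No multiplicity adjustment is applied across the thousands of PTs
  screened — standard practice for hypothesis *generation*, but another
  reason a flagged pair is not a finding.
* Stratified (age/sex/period) tables and drug–drug interaction screens
  are out of scope.
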