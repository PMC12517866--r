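---
title: "Case/non-case signal detection for FAERS spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case/non-case signal detection for FAERS spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous-report databases such as the FDA Adverse Event Reporting
System (FAERS) collect voluntary post-marketing reports of suspected
adverse drug reactions. They have no denominator — nobody knows how many
patients took a drug uneventfully — so incidence cannot be estimated.
What can be estimated is *disproportionality*: whether a drug and an
adverse event are co-reported more often than the rest of the database
would predict. `faersignal` implements the standard case/non-case
screening design for that question: reports carrying the target event
(defined at the MedDRA system organ class, SOC, level) are "cases", all
other reports are "non-cases", and exposure is restricted to reports
naming the study drug as the *primary suspect* (role code PS). The
running example throughout the package is the screen of two statins
(ATC C10AA05 and C10AA07) against the respiratory, thoracic and
mediastinal disorders SOC (MedDRA 10038738).

## Data model and deduplication

FAERS ships as quarterly `$`-delimited ASCII tables. The package models
five of them as typed records (DEMO, DRUG, REAC, THER, OUTC; RPSR and
INDI are readable stubs, since no analysis touches them). Reading is
header-driven and deliberately lenient: a malformed age or id becomes
`NA`, never an error — a single dirty row must not abort a quarter.

One case (CASEID) may appear as several report versions (PRIMARYID).
The FDA-recommended rule keeps, within each case, the version with the
most recent receipt date (FDA_DT), breaking ties by the highest
PRIMARYID. `deduplicate_reports()` implements exactly that rule. It is
idempotent and permutation-invariant, and the survivor count equals the
number of distinct cases. Two deliberate plumbing choices:

* Partial dates (`YYYY`, `YYYYMM`) are ordered inside deduplication by
  padding the absent month/day with 01. Receipt dates are 8-digit in
  practice, so this only buys robustness; it is *not* used to impute
  analysis dates.
* Deduplication runs *before* the receipt-window filter. The
  alternative order can keep a superseded in-window version whose
  replacement arrived after the window; deduplicating first treats the
  database state, not the extract, as primary. The window itself is a
  quarter range applied to FDA_DT, because that is how FAERS quarterly
  files are organized.

## Exposure, cases, and counting rules

Exposure: a report is exposed to a drug iff it has at least one DRUG row
for that drug with role PS. Secondary-suspect, concomitant and
interacting rows never create exposure — this is the usual guard against
confounding by co-medication. Drug names are resolved against a
name→ATC dictionary by exact match after normalization (case folding,
whitespace collapsing, stripping of trailing dose tokens such as
"20MG"). There is deliberately no fuzzy matching: in a disproportionality
screen a false exposure is worse than a missed one. The bundled
dictionary covers the study drugs with salt and brand synonyms plus
common co-medications; it is a plain TSV users can replace.

Cases: a report is a case iff any of its preferred terms (PTs) maps to
the target SOC — once per report, however many target PTs it carries.
PT→SOC mapping uses a single primary SOC per PT; the bundled map
(`meddra_pt_soc_synthetic.tsv`) is a constructed stand-in for the
licensed MedDRA dictionary, in a format a real MedDRA export can drop
into. Unmapped PTs never create cases and are tallied for QC.

Per-PT tables count *reports*, not reaction rows (duplicate rows of the
same PT within a report count once). Whether published top-PT tables
count reports or rows is typically not stated; the once-per-report rule
is the conservative choice and is flagged here as an interpretation.
Reports naming both study drugs as PS contribute to both per-drug
analyses.

## The two statistics

For a drug–event pair, the 2×2 table of report counts is

|            | target event | other events |
|------------|--------------|--------------|
| drug (PS)  | a            | b            |
| all others | c            | d            |

with the whole deduplicated universe as comparator, for PT-level events
as well as the SOC. The reporting odds ratio is

$$\mathrm{ROR} = \frac{ad}{bc}, \qquad
95\%\,\mathrm{CI} = \exp\!\Big(\ln \mathrm{ROR} \pm 1.96
\sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d}\Big)$$

(Woolf interval, the constant 1.96 used verbatim). Any zero cell makes
the estimate undefined — the package returns a marker, not an exception,
and applies no continuity correction by default. A Haldane +0.5
correction is available behind a flag for exploratory output only; it
cannot affect decisions because the signal rule requires $a \ge 10$
anyway.

The BCPNN information component is reported in its observed/expected
form,

$$\mathrm{IC} = \log_2 \frac{a\,(a+b+c+d)}{(a+b)(a+c)},$$

the log2 of how many times more often the pair is co-reported than
independence predicts. Its interval is $\mathrm{IC} \pm 2\sqrt{V(IC)}$
with $V(IC)$ from the closed-form posterior variance of the standard
BCPNN parameterization (all Beta/Dirichlet hyperparameters at their
conventional values: $\alpha_1=\beta_1=1$, $\alpha=\beta=2$,
$\gamma_{11}=1$, $\gamma$ scaled to the margins). A delta-method
variance, $(\ln 2)^{-2}(1/a - 1/(a{+}b) - 1/(a{+}c) + 1/n)$, is
selectable via `ic_variance = "delta"`; the choice is recorded in the
run metadata.

Two design points deserve a note:

* **Interval centring.** The field's shorthand "E(IC) ± 2√V(IC)" is
  ambiguous about whether the centre is the posterior mean or the
  reported point estimate. Centring on the posterior mean breaks the
  elementary ordering $IC_{025} \le IC \le IC_{975}$ on strongly
  disproportional small-count tables (the unshrunk point estimate can sit
  more than 2 posterior standard deviations above the shrunk mean). The
  package therefore centres the interval on the reported point estimate,
  which preserves the ordering by construction and reproduces the
  IC/IC025 spacing seen in published screening tables. When $a = 0$ the
  plug-in IC is undefined and the posterior mean is returned with a
  `shrunk` flag.
* **No multiplicity correction.** Screening practice reports each
  PT-level test at face value; the package follows suit but attaches the
  number of tests performed (`n_tests`) so users can post-correct.

A pair is a **signal** only when both arms agree: ROR lower 95% bound
above 1 with at least 10 co-reported cases, *and* IC025 above 0. The
conjunction is conservative by design; under planted-null simulation its
false-signal rate is well below the 5% a single arm would spend. All
comparisons use unrounded values; the two-decimal half-up rounding in the
report tables is presentation only.

## Subgroups and cross-stratification

Two different contrasts share the ROR code path:

* **Subgroup analysis** (exposure contrast): the report universe is
  restricted to a demographic stratum and the usual drug-vs-rest 2×2 is
  built inside it. The comparator is stratum-matched — a published
  subgroup table rarely states whether the denominator is the stratum or
  the full database, and the stratum-matched choice is the one that makes
  the subgroup ROR interpretable as "within this demographic"; it is
  flagged as an interpretation.
* **Cross-stratification** (demographic contrast): restricted to reports
  exposed to the drug, the 2×2 has rows stratum-vs-reference and columns
  event-vs-other-events. Strata must be disjoint, and
  $\mathrm{ROR}(A\,\mathrm{vs}\,B)\cdot\mathrm{ROR}(B\,\mathrm{vs}\,A)=1$
  exactly — the reciprocal structure visible in published
  cross-stratification tables, which is what motivates this reading of
  their construction.

Age bins are half-open, $[18, 75)$ and $[75, \infty)$ — the "18–74" /
"≥75" convention; where a summary table prints "18–75" it is the same
bin relabeled. Reports with unknown sex or missing age are excluded from
any stratum that conditions on the missing field, and only from those.
Subgroup RORs on a partition do not pool to the overall ROR
(non-collapsibility of the odds ratio); the test suite pins this with a
Simpson's-paradox fixture so nobody "fixes" it later.

## Time to onset

For each exposed case report, time to onset is the event date minus the
*earliest* complete therapy start date for that drug, in whole days.
Only day-resolution dates enter; partial or missing dates and negative
intervals are excluded (each exclusion tallied, nothing imputed).
Summaries are the median and IQR using linear interpolation between
closest order statistics (quantile type 7) — the convention under which
integer day counts produce fractional summaries such as 14.5 or 3.25
days, which is how published onset medians acquire half-day values.

## The synthetic generator

`generate_faers()` produces FAERS-schema datasets with known ground
truth so every stage is testable without any download. Case status
follows a per-report logistic model

$$\mathrm{odds}(\mathrm{case}) = \mathrm{odds}_0 \times
\theta^{\,\mathrm{exposed}} \times s(\mathrm{stratum}),$$

where the planted multiplier $\theta$ acts on reporting *odds*, so it is
exactly the estimand of the ROR — parameter recovery is a sharp test,
not an approximation. The generator emulates the features the pipeline
must survive: duplicate case versions with perturbed receipt dates and
random id order (so both tie-break branches of the dedup rule are
exercised), role-coded drug rows including target drugs in non-PS roles,
1–3 PTs per report (so the once-per-report case rule matters), partial
dates, missing sex/age/country, dose-token and brand-name noise in drug
names, and log-normal onset intervals wired consistently into THER start
and DEMO event dates.

Default parameters are the study conditions of the motivating screen,
chosen once: planted $\theta$ of 2.05 and 1.90 for the two statins (the
SOC-level point estimates of the motivating study), a ~52/40/9
female/male/unknown sex mix, ~19% missing age with an age mixture whose
median is in the mid-60s, 20% duplicate-version rate, and onset
medians of 7 and 14.5 days with log-scale spread back-solved from the
published interquartile ranges (sdlog 3.4 and 4.0). With both drugs
planted, each drug's comparator arm contains the other drug's elevated
reports, attenuating realized RORs by roughly 2% — visible in
calibration runs and accepted as realistic; single-drug configurations,
where $\theta$ is exactly the estimand, are used for estimator-recovery
validation.

What the generator does **not** emulate: co-prescription structure,
free-text drug-name noise beyond dose tokens, reporting-rate drift over
calendar time, event seasonality, or informative missingness. Passing
tests therefore demonstrate that the *methods* are implemented correctly
under known truth — not that real FAERS extracts are free of the biases
(underreporting, notoriety effects, confounding) that disproportionality
cannot remove.

## Validation sizes and numerical choices

The test suite validates, at fixed seeds chosen in advance:

* formula agreement of ROR/CI/IC with a 50-digit arbitrary-precision
  oracle on 200 random tables (tolerance 1e-9);
* exact recovery of the generator's survivor map by the dedup rule at
  10,000 reports with a 20% duplicate rate, plus idempotence and
  permutation invariance;
* estimator recovery at planted $\theta \in \{1, 2, 4\}$: 100 seeds per
  $\theta$ at n = 100,000 reports, median realized ROR within 5% of
  $\theta$, and Woolf-interval coverage of $\theta$ pooled across the
  300 replicates inside 93–97% (pooling trades per-$\theta$ resolution
  for a Monte-Carlo standard error below 1.3 points);
* null behavior: with $\theta = 1$ and expected $a \approx 20$
  (n = 20,000), the dual criterion fires in fewer than 5% of 1,000
  datasets;
* concentration: median absolute log-ROR error decreases monotonically
  across n = 5,000 / 20,000 / 80,000 (8 seeds each);
* onset: type-7 summaries against an independently coded interpolation,
  and recovery of a planted log-normal median (sdlog 1.5 in the test
  configuration) within 10% from ~5,000 onset records.

Smaller numerical decisions, all deliberate: half-up rounding (not
banker's) for printed percentages; ties in top-PT rankings break
alphabetically; undefined estimates propagate as `NA` plus a reason code
rather than exceptions; onset intervals in the generator are capped at
6,000 days to keep the log-normal tail from generating absurd calendar
dates; percentages in demographic tables use per-drug case totals as
denominators (combined total for the "Total" column).

## Limitations

The package screens; it does not adjudicate. RORs from spontaneous
reports are not risks, the dual criterion is a hypothesis generator, and
no adjustment for confounding is attempted (none is possible in this
design). Multi-axial MedDRA linkage, other members of the statin class,
regression-based shrinkage methods (EBGM, Bayesian logistic) and
Weibull onset modeling are out of scope.
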