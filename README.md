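# faersignal

Case/non-case disproportionality screening for FAERS-style spontaneous
adverse-event reports.

Spontaneous-report databases (FAERS and its peers) have no denominator,
so they cannot yield incidence — but they can flag drug–event pairs that
are reported *disproportionately* often. `faersignal` implements that
screen end to end for pharmacoepidemiologists and drug-safety teams:

* **Data model & IO** — readers/writers for the quarterly `$`-delimited
  ASCII tables (DEMO, DRUG, REAC, THER, OUTC), lenient on dirty fields,
  strict on schema.
* **Deduplication** — the FDA-recommended rule: per CASEID keep the most
  recent FDA_DT, ties broken by highest PRIMARYID.
* **Cohorts** — exposure from primary-suspect (PS) drug rows resolved
  against a name→ATC dictionary; cases from PTs rolling up to a target
  MedDRA system organ class (once per report).
* **Statistics** — for each drug–event 2×2 with counts `a,b,c,d`:

      ROR   = ad / bc
      95%CI = exp( ln ROR ± 1.96 √(1/a + 1/b + 1/c + 1/d) )
      IC    = log2( a·n / ((a+b)(a+c)) ),   n = a+b+c+d
      IC025 = IC − 2 √V(IC)      (closed-form BCPNN posterior variance)

  A pair is a **signal** only if the ROR lower bound exceeds 1 with
  a ≥ 10 *and* IC025 > 0 (dual criterion).
* **Subgroups** — sex/age subgroup RORs (stratum-matched comparator) and
  within-drug cross-stratification (stratum vs reference; exactly
  reciprocal).
* **Time to onset** — event date minus earliest complete therapy start,
  median/IQR by type-7 interpolation, exclusions tallied.
* **Synthetic FAERS** — a generator with planted reporting-odds
  multipliers, duplicate versions, missingness and partial dates, so the
  whole pipeline is testable with known ground truth and no download.

## Worked example

```r
library(faersignal)

cfg <- synthetic_config(n_reports = 50000, seed = 42)  # default study conditions
ds  <- generate_faers(cfg)
res <- run_faers_pipeline(pipeline_config(data = ds, seed = 42), quiet = TRUE)
print(res)
```

```
<pipeline_result>
  reports: 67548 raw -> 50000 deduplicated -> 49862 in window
  cases: 2672; disproportionality tests: 88
  atorvastatin (SOC): ROR 2.62 (2.17-3.16), IC 1.23, IC025 0.96 *signal*
  rosuvastatin (SOC): ROR 1.85 (1.48-2.32), IC 0.81, IC025 0.48 *signal*
```

67,548 report versions collapse to 50,000 distinct cases; 2,672 are
respiratory-SOC cases. Both planted drugs (odds multipliers 2.05 and
1.90) are flagged by the dual criterion; the realized RORs differ from
the planted values by sampling noise. Drill-down tables come from the
same result object:

```r
res$top_pt$atorvastatin       # ranked PTs with report counts and shares
#>                     pt_name  n   pct
#> 1                  Dyspnoea 26 20.16
#> 2                     Cough 14 10.85
#> 3 Interstitial lung disease 12  9.30
#> ...
res$onset$atorvastatin$summary
#> <onset> atorvastatin: n=107, median 6 days (IQR 1-83.5)
```

`res$demographics`, `res$subgroups` and `res$cross_strata` hold the
demographic summary and the stratified RORs; `write_pipeline_outputs()`
(or `out_dir =` in the config) writes everything as TSV plus a
`run_metadata.json` with version, variance choice, seed and stage
counts.

Real FAERS extracts run through the same entry point via
`pipeline_config(paths = list(demo = ..., drug = ..., reac = ...))`,
with your licensed MedDRA export supplied as a four-column TSV in place
of the bundled synthetic PT→SOC map.

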