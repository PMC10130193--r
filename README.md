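# pvsignal

Disproportionality signal detection for spontaneous adverse-event report
databases in the four-table JADER layout (demo / drug / reac / hist),
built around the question: do oral antiplatelets and anticoagulants —
alone or in combination — show a reporting signal for intraocular
hemorrhage (IOH)?

The package is aimed at pharmacoepidemiologists and pharmacovigilance
analysts. It implements the full analysis path as composable,
tibble-in/tibble-out functions:

* **ETL** — read, validate, deduplicate and link the four tables into a
  case-level database with a complete provenance log
  (`read_jader_db()`, `link_tables()`).
* **Cohort definitions** — oral exposure to ten target antithrombotics,
  mono/dual/triple therapy categories by exact class set, the 17-PT IOH
  event definition, SMQ comorbidity flags, ocular-injection drug use,
  younger/elderly age groups (`build_cohort()`).
* **Signal statistics** — for a 2×2 patient-level table with cells
  N11, N10, N01, N00 and margins N1+, N+1, N++:

  - reporting odds ratio ROR = (N11·N00)/(N10·N01), 95% CI
    exp(ln ROR ± 1.96·√(1/N11+1/N10+1/N01+1/N00)), `NA` on any zero cell;
  - BCPNN information component
    E(IC11) = log2[(N11+γ11)(N+++α)(N+++β) / ((N+++γ)(N1++α1)(N+1+β1))]
    with priors γ11 = 1, α1 = β1 = 1, α = β = 2, variance V(IC11) per the
    standard BCPNN form, and 95% interval E ± 2√V;
  - the dual signal criterion: lower ROR limit > 1 **and** lower IC
    limit > 0 (`signal_stats()`, `run_signal_table()`).

* **Factor analysis** — per-drug multivariable logistic regression of IOH
  on hypertension, diabetes and injection-drug use, with principled NA
  reporting for separated covariates (`fit_logistic()`, broom-style
  `tidy()`/`glance()`).
* **Time to onset** — days from first administration to first IOH with a
  720-day cap, exclusion of partial dates, medians/IQRs and the standard
  bin distribution (`compute_onset_periods()`, `summarize_tto()`).
* **Synthetic data** — a generator for JADER-schema databases with exact
  ground truth, including planted reporting-rate multipliers,
  missingness, and duplicates (`generate_database()`,
  `scenario_presets()`).
* **Margin calibration** — `infer_event_margin()` recovers the one
  unprinted margin (total IOH-reporting cases N+1) from a published
  table's rows by integer grid search, making printed tables fully
  recomputable.

## Worked example

The aspirin-monotherapy row of a published signal table gives
N11 = 61 IOH cases among N1+ = 19,200 aspirin-monotherapy cases, in a
cleaned database of N++ = 688,467 with N+1 = 1,586 IOH-reporting cases:

```r
library(pvsignal)
signal_stats(contingency_from_margins(n11 = 61, n1p = 19200,
                                      np1 = 1586, npp = 688467))
#>     ror ror_low ror_high    ic ic_low ic_high  signal
#>   1.396    1.08    1.803 0.454   0.08   0.828    TRUE
```

Aspirin IOH reports are 1.40 times as frequent as expected under
independence; both lower limits clear their thresholds (ROR CI low
1.08 > 1, IC CI low 0.08 > 0), so the pair signals.

The same machinery runs end-to-end on synthetic data:

```r
cfg <- scenario_presets(seed = 2024, n_cases = 50000)[["paper-like"]]
cohort <- build_cohort(as_jader_db(generate_database(cfg)$tables))
run_signal_table(cohort)
#>           category total_aes events    ror ror_low     ic ic_low signal
#> 1    mono:apixaban       402      4  3.595  1.3228  1.213 -0.109  FALSE
#> 2     mono:aspirin      1236      1  0.278  0.0388 -1.186 -3.243  FALSE
#> ...
#> 7 mono:rivaroxaban       325     10 11.927  6.2029  2.507  1.588   TRUE
```

At 50,000 cases (7% of the original database) only the strongest planted
multiplier (rivaroxaban, 8.84×) is detectable — smaller planted effects
produce elevated RORs whose IC intervals still span zero, which is the
dual criterion doing its job at small counts. `plot_signals()` draws the
corresponding forest plot, and `run_all()` executes the whole pipeline
(cleaning → cohort → signal tables → factor analysis → time-to-onset)
from a YAML config, writing CSV tables and a JSON run manifest.

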