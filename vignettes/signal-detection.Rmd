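---
title: "Disproportionality signal detection for intraocular hemorrhage under antithrombotic therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for intraocular hemorrhage under antithrombotic therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem and the data model

Spontaneous reporting systems such as Japan's JADER collect voluntary
reports of suspected adverse drug reactions. Each report (a *case*) links a
demographic record to the drugs reported, the adverse events coded as
MedDRA preferred terms (PTs), and the patient's primary diseases. pvsignal
analyses such databases for intraocular hemorrhage (IOH) signals under oral
antiplatelet and anticoagulant therapy — ten target drugs in four classes
(aspirin; the P2Y12 inhibitors clopidogrel, ticagrelor, ticlopidine,
prasugrel; warfarin; the DOACs apixaban, dabigatran, edoxaban,
rivaroxaban) — taken alone or in combination.

The unit of counting throughout is the *patient*: a case contributes at
most one to any cell of any contingency table, regardless of how many
matching drug records or event PTs it carries.

### Cleaning

Cases with blank or unknown sex or age are excluded; exact duplicate rows
within each table are collapsed to their first occurrence; drug, event and
history records whose case identifier no longer resolves to a retained
demographic record are dropped. Every step logs its in/out/dropped counts
in a provenance record, and the identity `records_in = records_out +
records_dropped` holds at each step. Duplicate detection is exact-tuple
equality within one table; report-version reconciliation (which would need
regulator-specific metadata) is deliberately out of scope.

### Exposures, events, covariates

A case is exposed to a target drug when at least one drug record names it
(after synonym normalization — salt forms such as "clopidogrel sulfate"
map to "clopidogrel") with the oral route. All three involvement
categories (suspected, concomitant, interaction) count. Therapy categories
partition the cases: `mono:<drug>` for exactly one target drug; seven
analyzed combination groups defined by the *exact* set of classes present
(aspirin+P2Y12, aspirin+warfarin, aspirin+DOAC, P2Y12+warfarin,
P2Y12+DOAC, and the triples aspirin+P2Y12+warfarin, aspirin+P2Y12+DOAC);
`other-combination` for any other multi-drug pattern; `unexposed`
otherwise. The exact-set rule keeps mono/dual/triple rows disjoint and
non-nested, which is what makes their side-by-side comparison meaningful.
Exposure ignores timing and overlap of drug records: spontaneous reports
rarely carry reliable stop dates, so co-reporting within one case defines
combination therapy.

The event is defined by 17 PTs under the HLT "Ocular haemorrhagic
disorders" (shipped as `ioh_pts()`); hypertension and diabetes comorbidity
flags come from the corresponding SMQ PT sets applied to the history
table; the injection-drug covariate flags the intravitreal / posterior
sub-Tenon agents, with triamcinolone acetonide counted only under an
ocular-injection route. Age groups split younger ("under 10s"–"60s") from
elderly ("70s"–"100s").

## The signal statistics

For one therapy category and the event, the 2×2 table counts N11 (category
and event), N10 (category, no event), N01 (other cases with the event),
N00 (neither), with margins N1+ = N11+N10, N+1 = N11+N01 and total N++.

**Reporting odds ratio.** ROR = (N11·N00)/(N10·N01) with the log-scale
Wald interval exp(ln ROR ± 1.96·√(1/N11 + 1/N10 + 1/N01 + 1/N00)). When
any cell is zero the ROR is reported `NA` — no Haldane continuity
correction — because the published tables this package is designed to
reproduce print `NA` rather than a corrected value.

**BCPNN information component.** The IC is the log2 Bayesian shrinkage
estimate of the observed-to-expected reporting ratio, with prior constants
γ11 = 1, α1 = β1 = 1, α = β = 2 and the per-table joint prior
γ = γ11·(N+++α)(N+++β)/((N1++α1)(N+1+β1)):

$$E(IC_{11}) = \log_2 \frac{(N_{11}+\gamma_{11})(N_{++}+\alpha)(N_{++}+\beta)}
 {(N_{++}+\gamma)(N_{1+}+\alpha_1)(N_{+1}+\beta_1)}$$

$$V(IC_{11}) = \frac{1}{(\ln 2)^2}\!\left[
 \frac{N_{++}-N_{11}+\gamma-\gamma_{11}}{(N_{11}+\gamma_{11})(1+N_{++}+\gamma)}
 + \frac{N_{++}-N_{1+}+\alpha-\alpha_1}{(N_{1+}+\alpha_1)(1+N_{++}+\alpha)}
 + \frac{N_{++}-N_{+1}+\beta-\beta_1}{(N_{+1}+\beta_1)(1+N_{++}+\beta)}\right]$$

with the 95% credibility interval E ± 2√V (the conventional ±2, not
±1.96). The IC is defined even at N11 = 0, where shrinkage pulls it
strictly below zero; this is exactly why it complements the ROR for rare
exposures. We implement the standard published BCPNN form of these
equations; the test suite checks the implementation against an
independently transcribed copy of the formulas to 1e-12 on randomly drawn
tables.

**Dual signal criterion.** A category signals only when the lower 95%
limit of the ROR exceeds 1 *and* the lower limit of the IC exceeds 0.
Requiring both guards against false positives from small counts, where the
unshrunk ROR interval alone can clear 1 while the shrunk IC interval still
spans 0.

**Stratified tables.** For age subgroups all four cells are computed
within the stratum (the standard stratified practice); a `comparator =
"global"` flag retains the whole-database comparator instead, since
published reports do not always state which convention they used.

**Margin calibration.** Published signal tables typically print N11 and
N1+ per row and the database total N++, but not the total event-reporting
count N+1. Because every row shares the same N+1, `infer_event_margin()`
recovers it by integer grid search: the value minimizing the number of
rows whose recomputed ROR fails to round (half-up, two decimals) to the
printed value, ties broken downward, with a hard failure when no candidate
reproduces at least half the rows. This turns a printed table into a fully
checkable set of statistics.

## Factor analysis

Within the reports of each target drug, the occurrence of the event is
regressed on three binary covariates — hypertension, diabetes, and
injection-drug use — by maximum-likelihood logistic regression
(`fit_logistic()`): Newton/IRLS with step-halving whenever a step would
decrease the log-likelihood, convergence at max |score| < 1e-8 within 25
iterations. These mechanics are deterministic and exposed in the fit
object (iteration count, final gradient norm, likelihood trace), which is
what the package's property tests assert; `stats::glm` serves as an
independent cross-check in the test suite. Wald 95% intervals
exp(β ± 1.96·SE) and two-sided Wald p-values are reported, matching the
default inference of the common GUI front-ends for R.

A covariate is reported with status `NA` — rather than silently dropped
or allowed to diverge — when its 2×2 table against the outcome has an
empty cell (separation or zero variance), or when its coefficient
magnitude exceeds 15 during iteration; the model is then refit without
it. This mirrors how published multivariable tables show `NA` for drugs
with, say, no injection-drug users among their reports. The factor-model
population is "all cases reporting the drug" in any therapy context;
restricting to monotherapy is a config choice the caller can make by
subsetting the cohort.

## Time to onset

The onset period is the day count from the earliest full-precision start
date of the drug to the first full-precision onset date of an event PT,
with the administration day counted as day 1 (so a same-day onset gives
period 1; a `day_one = FALSE` switch counts elapsed days instead, since
reporting conventions differ and the choice is not observable from
published summaries). Cases with missing or partial dates on either side,
or onset before start, are excluded — the operational reading of "missing
or inaccurate" dates. Periods beyond 720 days are capped at 720 and
flagged; capped values land in the final (≥361 days) bin and never change
the membership of any earlier bin. Summaries (median, quartiles by linear
interpolation of order statistics, and the standard 8-bin distribution)
are produced only for drugs with strictly more than 10 evaluable cases;
the exact quantile rule behind any given published median is generally not
recoverable, so the interpolation type is an explicit argument.

## The synthetic-data generator

`generate_database()` emulates the statistical structure the analysis
assumes, with exact bookkeeping: demographics from configurable band
distributions; per-drug Bernoulli exposures with an aspirin
co-prescription odds multiplier (default 2, reflecting how often
antithrombotics are co-prescribed with aspirin); the event as a per-case
Bernoulli whose log-odds is a baseline plus the sum of exposed-drug and
covariate effects — the simplest model under which the reporting odds
ratio is the estimand; event PTs drawn uniformly from the 17-code set on
top of a disjoint synthetic background vocabulary, so event flagging is
unambiguous; history PTs for the comorbidities; Weibull onset delays
(default shape 0.9, scale 120 days — early-peaked, long-tailed onset,
which is how bleeding events on antithrombotics distribute); and
missingness injected last (default 3% blank sex, 3% blank age, 5%
partial dates, 1% exact duplicates — rates in the range seen in real
spontaneous-report extracts).

The default drug table plants the published per-drug exposure fractions
and log reporting-rate multipliers equal to the log of the published
monotherapy RORs, and the default baseline event probability is the
event-reporting fraction of the cleaned database (1586/688467), so the
default configuration is a scaled-down replica of the study population.
Presets: `"null"` (all multipliers 1 — no true signals), `"paper-like"`
(the defaults), `"separation"` (no injection users, exercising the NA
path of the factor model).

What the generator does *not* emulate: reporting dynamics over calendar
time, stimulated-reporting waves, correlated event co-reporting, and
report-version duplicates that are not byte-identical. Tests passing on
synthetic data therefore validate the pipeline's arithmetic and
bookkeeping, not the clinical validity of any signal on real data.

## Numerical choices and problem sizes

Report-output rounding is half-up to two decimals, matching how published
tables round. The grid search for the unprinted margin runs over
[1000, 3000] by default. Test simulations use 1,200–120,000 cases per
replicate and 200 replicates for the null false-positive coverage check —
sizes chosen so each check exercises the asymptotics it targets while the
whole suite stays comfortably interactive; the coverage property itself
(≤5% of drugs flagged under the null) is scale-free because both criteria
must fail jointly.

## Known limitations

The package reproduces report-level disproportionality, which measures
reporting association, not incidence or causal risk. Deduplication is
exact-row only. Drug-name normalization is a flat synonym table, not a
general Japanese-label normalizer. No multiple-testing adjustment is
applied to signal tables, and no PRR/EBGM-style alternative shrinkers are
provided — the dual ROR/IC criterion is the method implemented.
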