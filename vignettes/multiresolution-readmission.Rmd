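---
title: "Multi-resolution temporal features for readmission risk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-resolution temporal features for readmission risk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrtempo)
```

This vignette is the package's own account of its method: the data model,
the convolution filter bank, the evaluation protocol, the synthetic
generator, and the design choices made where the design was genuinely open.
It states no empirical result beyond what the package's tests and
`scripts/acceptance.R` compute themselves.

## From records to event series

The unit of raw data is a timestamped entity instance: one row per
occurrence, with a patient id, an entity code, an entity class (diagnosis,
admission, emergency, medication, ...), a kind, a start date and an optional
end date. Two kinds of entities are distinguished:

* **point** entities occupy a single instant (a coded diagnosis, a
  dispensed medication, an ED presentation);
* **continuing** entities span an interval (a hospital stay) and count once
  in *every* time unit they overlap after discretization.

Calendar time is discretized by a `timeline()` into units 1, ..., T. Both
daily and monthly units are supported; a month is fixed at 30 days so that
all bandwidth, delay, horizon and lookback conversions are deterministic and
independent of calendar irregularities. The default unit is the month: the
bank's bandwidths are month-valued, and monthly units keep desk-scale
experiments fast without changing any downstream arithmetic (with daily
units every month-valued parameter is multiplied by 30).

Three boundary rules are worth stating explicitly:

* a continuing entity with a missing end date counts in its start unit only
  (conservative: no unbounded spans);
* events starting after the end of the timeline are dropped with a warning,
  not an error (robust ingest);
* overlapping stays of the same entity sum, so per-unit counts can exceed
  one. Whether overlaps should saturate at 1 instead is genuinely
  underdetermined; summing is the linear choice and keeps the convolution's
  superposition property exact.

An entity schema may organize codes into a forest (e.g. procedure codes
under higher-level categories). `expand_hierarchy()` duplicates every event
onto all its ancestors, so parent-level series aggregate their descendants.

## Vocabulary control

The number of series M is bounded by two heuristics, applied per entity
class: codes seen fewer than `min_count = 50` times are pooled into a
reserved rare pseudo-code (a code seen exactly 50 times is kept), and only
the `max_size = 2000` most frequent codes are retained. Ties at the cut rank
are broken lexicographically so the vocabulary is a pure function of the
data. Occurrence counts are computed on the derivation period only (events
before the validation point): counting on the full database would let
validation-period frequencies influence the feature space, a mild but
avoidable leak.

## The one-sided filter bank

Each kernel has a bandwidth σ and a delay h, in months. The feature for
series E and kernel K at assessment point t is the one-sided convolution

\[
X(t) \;=\; \sum_{u=0}^{t-1} K(u - h)\, E(t - u),
\]

so only units at or before t contribute, and a delay h blanks out the most
recent h units entirely. Two families are implemented:

* **uniform**: K(u) = 1/σ for 0 ≤ u < σ, else 0. The support is half-open
  in discrete time so that the kernel's mass is exactly 1 — X is then the
  mean event rate over the window, and a single event contributes 1/σ. (The
  closed-support variant 0 ≤ u ≤ σ would carry mass (σ+1)/σ in discrete
  time.)
* **one-sided Gaussian**: K(u) = √(2/πσ²) e^{−u²/2σ²} for u > 0, else 0,
  emphasizing recent events. It is evaluated pointwise at integer offsets
  without renormalizing the discrete sum; its continuous integral over
  (0, ∞) is 1, and tests verify that property numerically.

The default bank is uniform with (σ, h) ∈ {(1,0), (3,0), (6,0), (12,0),
(12,12), (12,24)}: short-, medium- and long-range summaries of the last
year, plus two delayed year-wide windows reaching 12–24 and 24–36 months
back. Feature assembly caps history at 36 months, which is exactly the
default bank's support; a wider custom bank is truncated at the cap.

Feature columns are named `class:code|family|sigma|delay` (σ, h in months)
in series-major order, so column layouts are byte-identical across runs.
`temporal_features()` evaluates the whole block sparsely with windowed
joins; a property test pins it to the literal per-series convolution at
tolerance 1e-12.

Because the u = 0 term includes the assessment point's own unit, labels must
not: see the next section.

## Assessment points, labels, and the temporal split

An assessment point (AP) is a (patient, time) unit of analysis. In
`discharge` mode an AP is placed at every discharge at or after the
patient's first diagnosis with a configured disease code; by default only
emergency-flagged ("unplanned") discharges qualify, with a flag to admit all
discharges. A `fixed_date` mode places APs at configured calendar dates for
already-diagnosed patients.

The label for horizon H is 1 iff an admission carrying the emergency flag
starts in the half-open window (t, t + H]. Two choices deserve comment:

* *"Unplanned" means emergency-flagged.* Administrative data cannot
  distinguish planned from unplanned admissions reliably; flagging
  admissions that arrive through the emergency department is the pragmatic
  operationalization, and the synthetic generator plants exactly this flag.
* *Same-unit admissions are excluded.* Since features include the AP's own
  unit (the u = 0 term), counting a same-unit readmission as outcome would
  let the label leak into the features. Labels are therefore monotone in H
  and start strictly after the AP.

The derivation/validation split is disjoint in patients **and** time:
patients with any AP strictly before the validation point form the
derivation cohort (their later APs are discarded — they are not independent
units and would straddle the boundary); all remaining patients form the
validation cohort. An AP exactly at the validation point therefore belongs
to validation.

## Baseline comorbidity features

The baseline feature sets are the 30 Elixhauser comorbidity indicators
mapped from ICD-10 diagnosis codes with the Quan coding table, shipped as a
plain CSV (`inst/extdata/elixhauser_icd10_quan.csv`) so the mapping is
auditable. The published table has 31 categories with hypertension split
into uncomplicated/complicated; the two are combined here to give the
conventional 30 indicators. Matching is case- and dot-insensitive prefix
matching. The Quan hierarchy exclusions (complicated diabetes supersedes
uncomplicated; metastatic cancer supersedes solid tumour) are applied by
default and can be disabled. Codes are collected from all records in a
closed lookback window [t − L, t] — the AP's own admission included, since
the baseline is meant to summarize the index stay — with L = 1 month and
36 months giving the `baseline_1M` and `baseline_3Y` sets.

Demographic features are age in years at the AP (continuous; binning adds a
discretization parameter with no evident benefit), a binary gender
indicator, and a one-hot postcode encoding over categories seen at least 50
times among derivation rows (reusing the rare-event threshold); rarer
derivation postcodes share a pooled column and postcodes never seen in
derivation get all-zero indicators.

## Normalization, model, and AUC

Every feature is min–max normalized to [0, 1] and then square-rooted; the
per-column min and max are fitted on derivation rows only, validation values
outside the fitted range are clipped into [0, 1] before the square root, and
constant columns map to zero. The square root spreads out the small-value
mass of sparse count features.

The scorer is elastic-net logistic regression via `glmnet` with mixing
parameter α = 0.5 and the regularization strength chosen by 5-fold
cross-validation on the derivation rows (cross-validated AUC when each class
has at least 8 observations per fold, otherwise binomial deviance, which is
stable in small strata). Fold assignment is seeded, so fits are reproducible.
The penalty is tuned separately per (feature set, horizon) pair — sharing one
strength across horizons would couple otherwise independent fits for no
statistical gain. A design in which no column varies admits only the
intercept solution, which is returned directly (intercept = prevalence
log-odds). No class reweighting is applied.

Validation performance is the AUC computed as the normalized Mann–Whitney U
statistic (ties count 0.5 — the c-statistic), with a 95% CI from the
Hanley–McNeil variance under a normal approximation, clipped to [0, 1]. The
package computes this statistic itself; tests pin it to exhaustive pair
enumeration and to an independent ROC implementation.

## The synthetic generator

No public hospital database matches this data regime, so the package ships a
generator (`simulate_ehr()`) that emulates the structural features the
framework assumes:

* a 9-year monthly timeline (long enough for a 36-month lookback on both
  sides of a temporal split, which is placed at month 72 by default);
* 2,000 patients with demographics (age ~ N(65, 15²) truncated to [18, 95],
  gender, Zipf-distributed postcodes);
* admission episodes (continuing entities, mean 2.5 per patient, ~40%
  emergency) carrying point diagnosis and medication events whose codes
  follow Zipf(1.3) distributions over 400 and 200 codes — heavy-tailed
  enough that a sub-50-count rare tail always exists and the vocabulary
  pooling is genuinely exercised;
* ambient emergency-department visits (mean 3 per patient over the span,
  about one visit per three patient-years) in addition to the ED visit that
  accompanies every emergency admission. Without the ambient visits the
  same-month ED count would be nearly constant across unplanned discharges
  and the planted effect below would carry no recoverable variance;
* a per-discharge Bernoulli readmission with logistic hazard: baseline
  log-odds qlogis(0.15), +1.0 per ED visit in the discharge month (the
  (1, 0)-kernel window) and +1.0 per occurrence of a designated risk
  diagnosis in the trailing 12 months (the (12, 0)-kernel window). The risk
  code (R07.4, chest pain) deliberately maps to no Elixhauser category, so
  the comorbidity baseline cannot see that part of the signal. A planted
  readmission is realized as a new emergency admission after a lognormal gap
  whose median drifts from 3 toward 5 months across the study span,
  stressing the temporal split with exactly the kind of calendar
  non-stationarity real readmission data show;
* half the patients carry the cohort-defining disease code (J44.9), attached
  at their first admission.

`planted_truth()` maps each nonzero effect to the feature column expected to
carry it, which is what the recovery tests check: over 10 seeds at these
conditions, the auto-extracted feature set must beat the comorbidity
baseline on validation AUC in at least 8, its mean AUC must exceed 0.60, and
with both effects set to zero the mean validation AUC over 5 seeds must stay
within [0.45, 0.55]; additionally the largest-magnitude temporal coefficient
of the elastic net must land on a planted column in at least 8 of 10 seeds.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: coded-diagnosis error and drift, correlated
comorbidity structure, within-patient heterogeneity of admission intensity,
informative censoring by death, and seasonal patterns. The generator's
purpose is structural: to exercise every pipeline stage and to carry a known
planted signal, not to be epidemiologically faithful.

## Numerical choices and problem sizes

* Uniform kernel mass is exact (half-open support), and the convolution
  oracle tolerance is 1e-12 absolute.
* The sparse block extractor and the per-series convolution are pinned to
  each other; the temporal block, demographic and comorbidity columns are
  concatenated sparse and densified only for the min–max transform.
* Ties: vocabulary ranks break lexicographically; AUC ties count 0.5 via
  midranks.
* Degenerate inputs: empty record sets give empty-but-valid vocabularies and
  zero series; single-class labels and empty cohorts are errors by design;
  an all-constant design returns the intercept-only fit.
* Test problem sizes: unit and property tests run on timelines of 24–120
  months with tens of patients; the recovery experiment runs the full study
  conditions (2,000 patients, 10 planted + 5 null seeds, 6-month horizon,
  the horizon at which the planted hazard yields the most balanced labels).
  The whole suite completes in roughly two minutes on one CPU.

## Known limitations

* The 30-day month makes unit conversion exact but shifts calendar dates by
  up to 1.5% per year relative to true months; all internal arithmetic is
  consistent, but external date joins should go through `date_to_index()`.
* Elixhauser mapping is prefix-based; it does not implement the handful of
  Quan rules that depend on code *combinations* beyond the two hierarchy
  exclusions.
* `cv.glmnet`'s AUC criterion is itself estimated on folds; with very small
  derivation cohorts the chosen penalty is noisy (the deviance fallback
  mitigates, but small-cohort AUCs should be read with their CIs).
* The CLI writes dense CSV feature matrices; at M×N in the thousands and
  10⁵ assessment points, use the in-memory API instead.
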