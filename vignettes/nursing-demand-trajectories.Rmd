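---
title: "Modelling ward-level nursing-demand trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ward-level nursing-demand trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(wardflow)
```

## The model

wardflow treats a hospital admission as a discrete-time trajectory over a
fixed 15-element state space. Each day a patient is in exactly one state:
an integer nursing-demand score from 0 to 12 (the activities-of-daily-living
and cognition component of the Japanese Intensity of Nursing Care Needs
instrument, where higher means more care), `"other"` (the patient spent the
day in another ward or a specialized bed, so the score does not describe care
delivered by the ward under analysis), or `"discharged"`. Discharge is
absorbing. The analysis horizon is 18 days from admission (day 1 = admission
day), the planned length of stay in 7:1-staffed acute wards, so there are 17
day pairs $d \to d+1$, $d \in \{1,\dots,17\}$.

For a cohort $\mathcal{E}$ of $N$ eligible admissions of one ward in one
fiscal year, the central object is the per-day transition count matrix

$$M^{(d)}_{ij} \;=\; \sum_{e \in \mathcal{E}} I_i(e,d)\, I_j(e,d+1),$$

where $I_i(e,d)$ indicates that case $e$ occupied state $i$ on day $d$.
Because trajectories are complete, each case contributes exactly one
transition per day pair, so $\sum_{ij} M^{(d)}_{ij} = N$ for every $d$, and
column sums of $M^{(d)}$ equal row sums of $M^{(d+1)}$ (the flow-continuity
property that makes the Sankey rendering consistent).

Two normalisations of $M^{(d)}$ answer different questions and are kept
strictly apart in the API:

* **Joint proportions** $P^{(d)} = M^{(d)} / N$
  ([transition_proportions()]) describe how the cohort distributes over
  transitions — the quantity a flow diagram draws and the one used for
  cross-ward comparison.
* **Conditional kernels** $Q^{(d)}_{ij} = M^{(d)}_{ij} / \sum_k M^{(d)}_{ik}$
  ([estimate_kernel()]) describe where a patient in state $i$ goes next —
  the quantity a forecast needs. Together with the empirical day-1
  distribution they define a day-inhomogeneous absorbing Markov model
  (`demand_kernel`) supporting marginal forecasts
  ([forecast_demand()]), seeded simulation ([simulate_cohort()]) and
  quantitative comparison ([compare_kernels()]).

Conflating the two normalisations is the main pitfall of this design:
$P^{(d)}$ rows do not sum to one and must never be iterated as a Markov
kernel.

The model deliberately assumes first-order, day-indexed dependence. One
known caveat: the "risk behavior" sub-item of the underlying instrument uses
a seven-day lookback, which can induce dependence beyond one day. We note
this rather than model it; the day-indexed first-order chain is the simplest
structure that can express the day-specific regularities of interest.

## Eligibility and trajectory processing

Raw data are patient-day records (date, patient ID, admission date,
discharge date, ward, bed, score). Each admission date of a patient is a
separate case. Processing ([process_case()]) builds the 18-day trajectory:

* days in a non-target ward **or in a specialized bed of the target ward**
  are masked to `"other"` — the recorded score is deliberately discarded,
  because it does not describe demand borne by the target ward's general
  beds (a specialized bed is treated like a foreign ward since the cohort
  definition is occupancy of *general* beds);
* days after the discharge record's entry date are `"discharged"`; the
  discharge day itself keeps its recorded state;
* remaining days take the recorded score, or are *missing* when no score
  was recorded.

Eligibility ([filter_eligible()]) then requires: admission inside the fiscal
window (April 1 to March 14, so the horizon closes before the fiscal year
ends; a case belongs to the fiscal year of its admission date), at least one
general-bed day in the target ward within days 1–18 (day 18 inclusive, since
day-18 occupancy is part of the analysis), and no missing day. Missingness
is evaluated *after* the other/discharge labelling: an `"other"` day without
a score is not missing (the score was removed on purpose), and discharged
days need no score. Ordering the rules the other way would discard every
transferred or discharged patient, which would contradict the observed
transfer and discharge flows. Each excluded case is logged with the first
rule it failed, so the cohort plus the exclusion log always partition the
input.

## Band summaries and diversity

For cross-ward description, scores are banded: low 0–2, medium 3–5, high
6–9, ultra-high 10–12. At a chosen day pair, [band_transition_summary()]
counts five named trajectory categories — within-band persistence for the
four bands plus the score-0-to-discharge path — and a residual. Two
conventions matter and are fixed here: the 0-to-discharge category requires
source state exactly 0 (not the whole low band), and a case discharged on
both days falls in the residual, not in a named category (the named
categories describe care trajectories, and an already-absent patient has
none; consequently named shares need not sum to 100%).

[transition_diversity()] counts how many of the $15^2 = 225$ possible
single-step transitions are observed, the score range touched, and the
top-2 concentration: the share of the cohort in the two *largest named
categories* (not the two largest of all 225 cells — the concentration is a
statement about the named clinical paths). Ties between equally large
categories are broken by the fixed category order (low, medium, high,
ultra-high, 0-to-discharge); with integer counts on real cohorts ties are
rare and the choice is recorded here once.

Percentages are rendered by multiplying by 100 and rounding **half up** to
one decimal ([percent_round()]). Half-even rounding (R's default `round`)
does not reproduce conventional clinical-table formatting. Cohort quartiles
([summarize_cohort()]) use linear interpolation between order statistics
(quantile type 7), recorded in the output's `quantile_type` attribute since
published tables rarely state a convention.

## Fixed-layout Sankey diagrams

Automatically arranged Sankey layouts destroy comparability between
diagrams. [build_sankey_spec()] therefore fixes the layout: the horizontal
position of day $d$ is exactly $(d-1)/17$ (equal intervals), and within a
day the occupied states are stacked in the fixed display order — scores
descending from 12 to 0, then `"other"`, then `"discharged"` — with uniform
gaps normalised to $[0,1]$. Placing the two non-score labels below score 0
keeps the ordinal score axis contiguous; their exact position is a package
convention. Nodes with zero occupancy are omitted. Link thickness carries
$M^{(d)}_{ij}$; a renderer can divide by $N$ for cross-ward comparison.
JSON output is lossless and round-trips through [read_sankey()]; HTML output
is a self-contained SVG rendering with native hover tooltips, intended for
quick inspection rather than publication graphics.

## The kernel model: estimation, forecasting, comparison

[estimate_kernel()] is purely empirical by default: no smoothing, and rows
whose state was never occupied on a given day are flagged as unobserved
(`support = 0`) rather than imputed — inventing dynamics for unseen states
would silently bias forecasts. An optional Laplace pseudocount `alpha` is
available when a fully supported kernel is needed. The `"discharged"` row is
fixed to the unit vector for every day because absorption is definitional,
not estimated. Simulation refuses to enter an unobserved row unless the
caller opts into a stay-in-place fallback.

[compare_kernels()] summarises the difference between two wards (or two
fiscal years of one ward) as the support-weighted mean total-variation
distance between corresponding conditional rows, skipping rows unobserved in
either kernel and weighting each compared pair by the smaller of the two
support counts. Total variation is bounded in $[0,1]$, symmetric and
interpretable (the largest possible disagreement in the probability of any
event); min-support weighting lets well-determined rows dominate without
letting one cohort's large support vouch for the other's noise. The choice
of divergence is a design decision — any bounded divergence would support
the same qualitative ordering — and is recorded in the kernel metadata.

[transition_entropy()] quantifies trajectory diversity at a day pair as the
Shannon entropy (bits) of the joint transition distribution (forecast
occupancy times conditional row), i.e. the distribution $P^{(d)}$ estimates.

## The synthetic cohort generator

No patient-level hospital data can be shipped, so [make_archetype()] and
[generate_cohort()] provide a fully specified data-generating process with
the statistical structure the analysis assumes, one archetype per studied
ward type:

* **orthopaedic** — a post-operative surge: day-1 mass concentrated on
  scores 0–2; at the day 2→3 pair every low-band state moves at least 20% of
  its conditional mass into high-band scores (score 0 sends ≥ 20% to score 7
  alone); stabilisation at day 3→4; decline to mid scores at day 4→5; then a
  quiescent phase with a slow discharge hazard.
* **cardiology** — early discharge: low scores throughout, a discharge wave
  at day 3→4 bringing the day-4 discharged mass to at least 20%, a second
  wave at day 5→6, a small flat ultra-high stratum, and transfers returning
  to mid scores.
* **neurosurgery** — diversity: a broad initial distribution, persistent
  mid- and high-acuity strata, transfers landing on high scores, daily
  high-score discharges, and — by construction — strictly the highest joint
  transition entropy of the three archetypes at every day pair.

Kernels are built parametrically (a stay component, band-shift moves, and
day-indexed discharge hazards), not as hand-entered 15×15×17 tables: the
hundreds of numbers involved are not individually meaningful, and the
parametric family keeps the generator auditable. Two further construction
rules are deliberate. First, rows are sparse — at most five nonzero entries
— and stochastic rows are attached only to states that stay heavily occupied
throughout the stay, while sparsely occupied states follow deterministic
rules. This makes the generator *identifiable at realistic cohort sizes*: a
single ward-year of a few thousand admissions pins every observed kernel row
down tightly, which is exactly the regime in which year-over-year regularity
is a meaningful claim. Second, the archetypes are calibrated to the
magnitudes of the ward behaviours listed above, not to any full empirical
transition table (none is available); they are stylised study conditions,
not a re-identification of any hospital.

Raw records are emitted one per patient-day: transfer days carry either a
foreign ward label or an `SP`-prefixed specialized bed (both masked to
`"other"` at ingest, exercising both masking rules), discharge sets the
discharge date to the last inpatient day, and in-ward scores are dropped
independently per day with probability `missing_rate` (default 0.0004,
chosen so that roughly 0.7% of cases — $1-(1-0.0004)^{18}$ per case, matching
the study population's overall exclusion fraction — trip the missing-data
rule). Admission dates are uniform over the fiscal window; no seasonality is
modelled. Everything is seeded: identical `(archetype, n, seed)` give
byte-identical records.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: demographic covariates and their correlation with
trajectories, inter-patient dependence (shared complications, bed-capacity
pressure), non-Markov within-patient dependence, score measurement error,
and the true magnitude of year-to-year drift within a ward (synthetic
"fiscal years" are exchangeable draws from one process, so within-ward
dissimilarity reflects sampling noise only).

## Numerical choices and degenerate inputs

* Percentages: round half up to one decimal (with a $10^{-9}$ guard against
  binary representation artefacts); quartiles: type 7.
* Kernel rows: unobserved rows are `NA` + `support = 0`, never imputed;
  row sums are validated to $1 \pm 10^{-9}$ at construction.
* Empty cohorts: transition counts return all-zero matrices; summaries and
  kernel estimation refuse them ($N = 0$ has no proportions).
* Day 18 has no successor; transition operations accept only days 1–17 and
  say so.
* `compare_kernels` on kernels sharing no observed row is an error rather
  than an arbitrary 0.
* Sankey: a single occupied state in a day is centred at $y = 0.5$; an empty
  specification serialises to a valid file with empty node and link arrays.

## Problem sizes used by the test suite

The shipped checks run the generator at the scales at which its guarantees
were designed: parameter recovery on cohorts of 5 000 cases per archetype
(every observed kernel row within total variation 0.05 of the generating
row), forecast calibration against 10 000 simulated trajectories (L1 within
0.05 at every day), and the within-ward vs between-ward ordering on
estimated kernels from cohorts of 2 000 cases per synthetic fiscal year.
These sizes mirror realistic ward-year cohort magnitudes (hundreds to a few
thousand admissions) while keeping the whole suite fast.

## Known limitations

* The Markov assumption is untested against real data; the package measures
  and models day-indexed first-order structure only.
* Band boundaries (0–2 / 3–5 / 6–9 / 10–12) are descriptive conventions,
  not clinically validated cut-points.
* The generator's archetypes are stylised; conclusions about method
  behaviour on real extracts should be re-checked on those extracts.
* Horizons other than 18 days are accepted throughout the API but the
  shipped generator and tests exercise 18 only.
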