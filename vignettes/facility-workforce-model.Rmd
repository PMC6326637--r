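---
title: "The facility-ladder Markov model and its workforce translation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The facility-ladder Markov model and its workforce translation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hwforecast)
```

## The model

`hwforecast` projects a census of healthcare facilities over an ordered
ladder of eleven workload categories and converts the projected mix into
staff requirements. The cohort state is the real-valued count of facilities
per (region, category, year). Each annual cycle, the count at rank *r*
loses the fraction `p(r → r+1)` to the rung above, gains the corresponding
inflow from the rung below, and gains any newly commissioned facilities;
the top rung (established teaching hospitals) is absorbing.

Three structural assumptions define the model, and all are enforced in
code rather than merely documented:

* **Upward-only movement.** Facilities are upgraded when workload grows;
  they are not downgraded or closed. Only the ten adjacent upward pairs
  exist in a transition table, and the panel estimator rejects downward
  moves unless told to drop them.
* **One rung per year.** The cycle length is one year because facility
  workload statistics are compiled annually; a facility cannot skip a rung
  within a cycle.
* **Expected-value (cohort) semantics.** Counts are fractional internally
  — 0.34 of a regional hospital is the expected value over the underlying
  facility-level Bernoulli process, not a physical half-building. Rounding
  (half away from zero) happens only in the report renderers:
  whole facilities for census tables, one decimal for flow tables.

The 10-year default horizon matches the planning lifespan of the strategic
policies this class of forecast feeds; forecasts further out are dominated
by structural change rather than parameter uncertainty.

## The CHPS stock: two regimes

The bottom rung (CHPS, community-based health planning and services zones)
is special: zones are *demarcated* administratively at one per 1,500
population, so the stock is driven by population rather than workload.
`project()` therefore supports two regimes:

* **`population` mode** (a population series is supplied): each projected
  year the CHPS count is set to `population / chps_divisor`, replenishing
  whatever upgraded out; the divisor defaults to the policy value 1500.
* **`markov` mode** (no population series): CHPS evolves endogenously as
  an outflow-only stock plus construction.

Neither regime alone reproduces every published census trajectory for this
rung — the demarcation pace embedded in published national figures is not
recoverable — so the package exposes both and leaves the choice to the
analyst. All printed-table checks in the test suite use `markov` mode,
whose hospital-tier values match the published one-cycle census exactly.

## Transition probabilities

`estimate_transitions()` uses a pooled binomial MLE: every facility-year
observed in category *r* with an observation the following calendar year is
at risk; moving to *r+1* is an event; `p̂ = events / at-risk` with the
binomial standard error `sqrt(p̂(1−p̂)/n)`. Pooling across regions and
years is the simplest estimator consistent with a time-homogeneous Markov
model, and the reported standard-error magnitudes of the national
parameter table are consistent with binomial scaling at plausible
denominators. Facilities missing a year are censored for the affected
intervals; interpolation would fabricate at-risk time from exactly the
records most likely to be unreliable.

## Workforce translation

The base requirement is a dot product: census vector × per-facility
staffing standard, per staff type, region and year; national figures are
exact sums over regions. The workload-change adjustment is the piecewise
ladder (±23.5% at |Δ| ≥ 15%, ±14.3% for 10% < |Δ| < 15%, ±6.3% for
5% ≤ |Δ| ≤ 10%, else 0), with the sign following the sign of the change.
The published wording leaves exactly 10% ambiguous between two bands; this
implementation reads "5% up to 10%" as inclusive, so 0.10 maps to 0.063 —
a single documented constant, trivially changed. Changes beyond 15% also
set a `needs_review` flag, reflecting the policy requirement for a
facility-status assessment, without altering the arithmetic. How future
workload changes arise is deliberately *not* modelled: `workload` is an
explicit input, defaulting to none, because inventing a workload process
would smuggle a second forecasting model into the staffing step.

## Predictive intervals

Parameter uncertainty is propagated by scenario limits: the pipeline runs
with all ten probabilities simultaneously at `p`, `p − 1.96·se` and
`p + 1.96·se` (clamped to [0, 1]). Shifting all probabilities up does not
move all outputs up — faster upgrading enriches high categories while
draining low ones — so per-cell bounds are the minimum and maximum over the
three runs, which guarantees the base case lies inside its interval for
every cell. A seeded Monte-Carlo mode (probabilities drawn per pair from a
normal truncated to [0, 1], bounds from the 2.5%/97.5% quantiles) is
provided as a clearly-labelled optional extension for analysts who prefer
distributional intervals; the limit scenarios remain the default because
they are deterministic and directly comparable across runs.

## The synthetic-data generator

The pipeline's original inputs — a national routine-information-system
facility panel, the ministry staffing-norms matrix, employment rosters —
are not publicly distributable, so `simulate_panel()`, `synth_norms()`,
`synth_population()`, `synth_construction()` and `synth_roster()` generate
statistically analogous stand-ins, all reproducible under a single seed:

* the panel applies exactly the Bernoulli upgrade process the cohort model
  takes expectations over (each facility moves one rung with probability
  `p`, independently, no downward moves), with optional missing-year
  censoring;
* norms are non-negative, monotone non-decreasing up the ladder for every
  cadre, with specialist cadres absent below hospital level, at
  order-of-magnitude-plausible but **fictional** values;
* the roster is drawn so the aggregate staff-availability ratio lands near
  a target (default 0.68), with wide per-cadre jitter.

What the generator does **not** emulate: service-volume data and the
workload-classification criteria that assign categories from it (panels
arrive pre-categorised); reporting artefacts of real routine data beyond
simple missingness; correlated shocks across facilities (epidemics,
policy waves); and real norms magnitudes. A passing test suite therefore
demonstrates that the pipeline is faithful to its own model assumptions
and to the published tables it can reach — not that the model is an
adequate description of any particular health system.

## Numerical and testing choices

* Counts, probabilities and norms are validated at every entry point;
  violations abort with the offending cell named. Degenerate inputs
  (all-zero probabilities, zero standard errors, empty categories) are
  exercised in tests and propagate exactly (identity projection, collapsed
  intervals, zero flows).
* Conservation (no construction, endogenous CHPS) is asserted to 1e−9
  relative; requirement aggregation to 1e−12.
* The microsimulation cross-check compares deterministic expected counts
  with empirical counts from 10,000 simulated facilities per category and
  a ±3 standard-error band from the exact binomial variances of one
  update. Parameter recovery uses 200 replicate panels of 5,000
  health-centre facilities over 5 years, asserting 95% interval coverage
  between 0.90 and 0.99. These sizes give sampling error comfortably
  below the assertion bands while keeping the default suite under a
  minute.
* Report outputs are staged and moved atomically; manifests contain no
  timestamps so identical configurations produce byte-identical output
  sets.

## Limitations

The model tracks counts, not individual facilities, so it cannot site new
facilities or respect district-level caps; transition probabilities are
time-homogeneous over the horizon; norms and construction schedules carry
no uncertainty; and the workforce translation assumes the norms themselves
remain fixed policy throughout the forecast period.
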