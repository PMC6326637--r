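# hwforecast

Forecasting healthcare facilities and the health workforce they require.

Health ministries plan recruitment against *staffing norms*: for every
category of health facility, a stipulated headcount of each staff cadre.
Facility categories are not static — as utilisation grows, a health centre
becomes a polyclinic, a district hospital climbs from workload category A to
B, and its staffing entitlement grows with it. `hwforecast` implements a
two-level forecasting pipeline for this setting, shaped around Ghana's
public-sector facility ladder:

1. **Facility projection.** Facilities occupy an ordered ladder of 11
   workload categories
   (CHPS < HCA < HCB < PolyC < PHA < PHB < PHC < PHD < RH < EmTH < EsTH).
   A deterministic discrete-time Markov cohort model advances the census one
   year per cycle: for category *c* at rank *r* in region *i*,

   ```
   N_c(i, j) = N_c(i, j-1) − N_c(i, j-1) · p(r → r+1)
             + N_{c-1}(i, j-1) · p(r−1 → r) + B_c(i, j)
   ```

   where `p(r → r+1)` is the annual probability of moving one rung up
   (estimated from a facility-category panel), `B_c` counts newly
   constructed facilities, the top rung is absorbing, and the CHPS stock can
   alternatively be pinned each year to `population / 1500` (the
   one-CHPS-zone-per-1,500-population demarcation rule).

2. **Workforce translation.** The projected census is multiplied by a
   staffing-norms matrix `SS(k, c)` (staff type × category → headcount per
   facility): `HWF_k(i, j) = Σ_c N_c(i, j) · SS(k, c)`, optionally adjusted
   by the piecewise workload-change ladder (±23.5% / ±14.3% / ±6.3% / 0 for
   workload changes ≥15% / 10–15% / 5–10% / <5%). Staff-availability ratios
   (SAR = employed / required) quantify current gaps, and 95% predictive
   intervals are obtained by re-running the pipeline with all transition
   probabilities simultaneously at their lower and upper confidence limits.

The package also estimates the transition probabilities from longitudinal
facility panels (pooled binomial MLE with binomial standard errors) and
ships a seeded synthetic-data generator for every input — facility panels,
censuses, population series, construction schedules, staffing norms and
employment rosters — so the full pipeline is testable end-to-end without any
restricted data. The bundled staffing norms are explicitly synthetic; real
norms are a policy input you supply.

## Worked example

```r
library(hwforecast)

fix <- make_ghana_fixture()            # printed 2016 census + probabilities
proj <- project(fix$census, fix$transitions, horizon = 10)
glance(proj)
#>   baseline_year horizon chps_mode n_regions baseline_total final_total growth
#> 1          2016      10 markov            1           5749        5749      0

census_wide(proj)[, c("category", "2016", "2017", "2021", "2026")]
#>                       category 2016 2017 2021 2026
#>                           CHPS 4449 4405 4231 4024
#>                            HCA  903  918  968 1012
#>                            HCB  158  183  282  399
#>                          PolyC   40   43   59   91
#>                            PHA   96   82   46   29
#>                            PHB   49   59   69   58
#>                            PHC   29   33   53   70
#>                            PHD   14   16   28   50
#>                             RH    7    7    6    7
#>                           EmTH    2    3    5    8
#>                           EsTH    2    2    2    2
#>    Primary hospitals (PHA-PHD)  188  189  196  207
#>                 All facilities 5749 5749 5749 5749
```

One cycle from the 2016 baseline reproduces the published 2017 column for
the hospital tiers (HCB 183, PHB 59, PHC 33, PHD 16, EmTH 3); with no
construction and endogenous CHPS the national total is conserved at 5,749,
and the mix shifts up-ladder: primary hospitals grow from 188 to 207 while
PHA drains into PHB and beyond. The published census instead grows CHPS via
population-driven demarcation — supply a `population` series to `project()`
to switch to that regime.

Translating to staff and gaps, with the bundled *synthetic* norms:

```r
norms <- read_norms_csv(system.file("extdata", "synthetic_norms.csv",
                                    package = "hwforecast"))
req <- staff_requirements(proj, norms)
requirements_wide(req)[c(11, 24), c("staff_type", "2016", "2017", "2026")]
#>   staff_type  2016  2017  2026
#> 1    Midwife  1666  1714  2146
#> 2      Total 43711 45001 56649

roster <- synth_roster(req, 2016, sar_target = 0.68, seed = 1)
staff_availability_ratio(req, roster, 2016)
#>               staff_type employed required       sar shortfall
#> 1   Biomedical scientist      728  1194.57 0.6094243 0.3905757
#> 2 Community health nurse     3347  5215.84 0.6416991 0.3583009
#> 3    Critical care nurse     3531  5030.65 0.7018974 0.2981026
#> # … 23 staff types in total
```

A Midwife requirement of 1,666 in 2016 rising to 2,146 by 2026 means the
facility mix alone (not population growth) raises the midwifery requirement
by ~29% over the decade under these fictional norms; a SAR of 0.61 for
biomedical scientists says current employment covers 61% of the modelled
need. `predictive_interval()` appends lower/upper bounds per cell;
`run_forecast()` executes the whole pipeline from a config (list or YAML)
and writes the report set with a reproducible manifest.

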