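---
title: "Measuring medical accessibility under hierarchical diagnosis and treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring medical accessibility under hierarchical diagnosis and treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierfca)
```

## The model

Two-step floating catchment area (2SFCA) methods measure spatial
accessibility by (step 1) computing a supply-to-demand ratio at each
facility from the population it can reach and (step 2) summing those
ratios, distance-decayed, at each demand point. `hierfca` adapts this to
a hierarchical diagnosis-and-treatment system, in which the facilities a
resident may use are fixed by administrative containment and referral
rules rather than by travel time:

- residents visit the **primary institutions of their own township**;
- a referral share `alpha` continues to the **county hospitals of their
  county**;
- an acute-case share `beta` goes **directly to municipal hospitals** of
  their city;
- of county patients, a share `gamma` is referred on to **municipal
  hospitals**.

Accessibility decomposes into the four corresponding components:

$$A_i = A_{ip} + A_{ic} + A_{im_1} + A_{im_2}.$$

Each component has the same anatomy: a pooled supply-demand ratio `R`,
a distance-decay factor `f(d)`, and a selection weight `G` splitting flow
among same-tier candidates. For a township *i* with primary institutions
*p* in it:

$$A_{ip} = \sum_p R_p \, f(d_{ip}) \, G_{ip},$$

and referral components fold through the chain, e.g.

$$A_{ic} = \sum_p G_{ip} \sum_c R_c \, f(d_{pc}) \, G_{pc}, \qquad
  A_{im_2} = \sum_p G_{ip} \sum_c G_{pc} \sum_m R_{m}\, f(d_{cm})\, G_{cm}.$$

### Pooled supply-demand ratios

Same-tier hospitals within one administrative unit share a pooled ratio:
summed beds divided by the population the unit serves. Referral demand
pools are `P_{k_1} = \alpha \cdot` county population for the county tier
and `P_{k_2} = (\beta + \alpha\gamma) \cdot` city population for the
municipal tier; the direct and referred municipal routes draw on the same
pool, so `R_{m_1} = R_{m_2}`.

### Selection weights

Patient flow to a candidate hospital is proportional to a composite score
`T = X_1^* + X_2^* + X_3`:

- `X_1`: the accreditation-grade coefficient — 0.5 (below secondary),
  1 (secondary), 1.5 (grade-A secondary), 2 (tertiary),
  2.5 (grade-A tertiary) — min-max standardised;
- `X_2`: bed count, min-max standardised;
- `X_3`: the national visit share of the hospital's type (general 0.6694,
  TCM 0.1418, integrated 0.0176, ethnic-national 0.0036, specialized
  0.0919, maternal and child health 0.0756), used raw. These six shares
  sum to 0.9999 and are deliberately not renormalised.

Standardisation pools **all hospitals of the tier across the region**, so
scores are comparable region-wide; within a demand point, weights
normalise: `G = T / \sum T`. A constant pool (all grades equal, or all
bed counts equal) standardises to 0.5 for every member.

One consequence worth knowing: min-max standardisation makes the
*pool endpoints* special. Raising the grade of the hospital that defines
the pool maximum rescales every rival's standardised score, so "higher
grade ⇒ weakly higher weight" holds only when the pool endpoints are
fixed. The test suite checks the monotonicity property in that anchored
form.

### Capacity-derived referral rates

Rates may also be derived from the data. Carrying capacity converts beds
into servable residents,

$$C = \frac{\text{beds} \times 1000 \times k}{N},$$

with `k` the scenario occupancy coefficient and `N` a beds-per-1000-
residents norm (defaults: 6 overall, 1.2 primary, 3.3 public hospitals).
The referral rate is the median over administrative units of
`min(C / population, 1)`. `derive_scenario_rates()` applies this at the
county tier (giving `alpha`) and city tier (giving `gamma`). Because a
scenario must satisfy `alpha + beta <= 1`, a derived `alpha` exceeding
`1 - beta` is capped there with a warning — this happens in bed-rich
regions where most counties could serve their whole population.

## Parameters and defaults

| Parameter | Default | Rationale |
|---|---|---|
| `scenario()` rates | BAU `k=0.8, alpha=0.43, gamma=0.63`; general event `k=1.0, 0.54, 0.67`; major event `k=1.2, 0.65, 0.70`; `beta = 0.10` | published planning scenarios; `k` is hospital-bed occupancy under normal / elevated / crisis operation |
| `decay_params()` | power decay, exponent 1, floor 0.1 km | classic gravity decay; the floor keeps co-located origin-destination pairs finite. A Gaussian kernel (`form = "gaussian"`, bandwidth 10 km) is available |
| `detour` | 1.3 | Euclidean-to-road-network circuity factor typical of regional road networks; any long-format distance table can be supplied instead |
| `capacity_norms()` | 6 / 1.2 / 3.3 beds per 1000 | national planning norms for total, primary-institution and public-hospital beds |

### Conventions

- **Zero flow.** A supply-demand ratio with zero demand is 0 (no demand,
  nothing to ration). If `alpha = 0` the county and county-to-municipal
  components vanish; the `A_{im_2}` route is open only when both `alpha`
  and `gamma` are positive. Townships without any primary institution
  have no entry point into the system and get all four components 0, with
  a warning.
- **Dispersion.** Summary standard deviations use the population
  convention (divide by *n*), matching how dispersion across a fixed,
  fully enumerated set of townships is usually reported.
- **Classification.** `classify_accessibility()` defaults to quartile
  breaks (four equal-count classes: low / lower / higher / high); a
  Fisher-Jenks natural-breaks alternative (`method = "jenks"`) is
  implemented as an exact dynamic program and falls back to quartiles
  with a warning when there are fewer than four distinct values.

## The synthetic generator

`generate_region()` draws seeded regions shaped like real study areas:

- a nested city / county / township hierarchy (defaults 3 × 3 × 4);
- lognormal township populations, median about 30,000 (`meanlog =
  log(30000)`, `sdlog = 0.7`) — heavy-tailed, as empirical township
  populations are;
- an inverted-triangle bed distribution: log-uniform draws in 5–30
  (primary), 50–500 (county), 300–2000 (municipal) beds per facility;
- facility counts: Poisson(2) primary institutions per township (zero is
  allowed, mirroring townships with no functioning primary institution),
  and at least one county hospital per county and municipal hospital per
  city;
- accreditation grades skewing upward with tier, and hospital types drawn
  with the packaged national visit shares;
- one designated capital city whose hospitals get a 1.5× bed multiplier,
  mimicking capital-city resource concentration;
- planar coordinates in a 300 km square, with distances = Euclidean × 1.3.

Generation is a pure function of its configuration: the seed is set
internally and the caller's RNG stream is restored afterwards.

## Problem sizes

The engine is vectorised over edge tables (origin-destination pairs per
stage). A default demo region (36 townships, ~90 hospitals) computes in
milliseconds; the test suite's largest generated region (550 townships,
>11,000 hospitals) runs in a few seconds. Complexity is linear in the
number of containment pairs, which under administrative catchments grows
linearly with the number of facilities.

## Limitations

- Catchments are purely administrative; cross-boundary utilisation
  (documented in border townships in reality) is not modelled.
- Distances default to detour-scaled Euclidean geometry; for serious use,
  supply network travel distances or times via the `distances` table.
- Referral rates are uniform within a scenario; the model does not vary
  `alpha`, `beta`, `gamma` by county or by disease severity mix.
- The selection weight treats grade, beds and type as additive and
  equally scaled after standardisation; no interaction or calibration
  against observed flows is attempted.
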