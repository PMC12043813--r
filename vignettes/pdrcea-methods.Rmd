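---
title: "Methods: a Markov cohort model for PDR treatment cost-effectiveness"
author: "pdrcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model for PDR treatment cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdrcea)
```

## The decision problem and model structure

Proliferative diabetic retinopathy (PDR) threatens vision through
retinal neovascularisation. The standard of care, panretinal
photocoagulation (PRP), is cheap and durable; intravitreal anti-VEGF
drugs improve short-term acuity but are expensive, repeated
indefinitely, and of uncertain long-term benefit. This package
implements the cohort Markov model used to compare these options on
lifetime discounted costs and QALYs.

The state space is nine health states: eight bands of best corrected
visual acuity (BCVA), each spanning 10 ETDRS letters from ">85" down to
"≤25", plus death. The cohort starts at age 56 (57.6% male) distributed
over the bands as (0, 0.11, 0.39, 0.27, 0.15, 0.08, 0, 0), and evolves
in 3-monthly cycles to age 100. Within a cycle a patient can move at
most one band in either direction, die, or stay — the transition matrix
is tridiagonal plus a death column, and `build_matrix()` enforces that
shape. The model follows one (treated) eye; fellow-eye involvement is a
cost and utility channel, not a second trace (see below).

## Transition probabilities from acuity change

All visual dynamics derive from a single generative assumption: annual
BCVA change in letters is normal, `X ~ N(mean, sd)`. A change of at
least 5 letters crosses a band boundary — 5 letters is the minimal
band-crossing change for 10-letter bands, and it is the only threshold
choice consistent with the published quarterly natural-history
probabilities. Annual tail probabilities `P(X >= 5)` and `P(X <= -5)`
are converted to quarterly probabilities on the rate scale,
`1 - (1 - p)^(1/4)`; simple division by four is *not* equivalent and
does not reproduce the published values.

```{r nh}
nh <- acuity_model(-1.30, 4.90)     # natural history, letters/year
round(100 * cycle_change_probs(nh), 2)
```

The published values are 2.57% and 6.10%. Our derivation gives 2.58%
and 6.18% under the stated method; the residual gap is a rounding-path
difference in the original spreadsheet (rounding the annual gain
probability to three decimals before conversion reproduces 2.57%
exactly). We implement the stated method and document the discrepancy
rather than reverse-engineering a rounding chain.

The PRP arm's own change model is not published directly — only its
quarterly transition probabilities (4.79% gain, 8.48% loss) are. We
back-solve the two normal tail conditions for the mean and SD:

```{r prp}
print(acuity_model_from_cycle_probs(0.0479, 0.0848))
```

Treatment effects are 1-year mean LogMAR differences versus PRP from a
network meta-analysis (aflibercept −0.088, ranibizumab −0.123,
ranibizumab+PRP −0.080, bevacizumab −0.193, bevacizumab+PRP −0.172).
With the ETDRS equivalence of 5 letters per 0.1 LogMAR, an effect
shifts the PRP mean by `-effect / 0.02` letters. The evidence base
reports only the dispersion of the mean difference, not arm-level
change SDs, so all arms reuse the PRP SD; this is configurable.

### Effect trajectory scenarios

Because long-term anti-VEGF outcomes in PDR are scarce, two scenarios
bracket the possibilities:

* **continued** — the year-1 arm model applies for the remainder of
  life;
* **stabilised** — acuity freezes (gain = loss = 0 per cycle, mortality
  unaffected) beyond year 1 for PRP and beyond year 2 for anti-VEGF
  arms, with the mean declining linearly to zero across years 1–2.

"Stabilised" is implemented as a hard freeze because the clinical
rationale is long-term stability after PRP; an alternative
small-movement variant can be supplied through
`config$scenario$stabilised_probs`. The trajectory is population-level:
it is applied regardless of individual discontinuation status, since
the scenario definitions describe the cohort, not treatment exposure.
The one-way sensitivity analyses can additionally switch the cohort to
the natural-history model from year 5, 10 or 20
(`natural_history_onset_years`).

## Mortality

Annual death probabilities come from a life table mixed by sex
(`male_fraction` = 0.576), adjusted for diabetes with a hazard ratio of
1.95 applied on the hazard scale, `q_adj = 1 - (1 - q)^hr`, then
converted to quarterly probabilities by the same complement-root rule.
The cohort ages deterministically, `age(t) = 56 + 0.25 t`, and
mortality uses the integer age floor — the standard cohort convention.

The shipped life table is synthetic: a Gompertz–Makeham hazard
(`makeham` 2e-4/yr, scale 2.2e-5, slope 0.095 per year of age) with a
male/female hazard ratio of 1.45 split symmetrically. These values were
chosen once so that sex-mixed life expectancy at 56 is ≈ 27 years
before the diabetes adjustment — a plausible national magnitude. Users
with an actual national life table can load it with
`read_life_table()`; the format is three-column delimited text.

## Discontinuation, fellow eye, and bookkeeping

Treatment discontinuation is a right-continuous step function: 100% on
treatment in year 1, 87% in years 1–3, 75% in years 3–5, 50%
thereafter, identical across strategies. Discontinuation affects costs
only; effect persistence is governed by the trajectory scenario.

22% of patients are treated in both eyes at baseline, and the
single-eye fraction acquires fellow-eye disease at 5.4% per cycle
(absorbing). Both eyes share the modelled health state — the trace is
one-eye — but drug costs double for the both-eye fraction while
administration and monitoring do not (both eyes are treated in the same
visit). Of single-eye patients, 67.2% are treated in their worst-seeing
eye and 32.8% in their best-seeing eye, fixed over time.

## Costs and utilities

Unit costs (GBP, 2019–20 prices; the sources pre-inflated them, so no
inflation machinery is implemented): drug list prices per dose
(aflibercept £816.00, ranibizumab £551.00, biosimilar £523.45,
bevacizumab £50.00), PRP £126.77 per session (administration included
in the session cost), anti-VEGF administration £257.981 per visit
(OCT £101.804 × 100% + outpatient £129.616 × 95% + day case
£660.838 × 5%), monitoring £101.804 per visit on treatment and £38.344
after, and £421.609 per cycle of low-vision care applied to occupancy
of the two worst bands (BCVA ≤ 35 letters, the modelled band — whether
the source applied it to a best-eye construct is unstated).

Utilities are per-band, indexed by whether the treated eye is the
best- or worst-seeing eye. The worst-seeing-eye column interpolates a
0.1 total decrement linearly from the second-best band (0.839) to the
worst (0.739); `wse_utility_vector()` reproduces the published
intermediate values 0.822, 0.806, 0.789, 0.772, 0.756, 0.739 at their
printed precision. Both-eye patients use best-seeing-eye utilities,
since the better eye drives overall functioning.

Several inputs exist only in the source study's supplementary material
and are shipped as documented placeholders, tagged
`provenance: "placeholder"` so no test or report can mistake them for
published values: injection schedules (7, 4, 3, 3, 2 per year,
identical across anti-VEGFs, last value persisting), PRP sessions (3 in
year 1, then 0.5/year), monitoring (4 visits/year on treatment, 2
after), two adverse events with sub-2% year-1 probabilities and modest
costs/disutilities (their aggregate impact is deliberately small), and
a subsequent-treatment rule (25% of discontinuers switch — anti-VEGF
arms to PRP, PRP to bevacizumab, no within-class switches — accruing
the new strategy's acquisition and administration costs for at most 8
cycles, with no effect change). Consequently the per-strategy cost and
QALY *totals* are illustrative; every quantity determined by published
main-table inputs is reproduced and tested.

By default a monitoring visit is assumed to coincide with an injection
visit (the on-treatment monitoring count is netted against injections);
the `treatment_separate_visit` flag in the scenario block restores
separate visits, one of the one-way sensitivity analyses.

## Valuation

Both costs and QALYs use trapezoidal half-cycle correction — each
cycle's flow is valued at the average of start and end occupancy (and
channels), so a constant trace is unaffected — and are discounted at
3.5% per year at the mid-cycle time. Adverse-event costs and
disutilities apply in year 1 only (the trial reporting window);
remaining occupancy at the age-100 horizon transitions to death without
further valuation.

## Incremental analysis

`incremental_frontier()` sorts strategies by cost, removes strictly
dominated strategies, then iteratively removes extended dominance
(non-increasing ICERs along the cost-ordered chain), and reports ICERs
along the remaining chain; `nmb()` and `rank_by_nmb()` implement the
NMB view at a willingness-to-pay threshold (£20,000/QALY by default).
ICERs are kept unrounded internally; display rounding happens only in
print methods. Equal-cost strategies form one comparison group in which
only the higher-QALY member can reach the frontier; exact cost-QALY
ties are retained and flagged. On the published scenario-1 cost/QALY
pairs the algorithm reproduces the published dominance pattern and the
bevacizumab+PRP ICER (computed 8944.6 vs printed 8947, which reflects
unrounded internal values).

## Probabilistic sensitivity analysis

Every parameter carries a distribution: beta for probabilities and
utilities, gamma for costs, normal for treatment effects and the
natural-history mean, lognormal for the mortality hazard ratio,
dirichlet for the baseline distribution and the treated-eye split.
Conventions worth stating:

* the lognormal point estimate is `exp(mu)` (the median), because the
  published 1.950 equals exp(0.668) — not `exp(mu + sigma^2/2)`;
* gamma is parameterised as (shape, scale) with mean = shape × scale;
  the published "μ, σ" column reads as shape and scale (96.036 × 8.497
  recovers the £816.00 list price). A shape of 96.036 = (1.96/0.2)²
  encodes the ±20% convention used where no dispersion data existed;
* the dirichlet concentrations for the baseline distribution are not
  published; we default to proportion × 100 (an effective sample size
  of 100, configurable). Zero-proportion bands keep concentration zero
  and remain structurally zero in sampling — whether they could truly
  be sampled nonzero is unknowable from the source, so we keep the
  structural zeros and flag the choice here;
* parameters are sampled independently (no correlations are specified);
* PSA draws are validated against *structural* rules only. The strict
  point-estimate rules — per-band utilities non-increasing, distribution
  means matching point estimates within 0.5% — would by construction
  reject a large share of independent draws, so they apply only to
  point-estimate configurations. Draws failing structural validation
  are rejected and recounted; more than 1% rejections aborts the run.

Probabilistic totals are per-draw means, with percentile NMB intervals,
and the probabilistic frontier is computed on mean costs and QALYs —
the standard reporting convention. The default draw count is 5,000
(the source does not state its own), and every run is reproducible from
its seed. `generate_psa_fixture(config, scale)` rescales all dispersion
by a common factor while preserving means; scale 0 gives point masses,
under which a PSA reproduces the deterministic run bit-for-bit — a key
equivalence test.

## Numerical choices and degenerate inputs

Probabilities are validated to [0,1] and `gain + loss <= 1` before a
matrix is built; row sums are exact by construction and tested to
1e-12. The cohort update uses a vectorised tridiagonal recursion that
is tested for equality against the explicit matrix path. Step-function
lookups (discontinuation, schedules) are right-continuous at
breakpoints. The zero-hazard, zero-cost, zero-utility and degenerate
PSA limits are all covered by tests. Configuration round-trips through
YAML are exactly idempotent (the second save is byte-identical), and
the life table serialises at 17 significant digits so doubles survive
the file format.

## What the synthetic inputs do and do not show

The synthetic life table and placeholder schedules make the pipeline
self-contained: tests exercise real dynamics at realistic magnitudes
without any download. They emulate plausible England/Wales mortality
and plausible PDR resource use, but they are not the source study's
supplementary inputs, so passing tests demonstrate the correctness of
the *machinery* (transitions, trace, valuation, frontier, PSA) and the
reproduction of main-table-derivable quantities — not the source's
absolute cost/QALY totals. Problem sizes used in the test suite — a
176-cycle lifetime trace, a 100,000-patient microsimulation oracle
compared at cycles 4, 40 and 100, 100 random frontier instances against
a brute-force NMB sweep, and PSA runs up to 5,000 draws — were chosen
as the smallest sizes at which the Monte-Carlo comparisons have
meaningful power.

## Known limitations

Diabetic macular oedema is not modelled as a separate risk (its effect
is assumed captured in the BCVA transitions); the model is one-eye with
second-eye costs added rather than a true two-eye structure; utilities
and effects beyond year 1 rest on the two bracketing trajectory
scenarios rather than long-term data; and bevacizumab's effect estimate
carries very large uncertainty (SD 0.499 LogMAR), which dominates the
probabilistic intervals.
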