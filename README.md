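# pdrcea

A Markov cohort cost-effectiveness model comparing intravitreal
anti-VEGF drugs — ranibizumab (Lucentis), aflibercept (Eylea) and
off-label bevacizumab — with panretinal photocoagulation (PRP), alone or
in combination, for treating proliferative diabetic retinopathy (PDR)
without diabetic macular oedema. The package is aimed at health
economists and HTA analysts who want a transparent, fully scriptable
implementation of this decision problem: every input is data, every
step is an exported function, and the whole pipeline is reproducible
from a seed.

## The model

Nine health states: eight 10-letter bands of best corrected visual
acuity (BCVA, ETDRS letters; ">85" down to "≤25") plus death. A cohort
starts at age 56 with a fixed baseline band distribution and evolves in
3-monthly cycles to age 100, moving at most one band per cycle
(adjacent-state transitions only), with half-cycle correction and 3.5%
annual discounting of both costs and QALYs.

Visual transitions derive from a normal model of annual BCVA change.
With annual change *X* ~ N(μ, σ) in letters and a 5-letter band-change
threshold,

    p_gain(annual) = P(X ≥ 5),   p_loss(annual) = P(X ≤ −5)

converted to quarterly probabilities on the rate scale,
*p_cycle = 1 − (1 − p_annual)^(1/4)*. For the natural-history model
N(−1.30, 4.90) this yields quarterly probabilities of 2.58% (gain) and
6.18% (loss). Treatment effects enter as 1-year mean LogMAR differences
versus PRP (1 letter = 0.02 LogMAR), shifting the PRP arm's mean annual
change; two trajectory scenarios are supported — effects *continued*
for life, or *stabilised* (acuity frozen beyond year 1 for PRP, beyond
year 2 for anti-VEGF arms with a linear decline in between).

Mortality mixes male/female life-table probabilities (57.6% male) and
applies a diabetes hazard ratio of 1.95 on the hazard scale,
*q_adj = 1 − (1 − q)^1.95*. Costs cover drug acquisition (doubled for
the fraction treated in both eyes), a weighted administration visit
(£257.981), PRP sessions, monitoring on and off treatment, low-vision
care for BCVA ≤ 35 letters, adverse events and subsequent treatment
after discontinuation. QALYs weight band occupancy by best-/worst-
seeing-eye utilities mixed over the treated-eye distribution. Each
strategy is summarised by discounted cost, QALYs and net monetary
benefit (NMB = QALYs × £20,000 − cost), and strategies are ranked by a
fully incremental frontier with strict and extended dominance.

## Worked example

```r
library(pdrcea)

fit <- pdr_cea(default_parameter_set(), scenario = "continued")
fit
#> PDR cost-effectiveness model | 6 strategies | scenario: continued
#>
#> Incremental cost-effectiveness frontier (WTP 20000 per QALY)
#>         strategy  cost  QALYs ICER/label    NMB
#>      bevacizumab 10457 12.101  reference 231561
#>  bevacizumab_prp 11322 12.085  dominated 230371
#>              prp 11908 10.548  dominated 199052
#>      ranibizumab 31287 12.011  dominated 208941
#>  ranibizumab_prp 32355 11.827  dominated 204191
#>      aflibercept 42416 11.878  dominated 195150
```

Each row is one treatment strategy: its lifetime discounted cost and
QALYs per person, its dominance label or ICER along the frontier, and
its NMB at £20,000 per QALY. Here the cheap off-label drug dominates
the branded anti-VEGFs outright, and the anti-VEGF arms' QALY advantage
over PRP reflects the continued-effect assumption. Resource-use
schedules and adverse-event inputs are documented placeholders (tagged
`provenance: "placeholder"` in the configuration), so absolute totals
are illustrative rather than reproductions of the source study;
quantities derived from published main-table inputs are reproduced
exactly (see below).

Probabilistic sensitivity analysis propagates every parameter's
distribution through the model:

```r
psa <- run_psa(default_parameter_set(), n_draws = 200, seed = 42)
psa
#> Probabilistic sensitivity analysis: 200 draws (seed 42 , 0 rejected)
#>         strategy  cost  QALYs ICER/label                    NMB
#>              prp 12017 10.616  dominated 200307 [179256-215720]
#>      bevacizumab 18064 11.121  dominated  204351 [81436-253681]
#>  bevacizumab_prp 11348 12.174  reference 232133 [209048-254153]
#>      ranibizumab 31802 11.943  dominated 207050 [176366-229761]
#>  ranibizumab_prp 32981 11.764  dominated 202293 [173894-223367]
#>      aflibercept 44296 11.606  dominated 187831 [136466-218367]
```

Note the very wide bevacizumab interval: its treatment-effect SD
(0.499 LogMAR) dwarfs the others, so its probabilistic mean drifts far
from the deterministic value — the model's nonlinearity at work.

Other entry points: `pdr_cea()` objects support `summary()` (cost
breakdowns), `plot()` (cost-effectiveness plane) and `simulate()`
(per-draw PSA replicates); `dsa_battery()` runs the twelve one-way
scenario analyses; `load_config()`/`save_config()` round-trip the full
parameter set through YAML (a reference copy ships in
`inst/extdata/default_config.yaml`); `run_analysis()` and friends write
traces, tables and a reproducibility manifest to disk, and
`inst/cli/pdrcea.R` wraps them for shell use.

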