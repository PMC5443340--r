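# embryoloss

How many naturally conceived human embryos die before birth? Widely quoted
answers — 78%, "most embryos", "half of all conceptions" — trace back to a
handful of historical computations whose arithmetic is rarely re-examined.
`embryoloss` implements each of those computations as tested, reusable R
code so that the estimates, their sensitivity to speculative inputs, and
their sampling uncertainty can be reproduced and probed.

## The framework

A menstrual cycle's reproductive outcome is decomposed into conditional
stage probabilities:

* π_SOC — sperm–ovum co-localisation (coital timing and ovulation),
* π_FERT — fertilisation given co-localisation,
* π_HCG — implantation of a fertilised ovum, marked by hCG elevation,
* π_CLIN — progression of an implanted embryo to clinical recognition,
* π_LB — live birth given clinical pregnancy.

Cumulative products give per-cycle fecundabilities, e.g.
FEC_HCG = π_SOC · π_FERT · π_HCG and
FEC_LB = π_SOC · π_FERT · π_HCG · π_CLIN · π_LB. Pre-implantation embryo
loss is 1 − π_HCG; loss before clinical recognition is 1 − π_HCG · π_CLIN.

On top of this framework the package provides:

* **`conception_ledger()` / `adjusted_params()` / `simulate_sensitivity()`** —
  the Roberts & Lowe annual conception ledger (England & Wales, 1971), its
  ±25% / ±10% deterministic scenarios, and a Monte Carlo sensitivity
  analysis drawing the five speculative inputs from normal distributions
  with 20% coefficient of variation.
* **`gestation_life_table()` / `interval_loss_probabilities()` /
  `kauai_scenarios()`** — an actuarial life table for pregnancies under
  staggered study entry (new entrants at risk for half an interval),
  including the re-allocation of the Kauai Pregnancy Study's weeks 4–7
  entries and losses and two perturbations of it.
* **`hertig_fixture()` / `derive_estimates()` / `balanced_bootstrap()` /
  `bootstrap_summary()` / `clopper_pearson()` / `agresti_coull()`** — the
  Hertig–Rock 107-case embryo-collection data, the normal/abnormal-embryo
  derivation behind the famous 84% fertilisation and 30% pre-implantation
  loss figures (with its counterfactuals), balanced-bootstrap percentile
  confidence intervals and exact/approximate binomial intervals.
* **`studies_fixture()` / `raw_fec_hcg()` / `survival_to_clinical()` /
  `loss_rates()`** — summary statistics over thirteen prospective hCG
  early-pregnancy cohorts.
* **`simulate_cohort()` / `simulate_hertig_study()`** — seeded generators
  for synthetic per-cycle hCG cohorts (fertile/sub-fertile mixture) and
  cross-sectional embryo-collection studies, used to validate every
  estimator against a known truth.
* **`run_report()`** — regenerates all tables and figure data as CSV/JSON
  artefacts with a checksummed manifest.

## Worked example

```r
library(embryoloss)

conception_ledger(roberts_lowe_params())
#> Conception ledger (per year):
#>   acts of coitus                253448000
#>   unprotected acts               63362000
#>   fertile-period acts             4525857
#>   fertilised ova                  2262929
#>   embryos lost                    1757929
#>   loss fraction                      77.7%
```

2,262,929 estimated conceptions against 505,000 births gives the famous
"78% of conceptions are lost" — but `simulate_sensitivity()` shows the
figure collapses to 22% or climbs to 92% under modest input changes, so
the point estimate carries no practical precision.

```r
interval_loss_probabilities(kauai_scenarios()$leridon)
#>  label new_entries losses at_risk q_pct survivors_index
#>    4-5          80      2      40   5.0             100
#>    5-6         120      6     138   4.3              95
#>    6-7         180     10     282   3.5              91
#>    7-8         212     14     468   3.0              88
#> overall loss: 15.0%
```

The same 592 entries and 32 losses give 10.9% or 19.1% overall loss when
just two first-week losses are re-allocated (`kauai_scenarios()$shift_out`
and `$shift_in`) — the earliest interval's estimate is that fragile.

```r
estimates_from_caseset(hertig_fixture())
#> Embryo-loss estimates (% of late cases unless stated):
#>   fertility                 41.7
#>   sterility                 41.7
#>   infertility               16.7
#>   fertilisation_rate        83.3
#>   preimplant_loss           30.0
#>   ...

bootstrap_summary(hertig_fixture(), 500, seed = 2)
#> Balanced bootstrap (500 datasets, 5 invalid excluded), 95% CIs:
#>              quantity median lower upper
#>             fertility     41    27    59
#>             sterility     42     6   187
#>           infertility     15  -132    58
#>   preimplant_survival     69    26   132
#>  postimplant_survival     71    52    89
#>        detection_rate     59    43    75
```

The derivation reproduces the canonical 42/42/16 fertility–sterility–
infertility split and 30% pre-implantation loss, while the bootstrap shows
how imprecise those figures are: the pre-implantation survival interval
spans 26–132%, and shifting one pre-implantation embryo between the
normal and abnormal columns moves the loss estimate from 30% to 13% or
48%.

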