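---
title: "Methods: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryoloss)
```

This vignette documents the models implemented by `embryoloss`, the
conventions they rely on, and the choices made where the historical
sources are silent. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The stage-probability framework

Reproduction in one menstrual cycle is modelled as a chain of conditional
Bernoulli stages: sperm–ovum co-localisation (π_SOC), fertilisation
(π_FERT), implantation with hCG elevation (π_HCG), clinical recognition
(π_CLIN) and live birth (π_LB). Each probability conditions on all
upstream successes, so per-cycle fecundabilities are cumulative products
(`fecundabilities()`) and are non-increasing from FEC_TOT down to FEC_LB.
The decomposition is an accounting identity, not a biological model: it
assumes only that the stages are ordered and exhaustive. Loss fractions
follow directly: `1 - pi_hcg` of fertilised ova perish before
implantation, `1 - pi_hcg * pi_clin` before clinical recognition.

`build_egg_life_table()` chains per-cycle fertilisation and the two
post-fertilisation transitions into survivor counts per 100 cycles. All
chaining uses unrounded values; `survivors_rounded` is display-only. The
historical tables themselves are internally inconsistent at the display
level (83 vs 84 fertilised eggs per 100 cycles, 16.7% printed as 16%), so
the package never lets display rounding feed back into computation —
rounding happens once, at the edge, with `round_half_up()` (ties away from
zero, matching how the printed tables round 19.05 to 19.1).

The two-exponential survival curve
`P(t) = 0.73 e^(-0.155 t) + 0.27 e^(-0.00042 t)` (`boklage_survival()`)
is evaluated verbatim from its published coefficients. Direct evaluation
gives 0.296 at *t* = 21 days, although the curve was reportedly
normalised to 0.287 at that point; the package does not rescale the
coefficients to resolve the discrepancy, because any rescaling would be
an arbitrary re-fit and re-fitting this model is out of scope. The curve
is provided for evaluation only.

## The conception ledger and its sensitivity

`conception_ledger()` chains the annual-conception arithmetic: acts of
coitus (women × weekly frequency × 52), the unprotected fraction, the
fertile-period fraction (`fertile_len / cycle_len`), the fertilisation
probability, and finally embryos lost as conceptions minus births. Two
inputs are reliable counts (2,437,000 women; 505,000 births); five are
speculative rates (2 acts/week, 25% unprotected, 28-day cycle, 2-day
fertile period, 50% fertilisation). Deterministic scenarios multiply the
four non-cycle speculative rates by 0.75 or 1.25 and cycle length by 1.10
or 0.90 — in opposite directions, because a longer cycle dilutes the
fertile window. No intermediate rounding is applied anywhere: the low
scenario works with 0.1875 and 30.8 days exactly, which is what makes its
printed intermediates (35,641,125; 1,735,769; 650,913) reproducible.

`simulate_sensitivity()` propagates input uncertainty: each of the five
speculative rates is drawn independently (no covariance) from
Normal(mean = ledger value, sd = 0.20 × mean). Three conventions are not
stated by the source and are fixed here as package policy:

* **Degenerate draws are rejected and redrawn** (non-positive values,
  probabilities above 1, fertile period longer than the cycle). At CV
  20% these are roughly 4–5σ events — a fraction of a percent of draws —
  and biologically meaningless; redrawing keeps every record evaluable.
  The count is reported as `n_redrawn`.
* **Loss values are not truncated.** A draw with fewer estimated
  conceptions than observed births yields a negative loss percentage.
  Retaining the left tail is what makes the mean of the simulated losses
  fall below their median, as the summaries show.
* **Percentiles use linear interpolation between order statistics**
  (type 7, the default of mainstream numeric environments). At 10,000
  records per repetition the difference between quantile conventions is
  far below reporting precision; the choice is verified in tests against
  a hand-rolled order-statistic oracle.

Per repetition, the mean, median and 2.5th/97.5th percentiles of the
loss values are recorded and then averaged over repetitions. The default
experiment is 1,000 repetitions × 10,000 records; the test suite runs the
full experiment once plus a 100-repetition replicate, sizes chosen as the
package's own desk-scale defaults.

## The staggered-entry life table

Pregnancy-loss studies enrol women at different gestational ages, so an
interval's at-risk denominator cannot be its enrolment count. The
convention implemented by `interval_loss_probabilities()` counts
survivors carried from earlier intervals at full exposure and new
entrants at half exposure: `at_risk_i = carried + entries_i / 2`,
`q_i = losses_i / at_risk_i`, with survival chained multiplicatively from
an index of 100. This is the standard actuarial treatment of mid-interval
entry, and it is the only candidate convention (full exposure, half
exposure, exposure net of same-interval losses were each evaluated) that
reproduces all four published weekly loss probabilities
(5.0, 4.3, 3.5, 3.0%) and the 15.0/10.9/19.1% overall losses from the
re-allocated Kauai data; the enumeration is kept as a test.

`kauai_scenarios()` fixes the three loss allocations (2/6/10/14, 0/6/11/15,
4/6/9/13 across entries 80/120/180/212). The scenarios demonstrate the
leverage of the earliest interval: moving two losses out of or into week
4–5 moves the overall weeks 4–8 loss from 15.0% to 10.9% or 19.1%. A
possible correlation between study entry and early loss is discussed in
the source literature but not quantified; it is not modelled here.

## The embryo-collection derivation and its uncertainty

`derive_estimates()` implements the reasoning applied to the 107-case
hysterectomy series: among `n_late` cases past the first missed period,
`k_norm` normal and `k_abn` abnormal embryos were found; the
pre-implantation sample (`m_norm`, `m_abn`) fixes the abnormal fraction
`p` at fertilisation. Assuming every normal embryo implants and the
normal:abnormal ratio at fertilisation equals the observed
pre-implantation ratio, the implied abnormal fertilisations are
`k_norm * p / (1 - p)`, of which those not observed implanted must have
failed to implant. Fertility, sterility and infertility (which sum to
100% as an algebraic identity), the fertilisation rate, and
pre-implantation loss all follow. The derivation's fragility is the
point: with the canonical 4/8 abnormal pre-implantation embryos the loss
is 30%, with 3/8 it is 13%, with 5/8 it is 48% and the implied
fertilisation rate exceeds 100%.

`estimates_from_caseset()` pools the two pre-implantation strata, uses
the post-missed-period stratum as the late sample, and excludes the
days 20–24 stratum — the omission made in the original analysis, since
its five normal, zero abnormal embryos cannot be reconciled with the
model's assumptions.

Degenerate inputs return a flagged result rather than an error, so
bootstrap replicates can be filtered. Two flags are distinguished:

* `valid = FALSE` — the estimates are not computable: no late cases, no
  pre-implantation embryos, or an all-abnormal pre-implantation sample
  (`p = 1`). These replicates are excluded from bootstrap summaries and
  counted in `n_invalid` (about 1–2% of replicates, since only 4 of the
  107 cases carry a normal pre-implantation embryo). Exclusion is the
  policy adopted here because the published interval endpoints are
  finite, which unbounded replicates would preclude; the original
  handling is undocumented, so interval-endpoint comparisons in the
  tests use deliberately loose tolerances.
* `consistent = FALSE` — the estimates are computable but the observed
  abnormal implants exceed the implied total (negative implied
  implantation failures, hence a negative pre-implantation loss). These
  replicates are **retained**: they are finite, and the published
  intervals themselves include out-of-range values (a negative
  infertility bound, survival above 100%), showing such replicates
  entered the original summaries.

`balanced_bootstrap()` uses balanced resampling: the 107 cases are
replicated `B` times, pooled, permuted and sliced into `B` pseudo-datasets
of 107, so each original case appears exactly `B` times overall. The
balance property is exact on every run and is asserted as such.
Percentile intervals use the same type-7 quantile convention as the
Monte Carlo module. Binomial intervals for simple proportions are
provided by `clopper_pearson()` (beta-quantile inversion of the binomial
tails; exact by construction, verified in tests against a direct
tail-inversion root-finder) and `agresti_coull()` (pseudo-count adjusted
Wald; bounds reported unclipped).

The fixture uses the 24 normal / 10 abnormal embryo classification; an
alternative classification counting three positionally questionable
embryos as abnormal (21/13) exists and can be explored by constructing a
custom `hertig_cases()` table.

## The hCG study table

`studies_fixture()` stores the published counts of the thirteen hCG
cohorts. Recomputed statistics (`raw_fec_hcg()`, `survival_to_clinical()`,
`loss_rates()`) are ratios with no modelling content; the
loss-to-live-birth column is stored as published rather than recomputed
because live-birth counts are unavailable for several studies and the
follow-up endpoint differs between them (some stop at late pregnancy).
No meta-analytic pooling is attempted — the studies differ in assay,
design and clinical-pregnancy definition, and the package's purpose is
to reproduce the tabulated values, not to synthesise them.

## What the synthetic generators emulate

`simulate_cohort()` emulates the prospective hCG study design: couples
monitored cycle by cycle until the first hCG-detected pregnancy (then
resolved to clinical recognition and live birth) or censoring at
`max_cycles`. Fertility heterogeneity is a latent two-point mixture —
normally fertile and sub-fertile classes — following the re-analysis of
the large cohorts that identified discrete sub-cohorts; a continuous
fecundability distribution is deliberately not used. Defaults are
Wilcox-like and were fixed once: 28.1% sub-fertile; fertile couples with
π_SOC = 0.80 (reflecting sub-daily coital frequency in the fertile
window), π_FERT = 0.90 and π_HCG = 0.60, giving the fertile-class
per-cycle hCG fecundability of 43.2%; π_CLIN = 0.783; and π_LB = 0.851 so
that roughly one third of hCG pregnancies fail before live birth. The
individual values of π_FERT and π_HCG behind the 43.2% product are not
identifiable from cohort data and their split here is a modelling
convenience. One pregnancy per couple, with no return to risk after a
loss, matches the per-cycle denominators of the raw fecundability
estimators applied to the real studies.

`simulate_hertig_study()` makes the longitudinal truth behind the
cross-sectional embryo collection explicit: per case, fertilisation with
`true_fert_rate` (coital timing folded in, as the strata already
condition on documented ovulation and coitus), abnormality with
`true_abnormal_frac`, survival of abnormal embryos through implantation
with `abnormal_implant_prob` (normal embryos survive to week two by
assumption, mirroring the derivation), and stratum-specific detection.
Default detection probabilities (0.133, 0.56, 0.182, 1.0) are calibrated
so that, under the canonical data's implied truth (fertilisation 30/36,
half of embryos abnormal, 40% of abnormal embryos implanting), the
expected observed embryo counts match the canonical table — encoding the
very feature the derivation is criticised for: detection rates before
day 25 are far below the post-day-25 rate.

What passing tests show — and what they do not: parameter recovery on
these generators validates the estimators *under the generators' own
assumptions* (independent Bernoulli stages, a two-point mixture,
detection independent of embryo type). Real cohorts have cycle-to-cycle
dependence, behavioural responses to non-conception, assay thresholds
and reporting artefacts that the generators do not emulate, so recovery
here does not certify the estimators against real data.

## Numerical conventions, sizes and limitations

* Quantiles: type 7 everywhere (Monte Carlo summaries, bootstrap
  percentile intervals), asserted against brute-force order-statistic
  oracles.
* Rounding: `round_half_up()` at the display/report edge only; all
  internal arithmetic unrounded.
* Randomness: every stochastic function takes an explicit seed and is
  bit-reproducible given one; `run_report()` derives per-stage seeds by
  fixed offsets from its global seed.
* Problem sizes: the test suite runs the Monte Carlo at 1,000 × 10,000
  (once) and 100 × 10,000, the bootstrap at 500 replicates, and cohort
  recovery at 1,500–2,000 couples; these are the package's default
  desk-scale experiment sizes.
* Limitations: the ledger ignores induced abortion and lactational
  sub-fecundability; the life table does not model entry–loss
  correlation; the two-exponential curve is evaluated, never re-fitted;
  the hCG table is tabulated, not pooled; Hertig-sampler truth values
  are identifiable only because the generator fixes them.
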