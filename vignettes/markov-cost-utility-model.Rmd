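---
title: "A Markov cohort cost-utility model for long-acting injectable antipsychotics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-utility model for long-acting injectable antipsychotics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppcea)
```

## The decision problem

Schizophrenia is a chronic relapsing illness in which poor medication
adherence drives relapse and costly rehospitalization. Long-acting
injectable paliperidone palmitate — given monthly (PP1M) or quarterly
(PP3M) — improves adherence relative to the daily oral extended-release
formulation (ER), at a much higher drug price. `ppcea` implements a cohort
state-transition model that asks whether the injectables' clinical
advantage is worth their price from a healthcare-system perspective,
measured as cost per quality-adjusted life year (QALY).

## Model structure and assumptions

Five mutually exclusive states follow the natural course of the illness:
**non-stable** (acute symptoms), **stable/adherent**,
**stable/non-adherent** (autonomous treatment discontinuation), **relapse**,
and **death**. The whole cohort enters non-stable at age 38 and advances in
3-month cycles — long enough for a state change given the pharmacokinetics
of the quarterly injection — for 20 years (80 cycles).

Structural assumptions, all fixed over the horizon:

1. treatment efficacy and event probabilities are time-constant;
2. drug intolerance and adverse-event costs are ignored (they contribute
   under 1% of total cost in this indication);
3. relapse is a one-cycle tunnel: survivors re-enter the non-stable state
   the next cycle;
4. there is no return path from non-adherence to adherence other than
   through relapse;
5. acute (non-stable) patients receive only ER or PP1M — the quarterly
   formulation is licensed only after stabilization — so the PP3M arm bills
   PP1M's drug cost during non-stable cycles.

Mortality is one age-banded schedule for schizophrenia (seven bands,
35–78 years, clamped outside), identical across states and arms. It is
applied first, as a competing risk: the per-cycle death probability `q` is
taken at the cohort's current age, and every printed transition probability
acts conditionally on survival, scaled by `1 - q`. This guarantees valid
row-stochastic matrices with no renormalization surprises.

## Rates, probabilities, and cycle length

Trial event rates `S` observed over `t` months become per-cycle
probabilities under a constant-hazard assumption:

`r = -ln(1 - S)/t`, `P = 1 - exp(-r T)`, `T = 3` months.

```{r}
rate_to_cycle_prob(0.1119, 12, 3)   # 12-month relapse rate -> per-cycle
```

The embedded reference fixture stores the converted per-cycle values as
published. One published entry disagrees with its own conversion: the PP3M
stable-state relapse probability is printed as 0.0240, while the formula on
the 9.24% twelve-month rate gives `r round(rate_to_cycle_prob(0.0924, 12, 3), 6)`,
which rounds to 0.0239. The package (tests and acceptance report alike)
asserts the formula's value and treats the printed entry as a rounding
slip.

## Accrual conventions

**Half-cycle correction.** State memberships are averaged over consecutive
cycle boundaries before any accrual, so costs and QALYs approximate
mid-cycle exposure. Discounting matches: cycle `k` carries
`(1 + r)^-(k - 0.5) * T/12` with `r = 0.05`/yr. End-of-cycle discounting is a
documented alternative the implementation deliberately does not use, since
mixing it with half-cycle-corrected memberships double-counts half a cycle.

**Utility scale.** The published utilities (0.23 stable, 0.15 non-stable)
are interpreted as *per-cycle* QALY weights — equivalently annual utilities
of 0.92 and 0.60. The alternative reading (EQ-5D indices multiplied by
cycle length in years) caps lifetime QALYs near 4.6 over 20 discounted
years and cannot produce totals of 8.6–9.5 QALYs; the per-cycle reading
can. The relapse state, whose weight is not published, reuses the
non-stable weight: both are acute-symptom states.

**State costs.** Per cycle: non-stable accrues drug + non-stable
outpatient + hospitalization cost weighted by the per-cycle hospitalization
probability; stable/adherent accrues drug + stable outpatient;
stable/non-adherent accrues outpatient only (treatment discontinued —
adherence defines drug exposure, symptom state defines utility); death
accrues nothing.

**Relapse costing.** The relapse state accrues non-stable outpatient cost;
whether it also bills a full admission is the
`relapse_hospitalization_policy` flag. The default is `"never"`, a
deliberate deviation from an `"always"` default one might expect given that
relapse burden is usually attributed to hospitalization. The evidence is
internal consistency: under `"always"` the reference fixture makes ER the
*most* expensive strategy (≈ $54.3k vs PP3M's ≈ $45.8k) and both
injectables dominate, contradicting the published cost ordering
(ER < PP3M < PP1M) and both published positive ICERs. Under `"never"` every
qualitative conclusion reproduces. Hospitalization already enters through
the non-stable state that every relapse feeds, so `"never"` is also the
structurally coherent reading.

## What the base case establishes

```{r}
params <- reference_parameters()
res <- run_all_arms(params)
comparison_table(res, gdp = params$config$wtp_per_qaly)
```

The package's totals are higher than the published ones (for example
`r round(res$ER$total_qaly, 2)` rather than 8.60 QALYs for ER) because the
published analysis left several conventions unstated — the relapse costing
above, the exact ER conversion windows, whether outpatient costs are per
cycle or per year — and its unrounded internals are unavailable. The test
suite therefore asserts the *decision-relevant* structure, which is robust
to those choices: cost ordering ER < PP3M < PP1M, QALY ordering
ER < PP1M < PP3M, PP3M dominating PP1M, both ICERs below the
$12,756.55/QALY threshold, drug costs leading the tornado, strictly falling
cumulative-horizon ICERs, and monotone scenario responses. A perturbation
check (every parameter jittered ±10%, 50 seeds) shows the dominance
conclusion survives in all 50 draws.

## Sensitivity machinery

**Tornado.** Each parameter in the registry is set to its low and high
bound in turn; both arms are rerun; the raw incremental-cost over
incremental-QALY ratio at each bound is recorded. A bar crossing zero means
the bound tips the comparison into dominance; only a bound with zero
incremental QALYs (ICER undefined) or an unbuildable model is flagged.
Ordering is deterministic: width descending, ties by identifier. The
registry collapses each drug's price to a single parameter — the PP1M
price moves the PP1M arm's two cost slots *and* the PP3M arm's non-stable
cost — mirroring how the published one-way analysis varies "the cost of
PP1M" as one quantity. The discount rate is varied over 0–8%/yr.

**PSA.** 1,000 Monte Carlo iterations; probabilities and utilities draw
from Beta, costs from Gamma, both fitted by the method of moments with
every published range read as a 95% interval (`sd = range/3.92` — the
publication does not state how its ranges parameterize the fits, so one
convention is applied uniformly; for ±10%/±20% ranges this is conservative
in neither direction). Draws are shared across arms for shared parameters
(hospitalization, outpatient costs, utilities); independent per-arm draws
are one flag away but are not the default, since shared quantities are the
same object in the real world. A draw violating
`p_disc_stable + p_relapse_stable <= 1` redraws that pair only, keeping the
iteration count exact; redraws are counted in the result's diagnostics.
Degenerate check: with every family forced to `fixed`, all 1,000 iterations
equal the base case bit-exactly.

**CEAC.** The probability that the intervention is cost-effective at
threshold λ is the fraction of iterations with strictly higher net monetary
benefit; ties count for the comparator, so the two curves of a pairwise
comparison always sum to one. The published acceptance probabilities at
the WTP threshold (59.2%/66.0%) are *not* reproduced — they inherit the
unavailable internals above — and are not asserted.

**Scenarios.** Three swept axes, each anchored at the base case: drug price
multipliers {1, 0.89, 0.8, …, 0.1} (0.89 marks the observed generic-ER
discount; the default cuts all three prices, `pp_only = TRUE` restricts the
cut to the injectables), hospitalization cost multipliers
{1.2, 1, 0.8, 0.6, 0.4, 0.2} (hospital-level variation), and horizons
{1, 5, 10, 20, 30, 40} years. The cumulative-horizon series
(`icer_by_cycle`) reruns each truncated horizon as its own
half-cycle-corrected model.

## The microsimulation oracle

`microsim_oracle()` pushes individual patients through exactly the same
transition matrices and accrual rules as the cohort engine, with a seeded
RNG. It is the package's independent check: cohort totals must fall within
3 Monte Carlo standard errors of the microsimulation means at n = 100,000
on the reference fixture (and on 20 synthetic sets at n = 20,000, scaled
down purely for test-run time — the 3-SE criterion is unchanged, the
standard errors are simply wider). The oracle shares the matrix builder
with the engine by design: it validates the trace arithmetic, accrual, and
correction conventions, not the matrix construction, which is covered by
exact closed-form tests instead.

## The synthetic generator

`random_parameter_set()` draws complete parameter tables uniformly within
configurable ranges: probabilities in [0.005, 0.4] (bracketing the
published table's per-cycle magnitudes), costs in [$50, $2,500], per-cycle
utilities in [0.1, 0.25] with acute states never better than stable, a
four-band mortality schedule rising with age, and a discount rate in
[0, 8%]/yr. Uniform — not Beta/Gamma — because the goal is coverage of the
valid parameter space for property testing, not mimicry of the PSA.
Infeasible draws are rejected (capped at 1,000 attempts) so generated sets
always validate. What a green synthetic test establishes is therefore
*engine* correctness over the whole valid space; it says nothing about any
particular drug's cost-effectiveness. Degenerate fixtures (`no_relapse`,
`no_mortality`, `immediate_death`, `zero_discount`, `single_cycle`) pin the
engine to closed forms.

## Numerical choices and degenerate inputs

- Probability-zero mortality is represented by a tiny positive value
  (1e-12) in the `no_mortality` fixture, since validation requires annual
  probabilities strictly inside (0, 1).
- A rate of exactly 1 maps to probability 1 directly (the hazard is
  infinite); the conversion is otherwise computed via `log1p` for accuracy
  at small rates.
- Sensitivity ranges that would exceed 1 are capped at 1 (the published
  table does the same for the ER non-adherent relapse range), which
  truncates the implied sd of that Beta fit.
- Equal-cost equal-QALY comparisons return `equal_effects` with an
  undefined ICER rather than throwing; downstream verdicts report
  `not_classifiable`.
- ICER-undefined points in scenario sweeps are `NA` and flagged, never
  silently dropped.

## Known limitations

- The published totals, per-cycle ICER table, and PSA probabilities are not
  reproduced quantitatively; only their orderings and decision conclusions
  are (see above for why).
- The ER transition rows are accepted as printed rather than re-derived:
  they are mutually consistent only under source-trial observation windows
  the publication never states.
- No treatment switching, no adverse-event states, no time trends, no
  indirect or intangible costs, no currency/inflation machinery — all
  outside the model's stated scope.
- Whether outpatient costs are per cycle or per year is unstated in the
  source; per cycle is assumed throughout and flagged here.
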