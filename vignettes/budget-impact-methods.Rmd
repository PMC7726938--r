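---
title: "Methods: costing the withdrawal of More Doctors Program physicians"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: costing the withdrawal of More Doctors Program physicians}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmmbimpact)
```

## The problem

Between 2015 and 2019 the *Programa Mais Médicos para o Brasil* (PMMB)
staffed family-health (FHS) teams in 373 municipalities of the state of São
Paulo with 2,533 federally paid physicians. A 2019 rule change restricted
physician replacement to municipalities in the highest vulnerability classes
(indicator 4 and above). Everywhere else, physicians leave when their
three-year contract cycle closes and are not replaced; a municipality that
wants to keep its coverage must hire a physician itself, under the CLT labor
code, at its own expense.

This package computes the resulting budget impact over the 39 months from
January 2019 to March 2022, separately for the two payers:

* the **Ministry of Health (MH)**, which pays physician scholarships, the
  supervision references, and the variable Primary Care Floor (PCF) transfer
  to each FHS team — reduced from R$ 7,130.00 to R$ 4,000.00 per month while
  a program physician staffs the team;
* the **municipalities**, which pay housing and food aid for program
  physicians and, after the rule change, the full employer cost of every
  replacement hire, partially offset by the restored full PCF transfer.

The analysis is deterministic: a scenario cost stream (physicians leaving on
the published cycle schedule, replacements hired immediately) is compared
with a counterfactual stream in which the January 2019 program ceiling
persists across the whole horizon. The impact per payer is the difference
between the two streams; a fixed ±30% band around each impact provides the
one-way sensitivity analysis. No discount rate is applied — the cost levels
themselves change at every cycle, and the projection is a nominal budget
exercise, not a welfare evaluation (a `discount_rate_annual` hook exists in
`expand_schedule()` for exploration but is zero in all headline runs).

## Payroll model

The anchor of the municipal side is the cost of one replacement hire whose
*net* monthly pay equals the program scholarship of R$ 11,865.60, so that the
position is exactly as attractive as the program post it replaces.
`gross_from_net()` inverts the deduction chain

$$\text{net}(g) = g - \min(r_e\, g,\ \text{cap}) - \tau\!\left(g - \min(r_e\, g,\ \text{cap})\right)$$

where \(r_e\) is the employee INSS rate (11%), cap the 2019 ceiling
contribution (R$ 642.34), and \(\tau\) the monthly income-tax table in
deduction-parcel form (`income_tax()`): the bracket's marginal rate applied
to the whole taxable amount minus the bracket's parcel, floored at zero.
Because the parcels telescope, \(\tau\) equals the band-by-band marginal sum
and is continuous at bracket boundaries — both properties are tested. The
net function is piecewise linear and monotone, so the solver enumerates the
analytic inversion of every (bracket × contribution-regime) piece and keeps
the self-consistent one, with a guarded bisection fallback that fails loudly
rather than returning an unconverged value.

```{r payroll}
gross <- gross_from_net(11865.60)
gross
b <- net_from_gross(gross)
round_brl(c(monthly = b$monthly_employer_total, annual = b$annual_employer_total))
```

The monthly employer total is `gross × (1 + 20% INSS quota + 8% FGTS)`. The
annual total is assembled from labeled components
(`rules$annual_composition`). Its default composition — twelve monthly
totals, vacation pay with the one-third bonus, the employer quota on that
vacation pay, the 13th salary and the FGTS on the 13th — deliberately
excludes the termination-notice items and the employer quota on the 13th:
with the notice items included the figure would price every year as if it
ended in dismissal, which is not what a steady-state replacement post costs,
and the chosen composition is the one consistent with the widely quoted
annual figure for this wage level. The composition is a plain character
vector, so either convention is one argument away.

## Precision and rounding

All internal arithmetic is carried at full double precision; rounding
half-up to cents (`round_brl()`, the spreadsheet convention rather than
banker's rounding) happens only at reporting boundaries. This choice is not
cosmetic. The replacement wage used in the municipal cost formula is the
*unrounded* employer total `15,809.57 × 1.28 = 20,236.2496`; carrying the
cents-rounded `20,236.25` instead shifts the 39-month municipal total by
about R$ 14 and every non-baseline municipal cell by a visible sub-real
amount. The sub-real digits printed in the reference results table (e.g.
`10,452,099.85` for the 9th cycle) are only reproducible with the unrounded
wage, which is therefore the default; `cost_parameters(physician_wage_monthly
= 20236.25)` restores the rounded convention explicitly.

## Per-cycle cost formulas

With `n` physicians remaining out of a baseline `N` (so `Δ = N − n`
departures), monthly costs are:

* **MH:** `Ref + n·(scholarship + PCF_PMMB) + Δ·PCF_dif`, where
  `Ref = 6,500 + 7 × 6,000 = 48,500` is the supervision-reference cost,
  `PCF_PMMB = 4,000` the reduced per-team transfer and
  `PCF_dif = 7,130 − 4,000 = 3,130` the transfer restored per departed
  physician. `PCF_dif` is always derived from the two PCF levels, never set
  directly.
* **Municipality (general):** `n·(food + rent) + Δ·wage − Δ·(PCF_PMMB +
  PCF_dif)` — counterpart aid of R$ 600 + R$ 2,000 per remaining physician,
  the full employer wage per replacement, minus the restored full transfer.
* **Municipality (baseline month(s)):** two conventions are implemented.
  The default, `"as_printed_table"`, books the baseline as
  `N·(food − PCF_PMMB) = 2,533 × (600 − 4,000) = −8,612,200` — food aid as
  the cash outlay and the PCF transfer as a receipt, with rent treated as an
  in-kind counterpart. It is the only reading that reproduces the reference
  results table, whose baseline row is a net municipal *receipt*. The
  alternative `"as_printed_box"` takes the baseline formula of the costing
  scheme literally, `N·(food + rent + PCF_PMMB)`; it is retained for
  comparison because the two published statements of the baseline are not
  mutually consistent, and the results-table reading is the one the totals
  and impacts are built on.

## From cycles to months

The cycle schedule is a step function: each entry's physician count holds
from its effective month until the month before the next entry, the last
entry running to the horizon end, endpoints inclusive, whole months only
(no pro-rating). For the packaged São Paulo schedule this yields the month
weights

```{r weights}
data.frame(sp_cycle_schedule()$entries, months = month_weights(sp_cycle_schedule()))
```

which sum to 39. This weighting was derived independently before being
frozen into the fixture: it is the unique step-function reading of the
published cycle months that reproduces the published 39-month MH total of
R$ 1,124,135,514.00 exactly. One quirk absorbed here: the published cycle
list repeats an "11th cycle (vacancies until June/2019)" label for the row
with 1,484 physicians; positionally and arithmetically that row is the 14th
cycle effective June 2020, and only that reading closes the totals, so the
packaged schedule labels it accordingly.

Totals, counterfactual (baseline costs × 39), impacts and the ±30% bounds
follow by arithmetic; the decomposition `mh_impact + mh_actual =
mh_counterfactual` is exact and tested. Impacts are stored as magnitudes
with a direction (`saving` for MH, `burden` for municipalities); the report
layer prints the municipal impact with the conventional negative sign.

```{r impact}
params <- sp_cost_parameters()
sch <- sp_cycle_schedule()
imp <- sensitivity(financial_impact(cost_totals(expand_schedule(sch, params)),
                                    counterfactual_totals(sch, params)),
                   params$sensitivity_fraction)
imp
```

## Stratification

A municipality's *dependence* is its program physicians as a share of its
FHS teams. Stratification bins are half-open, `[0,20), …, [60,80)`, with a
closed top bin `[80,100]` — published bin labels overlap at the edges, so a
convention was needed; half-open-with-closed-top is the standard one and
the edges are configurable in `bin_dependence()`. Replacement eligibility
is a simple threshold, `indicator ≥ 4`, applied over whatever indicator
range the data carry (the packaged data have classes 1–6). A municipality
*participates* while it holds at least one program physician; that
definition is what lets the physician series (2,533 → 320) and the
municipality series (373 → 86) drop consistently in `exit_projection()`.

Two published summary percentages do not name the same denominator: a
"76.9% reduction" matches municipalities (287/373) but not physicians
(2,213/2,533 = 87.4%). The package computes and labels both rather than
guessing; the exit-projection data frame carries the raw series from which
either follows.

## The synthetic roster generator

The original analysis assembled its roster from public registries (program
ordinances, the national health-establishment register, the national health
fund portal). Those extractions are not reproducible offline, so the
`synthetic_data` stage generates rosters with the statistical structure the
analysis actually consumes:

* municipalities placed into (dependence bin × vulnerability class) cells —
  exactly, when a cell matrix is supplied, or by seeded random pairing of
  the two marginals otherwise;
* physicians allocated within the eligible and non-eligible groups by equal
  quota, remainder to a seeded random subset, every participating
  municipality receiving at least one;
* team counts chosen per municipality so its dependence lands in its
  assigned bin (smallest feasible count, jittered upward within the bin's
  feasible range);
* contract end months of non-eligible physicians matched exactly to a
  requested per-month departure profile (or sampled from it as weights).

Generation is deterministic given the spec and seed (`roster_spec()`'s
`seed`), and infeasible specs fail naming the violated constraint. The
packaged `sp_roster()` uses the published cross-tab cells and a departure
profile back-solved from the cycle schedule's consecutive differences
(368, 58, 1, 22, 175, 425, 57, 881, 226), so the fixture roster
simultaneously reproduces the cross-tab marginals, the cycle counts and the
exit-projection endpoints. No per-municipality physician counts were ever
published, so any roster consistent with those totals is admissible; the
fixture freezes one such roster per seed and makes no claim of geographic
realism — real rosters are spatially clustered, have heavier-tailed team
counts, and correlate dependence with deprivation in ways the generator
does not emulate. Passing tests on synthetic rosters therefore validate the
*accounting*, not any distributional claim about São Paulo municipalities.

First-year attrition — evidence suggests at least 20.8% of program
physicians drop out within a year — contradicts the analysis's fixed-effect
assumption that every contract runs to term. `apply_attrition()` exists as
an exploratory scenario flag (binomial thinning of the standing cohort
after month 12) and is excluded from every headline computation.

## Numerical and testing choices

* Money comparisons in tests use the printed precision: federal cells to
  the cent, municipal cells within R$ 1.00 (the reference table's own cells
  carry sub-real rounding drift), aggregate totals within R$ 0.05.
* `gross_from_net()` accepts a solution within half a cent of the target
  net before rounding the gross to cents; the round-trip
  `gross_from_net(net_from_gross(g)) = g ± 0.01` is property-tested on
  1,000 wages drawn from R$ 1,000–50,000.
* Degenerate inputs are defined, not special-cased: an empty program
  (`n = 0`) costs the references federally and nothing municipally; an
  empty roster cross-tabulates to zeros; a zero-departure schedule has zero
  impact for both payers.
* Test problem sizes: rosters of 12–50 municipalities for the brute-force
  cross-tab comparisons (100 seeds), 1,000 attrition draws for the binomial
  expectation check, and the full 373-municipality fixture for every
  headline figure. The whole suite runs in well under a minute on one CPU.

## Known limitations

The package reproduces a deterministic, fixed-effect projection: immediate
replacement at a fixed wage, no attrition in the headline, no discounting,
no quilombola/settlement PCF exceptions (absent from São Paulo and
disregarded by assumption), physician-level rather than team-level PCF
accounting, and vulnerability indicators taken as inputs rather than
recomputed from census data. Regional wage variation is represented only
through the flat ±30% sensitivity band.
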