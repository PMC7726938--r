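# pmmbimpact

Deterministic budget-impact analysis of the withdrawal of *Programa Mais
Médicos para o Brasil* (PMMB — More Doctors for Brazil Program) physicians
from the municipalities of the state of São Paulo, January 2019 – March
2022, from the perspective of Brazil's Unified Health System (SUS).

In 2019 the program's replacement rule was restricted to municipalities in
the highest vulnerability classes (indicator ≥ 4). Everywhere else,
physicians leave at the close of their three-year contract cycle and are not
replaced; municipalities that want to keep coverage must hire under the CLT
labor code at their own expense. This package is for health-economics and
health-workforce analysts who want that projection as tested, configurable
code rather than a spreadsheet: every cost parameter, accounting convention
and bin edge is an argument, and a seeded synthetic roster generator stands
in for the public-registry extractions so the whole pipeline runs offline.

## The model

Per calendar month, with `n` physicians remaining out of a baseline
`N = 2,533` (`Δ = N − n` departures):

* **Ministry of Health:** `Ref + n·(PS + PCF_PMMB) + Δ·PCF_dif`, where
  `PS = 11,865.60` is the monthly scholarship, `PCF_PMMB = 4,000` the
  reduced variable Primary Care Floor transfer per staffed family-health
  team, `PCF_dif = 7,130 − 4,000 = 3,130` the transfer restored per departed
  physician, and `Ref = 6,500 + 7·6,000 = 48,500` the supervision
  references.
* **Municipalities:** `n·(food + rent) + Δ·W − Δ·(PCF_PMMB + PCF_dif)`, with
  food and rent aid of `600 + 2,000` per physician and `W` the employer cost
  of a CLT replacement hire whose **net** wage equals the scholarship —
  `W = gross × 1.28 = 15,809.57 × 1.28` from the payroll module (progressive
  income tax, capped INSS contribution, 20% employer quota, 8% FGTS).
* The baseline month books `N·(food − PCF_PMMB)`, a net municipal receipt.

The step-function cycle schedule (10 entries, 39 months) is expanded
month-by-month and summed; the counterfactual holds the baseline for all 39
months; the per-payer impact is scenario minus counterfactual, with fixed
±30% sensitivity bounds. Stratification classifies the 373 municipalities by
program dependence (physicians / FHS teams) and vulnerability class, and
projects the physician and municipality exit.

## Worked example

```r
library(pmmbimpact)
print(net_from_gross(gross_from_net(11865.60)))
#> Celetist payroll breakdown
#>   Gross                            R$ 15,809.57
#>   Employee INSS contribution       R$ 642.34
#>   Income tax                       R$ 3,301.63
#>   Net                              R$ 11,865.60
#>   Monthly employer total           R$ 20,236.25
#>   Annual employer total            R$ 285,204.64
#>   ...
```

Grossing the scholarship up through the 2019 tax tables prices one
replacement hire at R$ 20,236.25/month (R$ 285,204.64/year) for the
employer. Running the full pipeline:

```r
report <- run_pipeline(run_config())
report$impact
#> Budget-impact summary (BRL)
#>   MH total             1,124,135,514.00   counterfactual     1,569,206,527.20
#>   municipal total        593,612,104.77   counterfactual      -335,875,800.00
#>   MH impact              445,071,013.20  (federal saving)
#>   municipal impact       929,487,904.77  (extra municipal burden, reported as -929,487,904.77)
#>   sensitivity +/- 30%:
#>     MH            311,549,709.24 ..       578,592,317.16
#>     municipal     650,641,533.34 ..     1,208,334,276.20
```

Over 39 months the federal payer spends R$ 1.12 billion (saving
R$ 445.1 million against the kept-ceiling counterfactual, since scholarships
stop and only the cheaper restored PCF transfers remain), while
municipalities spend R$ 593.6 million — an extra burden of
R$ 929.5 million relative to the counterfactual in which the program, and
its transfers, had continued (R$ 650.6 million to R$ 1.21 billion under the
±30% band). The exit projection runs from 2,533 physicians in 373
municipalities down to 320 physicians in the 86 replacement-eligible
municipalities; 131 municipalities depend on the program for 40% or more of
their family-health teams.

`run_config(out_dir = "report")` additionally writes every product
(per-cycle table, monthly series, impact block, dependence cross-tab, exit
projection, audit log, parameter dump) as CSV and JSON.
`inst/scripts/run_pipeline.R` is a thin command-line wrapper over the same
function. See `vignette("budget-impact-methods")` for the model's
assumptions, conventions and limitations.

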