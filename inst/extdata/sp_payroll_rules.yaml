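employee_contribution_rate: 0.11
employee_contribution_cap: 642.34
tax_brackets:
- upper_bound: 1903.98
  marginal_rate: 0.0
  deduction_parcel: 0.0
- upper_bound: 2826.65
  marginal_rate: 0.075
  deduction_parcel: 142.8
- upper_bound: 3751.05
  marginal_rate: 0.15
  deduction_parcel: 354.8
- upper_bound: 4664.68
  marginal_rate: 0.225
  deduction_parcel: 636.13
- upper_bound: '.inf'
  marginal_rate: 0.275
  deduction_parcel: 869.36
employer_quota_rate: 0.2
severance_fund_rate: 0.08
vacation_bonus_factor: 0.333333333333
months_per_year: 12
include_13th: yes
annual_composition:
- monthly_employer_x12
- vacation_bonus
- employer_quota_vacation_bonus
- thirteenth_salary
- severance_fund_13th
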