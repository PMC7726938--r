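test_that("employee contribution applies the flat rate up to the ceiling cap", {
  rules <- payroll_rules()
  # a wage far above the 2019 contribution ceiling pays the flat cap
  expect_equal(employee_contribution(15809.57, rules), 642.34)
  expect_equal(employee_contribution(0, rules), 0)
  # below the cap the flat rate applies
  expect_equal(employee_contribution(1000, toy_flat_contribution_rules()), 80)
  expect_error(employee_contribution(-1, rules), "non-negative")
})

test_that("income tax matches the deduction-parcel table and the bandwise oracle", {
  rules <- payroll_rules()
  expect_equal(round_brl(income_tax(15167.23, rules)), 3301.63)
  expect_equal(income_tax(0, rules), 0)
  expect_error(income_tax(-5, rules), "non-negative")

  # toy telescoping table: parcel formulation == band-by-band marginal sum
  toy <- payroll_rules(tax_brackets = toy_bracket_table(),
                       employee_contribution_rate = 0,
                       employee_contribution_cap = 0)
  for (t in c(0, 500, 1000, 1500, 2999.99, 3000, 3001, 10000))
    expect_equal(income_tax(t, toy), bandwise_tax_oracle(t, toy_bracket_table()),
                 tolerance = 1e-10, info = paste("taxable", t))

  # continuity at the default table's bracket boundaries
  for (b in rules$tax_brackets$upper_bound[-5]) {
    lo <- income_tax(b - 1e-6, rules)
    hi <- income_tax(b + 1e-6, rules)
    expect_lt(abs(hi - lo), 0.01)
  }
})

test_that("net_from_gross reproduces the published celetist breakdown", {
  b <- net_from_gross(15809.57)
  expect_equal(round_brl(b$employee_contribution), 642.34)
  expect_equal(round_brl(b$income_tax), 3301.63)
  expect_equal(round_brl(b$net), 11865.60)
  expect_equal(round_brl(b$monthly_employer_total), 20236.25)
  expect_equal(b$annual_employer_total, 285204.64, tolerance = 0.05 / 285204.64)
  # published component lines
  cm <- round_brl(b$component_map)
  expect_equal(unname(cm["vacation_bonus"]), 21079.43)
  expect_equal(unname(cm["employer_quota_vacation_bonus"]), 4215.89)
  expect_equal(unname(cm["thirteenth_salary"]), 15809.57)
  expect_equal(unname(cm["severance_fund_13th"]), 1264.77)
  expect_equal(unname(cm["employer_quota_notice"]), 3161.91)
})

test_that("net equals gross minus deductions and employer ratio is exact", {
  rules <- payroll_rules()
  for (g in c(500, 1903.98, 2500, 5000, 15809.57, 40000)) {
    b <- net_from_gross(g, rules)
    expect_equal(b$net, b$gross - b$employee_contribution - b$income_tax)
    expect_equal(b$monthly_employer_total / b$gross,
                 1 + rules$employer_quota_rate + rules$severance_fund_rate)
  }
  # identity under the zero-deduction toy rules
  expect_equal(net_from_gross(100, toy_identity_rules())$net, 100)
})

test_that("net pay is monotone non-decreasing in gross", {
  rules <- payroll_rules()
  grid <- seq(0, 60000, by = 250)
  nets <- vapply(grid, function(g) net_from_gross(g, rules)$net, numeric(1))
  expect_true(all(diff(nets) >= -1e-9))
})

test_that("gross_from_net inverts net_from_gross", {
  expect_equal(gross_from_net(11865.60), 15809.57)
  expect_equal(gross_from_net(123.45, toy_identity_rules()), 123.45)
  # round trip over the working wage range
  rules <- payroll_rules()
  set.seed(42)
  for (g in round_brl(runif(1000, 1000, 50000))) {
    net <- net_from_gross(g, rules)$net
    expect_lt(abs(gross_from_net(net, rules) - g), 0.011)
  }
  expect_error(gross_from_net(-1), "non-negative")
})

test_that("payroll rule validation rejects malformed schedules", {
  expect_error(payroll_rules(employer_quota_rate = 1.2), "\\[0, 1\\]")
  expect_error(payroll_rules(tax_brackets = data.frame(
    upper_bound = c(2000, 1000, Inf), marginal_rate = c(0, .1, .2),
    deduction_parcel = c(0, 0, 0))), "increasing")
  expect_error(payroll_rules(tax_brackets = data.frame(
    upper_bound = c(1000, 2000), marginal_rate = c(0, .1),
    deduction_parcel = c(0, 0))), "unbounded")
  expect_error(payroll_rules(tax_brackets = data.frame(
    upper_bound = c(1000, Inf), marginal_rate = c(0, .1),
    deduction_parcel = c(0, -5))), "non-negative")
})

test_that("currency parsing accepts Brazilian and ISO formats", {
  expect_equal(parse_brl("R$ 15.809,57"), 15809.57)
  expect_equal(parse_brl("15,809.57"), 15809.57)
  expect_equal(parse_brl(c("642.34", "3,301.63", "1.234")), c(642.34, 3301.63, 1234))
  expect_equal(parse_brl("285.204,64"), 285204.64)
  expect_error(parse_brl("abc"), "unparseable")
})

test_that("half-up rounding follows the spreadsheet convention", {
  expect_equal(round_brl(c(2.345, 2.344, -2.345, 0.005)),
               c(2.35, 2.34, -2.35, 0.01))
})
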