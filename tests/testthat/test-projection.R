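test_that("schedule validation enforces the step-function invariants", {
  expect_error(cycle_schedule("a", "2020-02", 5, "2020-01", "2020-06"),
               "horizon start")
  expect_error(cycle_schedule(c("a", "b"), c("2020-01", "2020-01"), c(5, 4),
                              "2020-01", "2020-06"), "increasing")
  expect_error(cycle_schedule(c("a", "b"), c("2020-01", "2020-03"), c(4, 5),
                              "2020-01", "2020-06"), "non-increasing")
  expect_error(cycle_schedule(c("a", "b"), c("2020-01", "2020-09"), c(5, 4),
                              "2020-01", "2020-06"), "outside")
  expect_error(cycle_schedule("a", "2020-13", 5, "2020-13", "2020-13"), "month")
})

test_that("the packaged schedule expands to the expected month weights", {
  sch <- sp_cycle_schedule()
  expect_equal(month_weights(sch), c(2, 1, 2, 2, 6, 4, 7, 11, 3, 1))
  expect_equal(sum(month_weights(sch)), n_horizon_months(sch))
  expect_equal(n_horizon_months(sch), 39L)
  s <- expand_schedule(sch, cost_parameters())
  expect_equal(nrow(s), 39L)
  expect_equal(s$month, do.call(function(a, b) {
    # contiguity: every calendar month of the horizon, in order
    f <- seq(as.Date(paste0(a, "-01")), as.Date(paste0(b, "-01")), by = "month")
    format(f, "%Y-%m")
  }, as.list(sch$horizon)))
})

test_that("a single-entry schedule yields identical monthly records", {
  sch <- cycle_schedule("only", "2020-01", 10, "2020-01", "2020-03")
  s <- expand_schedule(sch, cost_parameters())
  expect_equal(nrow(s), 3L)
  expect_equal(length(unique(s$mh_cost)), 1L)
  expect_equal(length(unique(s$municipal_cost)), 1L)
  expect_equal(unique(s$n_physicians), 10L)
})

test_that("39-month totals reproduce the published table", {
  p <- cost_parameters()
  tot <- cost_totals(expand_schedule(sp_cycle_schedule(), p))
  expect_equal(unname(tot["mh"]), 1124135514.00)
  expect_equal(unname(tot["municipal"]), 593612104.77, tolerance = 0.05 / 593612104.77)
})

test_that("month-by-month summation agrees with weight-dot-cost accumulation", {
  p <- cost_parameters()
  sch <- sp_cycle_schedule()
  w <- month_weights(sch)
  nb <- sch$entries$n_physicians[1]
  per_mh <- vapply(seq_along(w), function(i)
    mh_monthly_cost(cycle_state(sch$entries$n_physicians[i], nb,
                                is_baseline = i == 1), p), numeric(1))
  per_mun <- vapply(seq_along(w), function(i)
    municipal_monthly_cost(cycle_state(sch$entries$n_physicians[i], nb,
                                       is_baseline = i == 1), p), numeric(1))
  tot <- cost_totals(expand_schedule(sch, p))
  expect_equal(unname(tot["mh"]), sum(w * per_mh), tolerance = 1e-12)
  expect_equal(unname(tot["municipal"]), sum(w * per_mun), tolerance = 1e-12)
})

test_that("counterfactual totals hold the baseline for every horizon month", {
  p <- cost_parameters()
  cf <- counterfactual_totals(sp_cycle_schedule(), p)
  expect_equal(unname(cf["mh"]), 39 * 40236064.80)        # 1,569,206,527.20
  expect_equal(unname(cf["municipal"]), 39 * -8612200.00) # -335,875,800.00
  # an empty program leaves only the references on the federal side
  sch0 <- cycle_schedule("none", "2019-01", 0, "2019-01", "2022-03")
  cf0 <- counterfactual_totals(sch0, p)
  expect_equal(unname(cf0["mh"]), 39 * references_total(p))
  expect_equal(unname(cf0["municipal"]), 0)
})

test_that("financial impact and sensitivity reproduce the published block", {
  p <- cost_parameters()
  sch <- sp_cycle_schedule()
  imp <- financial_impact(cost_totals(expand_schedule(sch, p)),
                          counterfactual_totals(sch, p))
  expect_equal(imp$mh_impact, 445071013.20)
  expect_equal(imp$municipal_impact, 929487904.77,
               tolerance = 0.05 / 929487904.77)
  imp <- sensitivity(imp, 0.30)
  expect_equal(unname(imp$sensitivity$municipal),
               c(650641533.34, 1208334276.20))
  expect_equal(unname(imp$sensitivity$mh), c(311549709.24, 578592317.16))
  # conservation: saving + actual spend == counterfactual spend
  expect_equal(imp$mh_impact + imp$mh_total, imp$mh_counterfactual)
})

test_that("sensitivity bounds follow the fixed-fraction arithmetic", {
  zero <- financial_impact(c(mh = 5, municipal = 7), c(mh = 5, municipal = 7))
  expect_equal(zero$mh_impact, 0)
  expect_equal(zero$municipal_impact, 0)
  z <- sensitivity(zero, 0.3)
  expect_equal(unname(z$municipal), NULL)  # no stray field
  expect_equal(unname(z$sensitivity$municipal), c(0, 0))
  forced <- sensitivity(financial_impact(c(mh = 0, municipal = 100),
                                         c(mh = 100, municipal = 0)), 0.30)
  expect_equal(unname(forced$sensitivity$mh), c(70, 130))
  expect_equal(unname(forced$sensitivity$municipal), c(70, 130))
  expect_error(sensitivity(zero, 1.5), "\\[0, 1\\]")
})

test_that("a constant schedule yields zero impact for both payers", {
  p <- cost_parameters()
  sch <- cycle_schedule("flat", "2019-01", 500, "2019-01", "2020-12")
  imp <- financial_impact(cost_totals(expand_schedule(sch, p)),
                          counterfactual_totals(sch, p))
  expect_equal(imp$mh_impact, 0)
  expect_equal(imp$municipal_impact, 0)
})

test_that("removing the last k physicians moves both totals monotonically", {
  p <- cost_parameters()
  totals_for_k <- function(k) {
    sch <- cycle_schedule(c("base", "cut"), c("2019-01", "2019-07"),
                          c(1000, 1000 - k), "2019-01", "2019-12")
    cost_totals(expand_schedule(sch, p))
  }
  res <- t(vapply(seq(0, 1000, by = 125), totals_for_k, numeric(2)))
  expect_true(all(diff(res[, "mh"]) < 0))         # federal spend falls with k
  expect_true(all(diff(res[, "municipal"]) > 0))  # municipal spend rises with k
})

test_that("the discounting hook leaves headline results untouched at rate zero", {
  p <- cost_parameters()
  sch <- sp_cycle_schedule()
  expect_identical(expand_schedule(sch, p, discount_rate_annual = 0),
                   expand_schedule(sch, p))
  disc <- expand_schedule(sch, p, discount_rate_annual = 0.05)
  expect_lt(sum(disc$mh_cost), 1124135514.00)
})
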