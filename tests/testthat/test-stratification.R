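test_that("dependence percentage is physicians over teams", {
  expect_equal(dependence_percent(4, 10), 40)
  expect_equal(dependence_percent(0, 5), 0)
  expect_equal(dependence_percent(7, 7), 100)
  expect_error(dependence_percent(1, 0), "zero FHS teams")
})

test_that("dependence bins are half-open with a closed top", {
  expect_equal(as.character(bin_dependence(40)), "40-60")
  expect_equal(as.character(bin_dependence(0)), "0-20")
  expect_equal(as.character(bin_dependence(100)), "80-100")
  expect_equal(as.character(bin_dependence(c(19.99, 20, 79.99, 80))),
               c("0-20", "20-40", "60-80", "80-100"))
  expect_error(bin_dependence(101), "outside")
  expect_error(bin_dependence(-0.1), "outside")
})

test_that("the fixture cross-tab reproduces the published marginals", {
  tab <- cross_tab(sp_roster())
  expect_equal(unname(tab$col_totals), c(97, 139, 51, 61, 5, 20))
  expect_equal(unname(tab$row_totals), c(127, 115, 89, 12, 30))
  expect_equal(tab$grand_total, 373)
  # exact cell-level match to the requested cross-tab
  expect_equal(unname(tab$counts), unname(sp_cross_tab_cells()),
               ignore_attr = TRUE)
})

test_that("cross-tab conserves counts and matches a brute-force tally", {
  empty <- cross_tab(as_roster(data.frame(
    id = character(0), vulnerability_indicator = integer(0),
    n_fhs_teams = integer(0), n_pmmb_physicians = integer(0),
    contract_end_months = character(0))))
  expect_equal(empty$grand_total, 0)
  expect_true(all(empty$counts == 0))

  r <- random_roster(50, seed = 7)
  tab <- cross_tab(r)
  expect_equal(tab$grand_total, 50)
  expect_equal(unname(tab$counts), unname(brute_force_cross_tab(r)),
               ignore_attr = TRUE)
})

test_that("replacement eligibility is a threshold on the vulnerability class", {
  expect_true(eligible_for_replacement(4))
  expect_false(eligible_for_replacement(3))
  expect_true(eligible_for_replacement(6))
  expect_equal(eligible_for_replacement(1:6), c(F, F, F, T, T, T))
})

test_that("exit projection hits the published endpoints", {
  ep <- exit_projection(sp_roster(), c("2019-01", "2022-03"))
  expect_equal(nrow(ep), 39L)
  expect_equal(ep$n_physicians[1], 2533)
  expect_equal(ep$n_municipalities[1], 373)
  expect_equal(ep$n_physicians[39], 320)
  expect_equal(ep$n_municipalities[39], 86)
  # both series are monotone non-increasing, floored at the eligible stock
  expect_true(all(diff(ep$n_physicians) <= 0))
  expect_true(all(diff(ep$n_municipalities) <= 0))
  expect_true(all(ep$n_physicians >= 320))
  expect_true(all(ep$n_municipalities >= 86))
})

test_that("physicians lost equal the non-eligible roster total", {
  r <- sp_roster()
  ep <- exit_projection(r, c("2019-01", "2022-03"))
  inel <- !eligible_for_replacement(r$vulnerability_indicator)
  expect_equal(ep$n_physicians[1] - ep$n_physicians[nrow(ep)],
               sum(r$n_pmmb_physicians[inel]))
})

test_that("an all-eligible roster yields constant series", {
  r <- random_roster(20, seed = 3)
  r$vulnerability_indicator <- 5L
  r <- as_roster(r)
  ep <- exit_projection(r, c("2019-01", "2020-12"))
  expect_equal(length(unique(ep$n_physicians)), 1L)
  expect_equal(length(unique(ep$n_municipalities)), 1L)
})

test_that("a two-physician municipality steps down at each contract end", {
  r <- as_roster(data.frame(
    id = "solo", vulnerability_indicator = 2L, n_fhs_teams = 3L,
    n_pmmb_physicians = 2L, contract_end_months = "2019-04;2019-08",
    stringsAsFactors = FALSE))
  ep <- exit_projection(r, c("2019-01", "2019-12"))
  # hand-traced event simulation: 2 until Mar, 1 until Jul, then 0
  expect_equal(ep$n_physicians, c(2, 2, 2, 1, 1, 1, 1, rep(0, 5)))
  expect_equal(ep$n_municipalities, c(rep(1, 7), rep(0, 5)))
})

test_that("roster validation rejects inconsistent records", {
  bad <- data.frame(id = "x", vulnerability_indicator = 2L, n_fhs_teams = 1L,
                    n_pmmb_physicians = 3L,
                    contract_end_months = "2019-01;2019-02;2019-03")
  expect_error(as_roster(bad), "exceeds")
  bad2 <- data.frame(id = "y", vulnerability_indicator = 2L, n_fhs_teams = 5L,
                     n_pmmb_physicians = 2L, contract_end_months = "2019-01")
  expect_error(as_roster(bad2), "disagrees")
  bad3 <- data.frame(id = "z", vulnerability_indicator = 9L, n_fhs_teams = 5L,
                     n_pmmb_physicians = 1L, contract_end_months = "2019-01")
  expect_error(as_roster(bad3), "vulnerability_indicator")
})
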