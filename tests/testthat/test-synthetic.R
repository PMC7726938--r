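test_that("roster generation is deterministic given spec and seed", {
  r1 <- generate_roster(sp_roster_spec(seed = 11L))
  r2 <- generate_roster(sp_roster_spec(seed = 11L))
  expect_identical(r1, r2)
  # byte-identical serialization
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_roster(r1, f1); write_roster(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  r3 <- generate_roster(sp_roster_spec(seed = 12L))
  expect_false(identical(r1, r3))
})

test_that("generated rosters satisfy the record invariants and marginals", {
  for (seed in c(1L, 2L, 3L)) {
    spec <- roster_spec(
      n_municipalities = 40L, total_physicians = 160L,
      indicator_marginals = c(`1` = 10L, `2` = 10L, `3` = 8L, `4` = 6L,
                              `5` = 3L, `6` = 3L),
      dependence_marginals = c(`0-20` = 8L, `20-40` = 12L, `40-60` = 10L,
                               `60-80` = 6L, `80-100` = 4L),
      contract_end_profile = c(`2019-06` = 30L, `2020-06` = 40L),
      seed = seed)
    r <- generate_roster(spec)
    expect_s3_class(r, "pmmb_roster")            # as_roster already validated
    expect_true(all(r$n_pmmb_physicians <= r$n_fhs_teams))
    expect_true(all(r$n_pmmb_physicians >= 1))
    expect_equal(sum(r$n_pmmb_physicians), 160L)
    tab <- brute_force_cross_tab(r)
    expect_equal(unname(colSums(tab)), unname(c(10, 10, 8, 6, 3, 3)))
    expect_equal(unname(rowSums(tab)), unname(c(8, 12, 10, 6, 4)))
  }
})

test_that("exact cross-tab cells are reproduced exactly", {
  cells <- matrix(c(3L, 1L, 0L, 2L,
                    1L, 2L, 2L, 1L), nrow = 2, byrow = TRUE,
                  dimnames = list(c("0-20", "20-40"), 1:4))
  # pad to the five standard bins
  full <- rbind(cells, matrix(0L, 3, 4,
                              dimnames = list(c("40-60", "60-80", "80-100"), 1:4)))
  spec <- roster_spec(n_municipalities = 12L, total_physicians = 36L,
                      indicator_marginals = colSums(full),
                      cross_tab_cells = full,
                      contract_end_profile = c(`2019-12` = 20L),
                      seed = 5L)
  r <- generate_roster(spec)
  tab <- cross_tab(r, indicator_levels = 1:4)
  expect_equal(unname(tab$counts), unname(full), ignore_attr = TRUE)
})

test_that("infeasible specs fail constructively, naming the constraint", {
  expect_error(roster_spec(10L, 100L, c(`1` = 4L, `4` = 4L),
                           contract_end_profile = c(`2019-06` = 10L)),
               "indicator_marginals sum")
  expect_error(roster_spec(10L, 5L, c(`1` = 5L, `4` = 5L),
                           contract_end_profile = c(`2019-06` = 3L)),
               "at least one physician")
  expect_error(roster_spec(6L, 20L,
                           c(`1` = 3L, `4` = 3L),
                           dependence_marginals = c(`0-20` = 4L),
                           contract_end_profile = c(`2019-06` = 3L)),
               "dependence_marginals sum")
})

test_that("the packaged fixture bundle carries the published inputs", {
  fx <- sp_fixture()
  expect_equal(nrow(fx$schedule$entries), 10L)
  expect_equal(fx$schedule$horizon, c("2019-01", "2022-03"))
  expect_equal(fx$schedule$entries$n_physicians,
               c(2533L, 2165L, 2107L, 2106L, 2084L, 1909L, 1484L, 1427L,
                 546L, 320L))
  expect_equal(fx$params$pcf_dif, 7130 - 4000)
  expect_equal(cross_tab(fx$roster)$grand_total, 373)
  expect_equal(sum(sp_departure_profile()), 2533 - 320)
})

test_that("fixture departures aggregate to the published cycle counts", {
  r <- sp_roster()
  inel <- !eligible_for_replacement(r$vulnerability_indicator)
  ends <- unlist(strsplit(r$contract_end_months[inel & r$n_pmmb_physicians > 0],
                          ";", fixed = TRUE))
  expect_equal(as.vector(table(ends)[names(sp_departure_profile())]),
               unname(sp_departure_profile()))
})

test_that("attrition thinning is a no-op at rate zero and total at rate one", {
  sch <- sp_cycle_schedule()
  expect_identical(apply_attrition(sch, 0), sch)
  single <- cycle_schedule("cohort", "2019-01", 200L, "2019-01", "2020-12")
  gone <- apply_attrition(single, 1, seed = 2L)
  s <- expand_schedule(gone, cost_parameters())
  expect_equal(s$n_physicians[12], 200L)   # intact through the first year
  expect_equal(s$n_physicians[13], 0L)     # fully removed after one year
  expect_error(apply_attrition(sch, 1.2), "\\[0, 1\\]")
})

test_that("mean attrition departures match the binomial expectation", {
  single <- cycle_schedule("cohort", "2019-01", 500L, "2019-01", "2020-12")
  p <- cost_parameters()
  dep <- vapply(1:1000, function(seed) {
    s <- expand_schedule(apply_attrition(single, 0.208, seed = seed), p)
    s$n_physicians[1] - s$n_physicians[13]
  }, numeric(1))
  # Binomial(500, 0.208): se of the mean over 1000 draws ~ 0.29
  expect_lt(abs(mean(dep) - 0.208 * 500), 3 * sqrt(500 * 0.208 * 0.792 / 1000))
  expect_true(all(dep >= 0 & dep <= 500))
})
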