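#' Packaged São Paulo study fixtures
#'
#' The `sp_*` family packages the published inputs of the São Paulo
#' January/2019–March/2022 withdrawal analysis as ready-made objects:
#' the 2019 payroll schedules, the cost parameters, the ten-entry cycle
#' schedule with its physician counts, the dependence x vulnerability
#' cross-tab cells, and a synthetic roster consistent with all of them.
#'
#' @name sp_fixtures
#' @seealso [sp_fixture()] for the whole bundle at once.
NULL

#' @describeIn sp_fixtures the 2019 celetist payroll rules (identical to the
#'   [payroll_rules()] defaults).
#' @export
sp_payroll_rules <- function() payroll_rules()

#' @describeIn sp_fixtures the study's cost parameters (identical to the
#'   [cost_parameters()] defaults, with the replacement wage derived from the
#'   payroll module at full precision).
#' @export
sp_cost_parameters <- function() cost_parameters(payroll = sp_payroll_rules())

#' @describeIn sp_fixtures the ten-cycle schedule over the 39-month horizon
#'   January/2019 to March/2022, with the published physician counts
#'   2,533; 2,165; 2,107; 2,106; 2,084; 1,909; 1,484; 1,427; 546; 320. The
#'   entry with 1,484 physicians is the 14th cycle, effective June/2020.
#' @export
sp_cycle_schedule <- function() {
  cycle_schedule(
    label = c("MDP ceiling", "9th cycle", "10th cycle", "11th cycle",
              "12th cycle", "13th cycle", "14th cycle", "15th cycle",
              "16th cycle", "17th cycle"),
    effective_month = c("2019-01", "2019-03", "2019-04", "2019-06", "2019-08",
                        "2020-02", "2020-06", "2021-01", "2021-12", "2022-03"),
    n_physicians = c(2533L, 2165L, 2107L, 2106L, 2084L, 1909L, 1484L, 1427L,
                     546L, 320L),
    horizon_start = "2019-01",
    horizon_end   = "2022-03")
}

#' @describeIn sp_fixtures the published dependence-bin x vulnerability-class
#'   municipality counts (row totals 127, 115, 89, 12, 30; column totals 97,
#'   139, 51, 61, 5, 20; grand total 373).
#' @export
sp_cross_tab_cells <- function() {
  m <- matrix(c(
    53, 39, 26,  7, 1, 1,
    27, 50, 17, 11, 4, 6,
    16, 36,  5, 25, 0, 7,
     0,  6,  3,  2, 0, 1,
     1,  8,  0, 16, 0, 5), nrow = 5, byrow = TRUE,
    dimnames = list(c("0-20", "20-40", "40-60", "60-80", "80-100"), 1:6))
  storage.mode(m) <- "integer"
  m
}

#' @describeIn sp_fixtures departures of non-eligible physicians per cycle
#'   month, back-solved from the schedule's consecutive count differences
#'   (sum 2,213 = 2,533 - 320).
#' @export
sp_departure_profile <- function() {
  sch <- sp_cycle_schedule()$entries
  stats::setNames(-diff(sch$n_physicians), sch$effective_month[-1])
}

#' @describeIn sp_fixtures the roster spec matching the published marginals:
#'   373 municipalities, 2,533 physicians, exact cross-tab cells, and the
#'   departure profile above. Any roster satisfying these is admissible; the
#'   packaged one is the deterministic draw for the given seed.
#' @param seed integer seed for the residual (non-quota) allocation choices.
#' @export
sp_roster_spec <- function(seed = 20190131L) {
  roster_spec(
    n_municipalities = 373L,
    total_physicians = 2533L,
    indicator_marginals = colSums(sp_cross_tab_cells()),
    cross_tab_cells = sp_cross_tab_cells(),
    contract_end_profile = sp_departure_profile(),
    eligibility_threshold = 4L,
    retained_end_month = "2022-03",
    seed = seed)
}

#' @describeIn sp_fixtures the synthetic roster generated from
#'   [sp_roster_spec()].
#' @export
sp_roster <- function(seed = 20190131L) generate_roster(sp_roster_spec(seed))

#' Full São Paulo fixture bundle
#'
#' @param seed integer seed passed to [sp_roster()].
#' @return a list with elements `schedule` ([sp_cycle_schedule()]),
#'   `roster` ([sp_roster()]), `params` ([sp_cost_parameters()]) and
#'   `payroll` ([sp_payroll_rules()]).
#' @examples
#' fx <- sp_fixture()
#' month_weights(fx$schedule)
#' @export
sp_fixture <- function(seed = 20190131L) {
  list(schedule = sp_cycle_schedule(),
       roster = sp_roster(seed),
       params = sp_cost_parameters(),
       payroll = sp_payroll_rules())
}
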