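# Toy rule sets and independent oracles shared across the suite.

# zero-tax, zero-contribution rules: net == gross, no employer charges
toy_identity_rules <- function() {
  payroll_rules(
    employee_contribution_rate = 0,
    employee_contribution_cap = 0,
    tax_brackets = data.frame(upper_bound = Inf, marginal_rate = 0,
                              deduction_parcel = 0),
    employer_quota_rate = 0, severance_fund_rate = 0,
    vacation_bonus_factor = 0, include_13th = FALSE,
    annual_composition = "monthly_employer_x12")
}

# single uncapped 8% contribution band, no income tax
toy_flat_contribution_rules <- function() {
  payroll_rules(
    employee_contribution_rate = 0.08,
    employee_contribution_cap = Inf,
    tax_brackets = data.frame(upper_bound = Inf, marginal_rate = 0,
                              deduction_parcel = 0))
}

# a 3-bracket toy table whose deduction parcels telescope from the rates,
# so the parcel formulation must equal the band-by-band marginal sum
toy_bracket_table <- function() {
  ub <- c(1000, 3000, Inf)
  rate <- c(0.05, 0.15, 0.30)
  parcel <- c(0, cumsum((rate[-1] - rate[-3]) * ub[-3]))
  data.frame(upper_bound = ub, marginal_rate = rate, deduction_parcel = parcel)
}

# independent oracle: integrate marginal rates band by band
bandwise_tax_oracle <- function(taxable, brackets) {
  lo <- c(0, brackets$upper_bound[-nrow(brackets)])
  hi <- brackets$upper_bound
  sum(pmax(0, pmin(taxable, hi) - lo) * brackets$marginal_rate)
}

# independent oracle: double-loop cell tally of a roster cross-tab
brute_force_cross_tab <- function(roster, breaks = c(0, 20, 40, 60, 80, 100),
                                  indicators = 1:6) {
  labs <- paste(breaks[-length(breaks)], breaks[-1], sep = "-")
  m <- matrix(0L, nrow = length(labs), ncol = length(indicators),
              dimnames = list(labs, indicators))
  for (i in seq_len(nrow(roster))) {
    p <- 100 * roster$n_pmmb_physicians[i] / roster$n_fhs_teams[i]
    for (b in seq_along(labs)) {
      in_bin <- p >= breaks[b] &&
        (p < breaks[b + 1] || (b == length(labs) && p <= 100))
      if (in_bin) m[b, as.character(roster$vulnerability_indicator[i])] <-
          m[b, as.character(roster$vulnerability_indicator[i])] + 1L
    }
  }
  m
}

# a small random-but-valid roster for property tests
random_roster <- function(n, seed) {
  with_seed <- function(code) { set.seed(seed); code }
  with_seed({
    teams <- sample(1:40, n, replace = TRUE)
    phys <- vapply(teams, function(t) sample.int(t + 1L, 1L) - 1L, integer(1))
    months <- sprintf("20%02d-%02d", sample(19:22, sum(phys), TRUE),
                      sample(1:12, sum(phys), TRUE))
    ends <- character(n)
    k <- 0L
    for (i in seq_len(n)) {
      if (phys[i] > 0) ends[i] <- paste(months[k + seq_len(phys[i])], collapse = ";")
      k <- k + phys[i]
    }
    as_roster(data.frame(
      id = sprintf("R%03d", seq_len(n)),
      vulnerability_indicator = sample(1:6, n, replace = TRUE),
      n_fhs_teams = teams,
      n_pmmb_physicians = phys,
      contract_end_months = ends,
      stringsAsFactors = FALSE))
  })
}
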