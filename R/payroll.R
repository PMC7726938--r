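#' Payroll rules for a celetist (CLT) hire
#'
#' Bundles the schedules that turn a gross monthly wage into the employee's
#' net pay and the employer's monthly and annual cost under Brazil's
#' Consolidation of Labor Laws: the employee social-security (INSS)
#' contribution, the progressive income-tax (IRPF) bracket table in its
#' deduction-parcel form, the employer INSS quota, the severance-fund (FGTS)
#' deposit, the statutory one-third vacation bonus and the 13th salary.
#'
#' The defaults are the 2019 schedules: employee INSS at a flat 11% capped at
#' the ceiling contribution of R$ 642.34/month, and the 2019 monthly IRPF
#' table (exemption to 1,903.98; then 7.5%, 15%, 22.5% and 27.5% with
#' deduction parcels 142.80, 354.80, 636.13 and 869.36). Every element can be
#' overridden, e.g. to model a different table vintage or a toy schedule.
#'
#' @param employee_contribution_rate fraction of gross withheld as the
#'   employee INSS contribution before the cap applies.
#' @param employee_contribution_cap flat maximum employee contribution in
#'   BRL/month; use `Inf` for an uncapped schedule.
#' @param tax_brackets data frame with columns `upper_bound` (BRL, strictly
#'   increasing, last must be `Inf`), `marginal_rate` (fraction) and
#'   `deduction_parcel` (BRL, non-negative). Tax on a taxable amount `t`
#'   falling in bracket `i` is `t * marginal_rate[i] - deduction_parcel[i]`,
#'   floored at zero.
#' @param employer_quota_rate employer INSS quota as a fraction of gross.
#' @param severance_fund_rate FGTS deposit as a fraction of gross.
#' @param vacation_bonus_factor statutory vacation bonus fraction (1/3).
#' @param months_per_year number of wage months per year (12).
#' @param include_13th whether a 13th salary is due.
#' @param annual_composition character vector of component labels summed into
#'   the annual employer total; see [net_from_gross()] for the available
#'   labels. The default keeps the recurring-year components (12 monthly
#'   employer totals, vacation pay with its bonus, the employer quota on that
#'   vacation pay, the 13th salary and the FGTS on the 13th) and leaves the
#'   contract-termination notice items out.
#' @return an object of class `payroll_rules`.
#' @seealso [net_from_gross()], [gross_from_net()]
#' @examples
#' rules <- payroll_rules()
#' employee_contribution(15809.57, rules)
#' @export
payroll_rules <- function(employee_contribution_rate = 0.11,
                          employee_contribution_cap = 642.34,
                          tax_brackets = data.frame(
                            upper_bound      = c(1903.98, 2826.65, 3751.05, 4664.68, Inf),
                            marginal_rate    = c(0, 0.075, 0.15, 0.225, 0.275),
                            deduction_parcel = c(0, 142.80, 354.80, 636.13, 869.36)),
                          employer_quota_rate = 0.20,
                          severance_fund_rate = 0.08,
                          vacation_bonus_factor = 1 / 3,
                          months_per_year = 12L,
                          include_13th = TRUE,
                          annual_composition = c("monthly_employer_x12",
                                                 "vacation_bonus",
                                                 "employer_quota_vacation_bonus",
                                                 "thirteenth_salary",
                                                 "severance_fund_13th")) {
  rates <- c(employee_contribution_rate, employer_quota_rate,
             severance_fund_rate, tax_brackets$marginal_rate)
  if (any(!is.finite(rates)) || any(rates < 0 | rates > 1))
    stop("all rates must lie in [0, 1]", call. = FALSE)
  stopifnot(is.data.frame(tax_brackets),
            all(c("upper_bound", "marginal_rate", "deduction_parcel") %in%
                  names(tax_brackets)),
            nrow(tax_brackets) >= 1)
  ub <- tax_brackets$upper_bound
  if (any(diff(ub) <= 0))
    stop("tax bracket upper bounds must be strictly increasing", call. = FALSE)
  if (!is.infinite(ub[length(ub)]) || any(is.infinite(ub[-length(ub)])))
    stop("exactly the last tax bracket must be unbounded (upper_bound = Inf)",
         call. = FALSE)
  if (any(tax_brackets$deduction_parcel < 0))
    stop("deduction parcels must be non-negative", call. = FALSE)
  if (employee_contribution_cap < 0)
    stop("employee contribution cap must be non-negative", call. = FALSE)
  if (vacation_bonus_factor < 0)
    stop("vacation bonus factor must be non-negative", call. = FALSE)
  structure(list(
    employee_contribution_rate = employee_contribution_rate,
    employee_contribution_cap  = employee_contribution_cap,
    tax_brackets               = tax_brackets,
    employer_quota_rate        = employer_quota_rate,
    severance_fund_rate        = severance_fund_rate,
    vacation_bonus_factor      = vacation_bonus_factor,
    months_per_year            = as.integer(months_per_year),
    include_13th               = isTRUE(include_13th),
    annual_composition         = annual_composition
  ), class = "payroll_rules")
}

#' @export
print.payroll_rules <- function(x, ...) {
  cat("Celetist payroll rules\n")
  cat(sprintf("  employee INSS: %.1f%% of gross, capped at R$ %s/month\n",
              100 * x$employee_contribution_rate,
              format_brl(x$employee_contribution_cap)))
  cat(sprintf("  employer charges: INSS quota %.1f%% + FGTS %.1f%% of gross\n",
              100 * x$employer_quota_rate, 100 * x$severance_fund_rate))
  cat(sprintf("  income-tax brackets (%d), top rate %.1f%%\n",
              nrow(x$tax_brackets), 100 * max(x$tax_brackets$marginal_rate)))
  cat("  annual composition:", paste(x$annual_composition, collapse = ", "), "\n")
  invisible(x)
}

#' Employee social-security contribution
#'
#' The employee INSS deduction on a gross monthly wage: a flat rate of gross,
#' limited by the ceiling contribution. Under the default 2019 rules any gross
#' at or above the contribution ceiling pays the flat cap of R$ 642.34.
#'
#' @param gross gross monthly wage(s) in BRL, non-negative.
#' @param rules a [payroll_rules()] object.
#' @return contribution in BRL (unrounded; round with [round_brl()] for
#'   display).
#' @examples
#' employee_contribution(15809.57, payroll_rules())  # at the ceiling: 642.34
#' @export
employee_contribution <- function(gross, rules = payroll_rules()) {
  stopifnot(inherits(rules, "payroll_rules"), is.numeric(gross))
  if (any(gross < 0)) stop("gross wage must be non-negative", call. = FALSE)
  pmin(rules$employee_contribution_rate * gross, rules$employee_contribution_cap)
}

#' Withheld income tax on a taxable amount
#'
#' Progressive income tax in the deduction-parcel form used by Brazil's
#' monthly withholding tables: locate the bracket containing the taxable
#' amount, apply that bracket's marginal rate to the whole amount and subtract
#' the bracket's deduction parcel, flooring at zero. When the parcels telescope
#' (as in the official tables) this equals the band-by-band marginal sum, and
#' the tax function is continuous at bracket boundaries.
#'
#' @param taxable taxable monthly amount(s) in BRL (gross minus the employee
#'   contribution), non-negative.
#' @param rules a [payroll_rules()] object.
#' @return tax in BRL (unrounded).
#' @examples
#' income_tax(15167.23, payroll_rules())  # top bracket: ~3,301.63
#' @export
income_tax <- function(taxable, rules = payroll_rules()) {
  stopifnot(inherits(rules, "payroll_rules"), is.numeric(taxable))
  if (any(taxable < 0)) stop("taxable amount must be non-negative", call. = FALSE)
  br <- rules$tax_brackets
  # bracket i holds taxable in (upper_bound[i-1], upper_bound[i]]
  idx <- findInterval(taxable, br$upper_bound, left.open = TRUE) + 1L
  pmax(0, taxable * br$marginal_rate[idx] - br$deduction_parcel[idx])
}

#' Full payroll breakdown from a gross wage
#'
#' Computes the employee-side deductions (INSS contribution, income tax, net
#' pay) and every employer-side cost component of a celetist hire: the monthly
#' employer total `gross * (1 + quota + FGTS)`, vacation pay with its
#' one-third bonus, the 13th salary, the contract-termination notice, and the
#' employer charges each of those attracts. The annual employer total sums the
#' components named in `rules$annual_composition`.
#'
#' All values are returned at full precision; the `print` method renders them
#' rounded to cents.
#'
#' @param gross gross monthly wage in BRL (scalar), non-negative.
#' @param rules a [payroll_rules()] object.
#' @return an object of class `payroll_breakdown`: a list with `gross`,
#'   `employee_contribution`, `income_tax`, `net`, `monthly_employer_total`,
#'   `annual_employer_total` and `component_map` (named vector with labels
#'   `monthly_employer_x12`, `vacation_bonus`,
#'   `employer_quota_vacation_bonus`, `thirteenth_salary`,
#'   `severance_fund_13th`, `employer_quota_13th`, `notice`,
#'   `employer_quota_notice`, `severance_fund_notice`).
#' @examples
#' b <- net_from_gross(15809.57)
#' round_brl(b$net)                    # 11,865.60
#' round_brl(b$monthly_employer_total) # 20,236.25
#' @export
net_from_gross <- function(gross, rules = payroll_rules()) {
  stopifnot(inherits(rules, "payroll_rules"),
            is.numeric(gross), length(gross) == 1)
  if (gross < 0) stop("gross wage must be non-negative", call. = FALSE)
  ec  <- employee_contribution(gross, rules)
  it  <- income_tax(gross - ec, rules)
  net <- gross - ec - it
  monthly <- gross * (1 + rules$employer_quota_rate + rules$severance_fund_rate)
  vac      <- gross * (1 + rules$vacation_bonus_factor)
  thirteen <- if (rules$include_13th) gross else 0
  comp <- c(
    monthly_employer_x12          = rules$months_per_year * monthly,
    vacation_bonus                = vac,
    employer_quota_vacation_bonus = rules$employer_quota_rate * vac,
    thirteenth_salary             = thirteen,
    severance_fund_13th           = rules$severance_fund_rate * thirteen,
    employer_quota_13th           = rules$employer_quota_rate * thirteen,
    notice                        = gross,
    employer_quota_notice         = rules$employer_quota_rate * gross,
    severance_fund_notice         = rules$severance_fund_rate * gross
  )
  missing <- setdiff(rules$annual_composition, names(comp))
  if (length(missing))
    stop("unknown annual_composition label(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(
    gross                 = gross,
    employee_contribution = ec,
    income_tax            = it,
    net                   = net,
    monthly_employer_total = monthly,
    annual_employer_total  = sum(comp[rules$annual_composition]),
    component_map          = comp
  ), class = "payroll_breakdown")
}

#' @export
print.payroll_breakdown <- function(x, locale = "iso", ...) {
  row <- function(lab, v) cat(sprintf("  %-32s R$ %s\n", lab, format_brl(v, locale)))
  cat("Celetist payroll breakdown\n")
  row("Gross", x$gross)
  row("Employee INSS contribution", x$employee_contribution)
  row("Income tax", x$income_tax)
  row("Net", x$net)
  row("Monthly employer total", x$monthly_employer_total)
  row("Annual employer total", x$annual_employer_total)
  cat("  components:\n")
  for (nm in names(x$component_map)) row(paste0("  ", nm), x$component_map[[nm]])
  invisible(x)
}

#' @export
as.data.frame.payroll_breakdown <- function(x, ...) {
  data.frame(component = c("gross", "employee_contribution", "income_tax", "net",
                           "monthly_employer_total", "annual_employer_total",
                           names(x$component_map)),
             amount_brl = round_brl(c(x$gross, x$employee_contribution,
                                      x$income_tax, x$net,
                                      x$monthly_employer_total,
                                      x$annual_employer_total,
                                      unname(x$component_map))))
}

#' Gross wage that yields a target net pay
#'
#' Inverts [net_from_gross()]: finds the gross monthly wage whose net pay
#' equals `net_target` to within a cent. The net function is piecewise linear
#' in gross (one piece per tax bracket, crossed with the capped/uncapped
#' contribution regimes), so the solver enumerates the analytic per-piece
#' inversions and keeps the consistent one; if no piece closes (e.g. under
#' pathological custom rules) it falls back to bisection on the monotone net
#' function, and fails loudly if that does not converge either.
#'
#' This is the anchor of the replacement-hire costing: a municipality hiring
#' a physician at a net wage equal to the program scholarship pays the
#' grossed-up wage plus employer charges.
#'
#' @param net_target desired net monthly pay in BRL, non-negative.
#' @param rules a [payroll_rules()] object.
#' @param tol acceptable absolute error on the achieved net, in BRL.
#' @return gross wage in BRL, rounded to cents.
#' @examples
#' gross_from_net(11865.60)  # 15,809.57
#' @export
gross_from_net <- function(net_target, rules = payroll_rules(), tol = 0.01) {
  stopifnot(inherits(rules, "payroll_rules"),
            is.numeric(net_target), length(net_target) == 1)
  if (net_target < 0) stop("net target must be non-negative", call. = FALSE)
  if (net_target == 0) return(0)
  br  <- rules$tax_brackets
  re  <- rules$employee_contribution_rate
  cap <- rules$employee_contribution_cap
  net_of <- function(g) {
    ec <- pmin(re * g, cap)
    g - ec - income_tax(g - ec, rules)
  }
  cands <- numeric(0)
  for (i in seq_len(nrow(br))) {
    rt <- br$marginal_rate[i]; pc <- br$deduction_parcel[i]
    if (rt < 1) {
      # uncapped contribution regime: net = (1-re)(1-rt) g + pc
      if (re < 1) cands <- c(cands, (net_target - pc) / ((1 - re) * (1 - rt)))
      # capped regime: net = (1-rt)(g - cap) + pc  (cap finite)
      if (is.finite(cap))
        cands <- c(cands, (net_target - pc) / (1 - rt) + cap)
    }
  }
  # zero-tax pieces (tax floored at 0): net = g - min(re g, cap)
  if (re < 1) cands <- c(cands, net_target / (1 - re))
  if (is.finite(cap)) cands <- c(cands, net_target + cap)
  cands <- cands[is.finite(cands) & cands >= 0]
  if (length(cands)) {
    res <- abs(vapply(cands, net_of, numeric(1)) - net_target)
    best <- cands[which.min(res)]
    if (min(res) <= tol / 2) return(round_brl(best))
  }
  # bisection fallback on the monotone net function
  hi <- max(net_target, 1)
  for (k in 1:60) {
    if (net_of(hi) >= net_target) break
    hi <- hi * 2
  }
  if (net_of(hi) < net_target)
    stop("gross_from_net failed to bracket the target net ",
         "(net pay appears bounded below the target under these rules)",
         call. = FALSE)
  root <- stats::uniroot(function(g) net_of(g) - net_target,
                         lower = 0, upper = hi, tol = 1e-9)
  g <- round_brl(root$root)
  if (abs(net_of(g) - net_target) > max(tol, 1e-6) &&
      abs(net_of(root$root) - net_target) > max(tol, 1e-6))
    stop("gross_from_net did not converge to within ", tol, " BRL",
         call. = FALSE)
  g
}
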