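#' Cost parameters of the budget-impact model
#'
#' The monetary constants the whole analysis flows from, one per cost item of
#' the federal (Ministry of Health, MH) and municipal budgets:
#'
#' * `scholarship` — monthly federal scholarship paid to a program physician
#'   (R$ 11,865.60), also the net-wage anchor for a municipal replacement hire;
#' * `pcf_full` / `pcf_pmmb` — monthly variable Primary Care Floor transfer
#'   per family-health team without (R$ 7,130.00) and with (R$ 4,000.00) a
#'   program physician; their difference `pcf_dif` (R$ 3,130.00) is derived,
#'   never set directly;
#' * `ref_central`, `ref_decentralized`, `n_decentralized` — monthly cost of
#'   the supervision references (one central at R$ 6,500.00 plus seven
#'   decentralized at R$ 6,000.00 for the state);
#' * `rent`, `food` — municipal housing (R$ 2,000.00) and food
#'   (R$ 600.00) aid per physician per month;
#' * `physician_wage_monthly` — monthly employer cost of hiring a replacement
#'   physician under CLT at a net wage equal to the scholarship. By default it
#'   is derived live from the payroll module at full precision
#'   (`gross_from_net(scholarship) * (1 + quota + FGTS)` = 20,236.2496); the
#'   commonly quoted 20,236.25 is this value rounded to cents and may be set
#'   explicitly;
#' * `sensitivity_fraction` — the fixed one-way sensitivity band (0.30).
#'
#' @param scholarship,pcf_full,pcf_pmmb,ref_central,ref_decentralized,rent,food
#'   monetary parameters in BRL/month, non-negative.
#' @param n_decentralized number of decentralized references.
#' @param physician_wage_monthly monthly employer cost of a replacement hire
#'   in BRL, or `NULL` (default) to derive it from `payroll`.
#' @param sensitivity_fraction fraction in `[0, 1]`.
#' @param payroll a [payroll_rules()] object used when
#'   `physician_wage_monthly` is derived.
#' @return an object of class `cost_parameters` (with derived field `pcf_dif`).
#' @examples
#' p <- cost_parameters()
#' p$pcf_dif                     # 3130
#' round_brl(p$physician_wage_monthly)
#' @export
cost_parameters <- function(scholarship = 11865.60,
                            pcf_full = 7130,
                            pcf_pmmb = 4000,
                            ref_central = 6500,
                            ref_decentralized = 6000,
                            n_decentralized = 7L,
                            rent = 2000,
                            food = 600,
                            physician_wage_monthly = NULL,
                            sensitivity_fraction = 0.30,
                            payroll = payroll_rules()) {
  if (is.null(physician_wage_monthly)) {
    gross <- gross_from_net(scholarship, payroll)
    physician_wage_monthly <- net_from_gross(gross, payroll)$monthly_employer_total
  }
  vals <- c(scholarship, pcf_full, pcf_pmmb, ref_central, ref_decentralized,
            rent, food, physician_wage_monthly)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all monetary cost parameters must be finite and non-negative",
         call. = FALSE)
  if (pcf_pmmb > pcf_full)
    stop("pcf_pmmb must not exceed pcf_full (pcf_dif would be negative)",
         call. = FALSE)
  if (n_decentralized < 0) stop("n_decentralized must be non-negative", call. = FALSE)
  if (sensitivity_fraction < 0 || sensitivity_fraction > 1)
    stop("sensitivity_fraction must lie in [0, 1]", call. = FALSE)
  structure(list(
    scholarship            = scholarship,
    pcf_full               = pcf_full,
    pcf_pmmb               = pcf_pmmb,
    pcf_dif                = pcf_full - pcf_pmmb,
    ref_central            = ref_central,
    ref_decentralized      = ref_decentralized,
    n_decentralized        = as.integer(n_decentralized),
    rent                   = rent,
    food                   = food,
    physician_wage_monthly = physician_wage_monthly,
    sensitivity_fraction   = sensitivity_fraction
  ), class = "cost_parameters")
}

#' @export
print.cost_parameters <- function(x, ...) {
  cat("Budget-impact cost parameters (BRL/month)\n")
  cat(sprintf("  scholarship            %12s per physician\n", format_brl(x$scholarship)))
  cat(sprintf("  PCF full / with PMMB   %12s / %s per team (dif %s)\n",
              format_brl(x$pcf_full), format_brl(x$pcf_pmmb), format_brl(x$pcf_dif)))
  cat(sprintf("  references             %12s (1 central %s + %d decentralized %s)\n",
              format_brl(references_total(x)), format_brl(x$ref_central),
              x$n_decentralized, format_brl(x$ref_decentralized)))
  cat(sprintf("  rent + food            %12s + %s per physician\n",
              format_brl(x$rent), format_brl(x$food)))
  cat(sprintf("  replacement wage cost  %12s per physician\n",
              format_brl(x$physician_wage_monthly)))
  cat(sprintf("  sensitivity band       +/- %.0f%%\n", 100 * x$sensitivity_fraction))
  invisible(x)
}

#' State of the program in one projection cycle
#'
#' @param n_current physicians still in the program in this cycle.
#' @param n_baseline physicians at the January/2019 program ceiling.
#' @param is_baseline whether this state is the pre-departure baseline, which
#'   uses the baseline cost formulas (defaults to `n_current == n_baseline`).
#' @return an object of class `cycle_state`.
#' @examples
#' cycle_state(2165, 2533)
#' @export
cycle_state <- function(n_current, n_baseline, is_baseline = n_current == n_baseline) {
  stopifnot(length(n_current) == 1, length(n_baseline) == 1)
  if (n_current < 0 || n_current > n_baseline)
    stop("require 0 <= n_current <= n_baseline, got n_current = ", n_current,
         ", n_baseline = ", n_baseline, call. = FALSE)
  structure(list(n_current = as.integer(n_current),
                 n_baseline = as.integer(n_baseline),
                 is_baseline = isTRUE(is_baseline)),
            class = "cycle_state")
}

#' Total monthly cost of the supervision references
#'
#' @param params a [cost_parameters()] object.
#' @return `ref_central + n_decentralized * ref_decentralized`, in BRL/month.
#' @examples
#' references_total(cost_parameters())  # 48,500
#' @export
references_total <- function(params) {
  stopifnot(inherits(params, "cost_parameters"))
  params$ref_central + params$n_decentralized * params$ref_decentralized
}

#' Ministry of Health monthly cost for a cycle state
#'
#' Federal spend while `n_current` physicians remain out of a baseline of
#' `n_baseline`: the references, plus scholarship and reduced-PCF transfer for
#' each remaining physician, plus the restored PCF difference for each team
#' whose physician has left:
#'
#' `Ref + n_current * (scholarship + pcf_pmmb) + (n_baseline - n_current) * pcf_dif`
#'
#' The baseline (no departures) case is the same expression with
#' `n_current = n_baseline`.
#'
#' @param state a [cycle_state()].
#' @param params a [cost_parameters()].
#' @return cost in BRL/month.
#' @examples
#' mh_monthly_cost(cycle_state(2533, 2533), cost_parameters())  # 40,236,064.80
#' @export
mh_monthly_cost <- function(state, params) {
  stopifnot(inherits(state, "cycle_state"), inherits(params, "cost_parameters"))
  delta <- state$n_baseline - state$n_current
  references_total(params) +
    state$n_current * (params$scholarship + params$pcf_pmmb) +
    delta * params$pcf_dif
}

#' Municipality monthly cost for a cycle state
#'
#' Municipal net outlay (positive = money spent). For non-baseline states,
#' with `delta = n_baseline - n_current` departures to replace:
#'
#' `n_current * (food + rent) + delta * physician_wage_monthly - delta * (pcf_pmmb + pcf_dif)`
#'
#' i.e. counterpart aid for the physicians still present, plus the full
#' employer cost of each replacement hire, minus the restored full PCF
#' transfer for each replaced team.
#'
#' For the baseline state two accounting conventions are offered. Under
#' `"as_printed_table"` (default) the baseline books the food aid as the cash
#' outlay and the reduced-PCF transfer as a receipt, `n * (food - pcf_pmmb)` —
#' a net receipt (negative), the reading consistent with the study's results
#' table. Under `"as_printed_box"` the baseline is taken literally from the
#' stated formula, `n * (food + rent + pcf_pmmb)`.
#'
#' @param state a [cycle_state()].
#' @param params a [cost_parameters()].
#' @param convention baseline accounting convention, `"as_printed_table"` or
#'   `"as_printed_box"`.
#' @return cost in BRL/month (negative = net receipt).
#' @examples
#' municipal_monthly_cost(cycle_state(2533, 2533), cost_parameters())  # -8,612,200
#' municipal_monthly_cost(cycle_state(2165, 2533), cost_parameters())
#' @export
municipal_monthly_cost <- function(state, params,
                                   convention = c("as_printed_table",
                                                  "as_printed_box")) {
  stopifnot(inherits(state, "cycle_state"), inherits(params, "cost_parameters"))
  convention <- match.arg(convention)
  if (state$is_baseline) {
    n <- state$n_current
    return(switch(convention,
                  as_printed_table = n * (params$food - params$pcf_pmmb),
                  as_printed_box   = n * (params$food + params$rent + params$pcf_pmmb)))
  }
  delta <- state$n_baseline - state$n_current
  state$n_current * (params$food + params$rent) +
    delta * params$physician_wage_monthly -
    delta * (params$pcf_pmmb + params$pcf_dif)
}
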