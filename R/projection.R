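#' Cycle schedule: the step-function backbone of the projection
#'
#' An ordered set of (cycle label, effective calendar month, physician count)
#' entries over an inclusive year-month horizon. Each entry's count holds
#' from its effective month until the month before the next entry's month;
#' the first entry must sit at the horizon start and is treated as the
#' pre-departure baseline. Counts must be non-increasing: this is the
#' no-replacement scenario, physicians leave and are not re-enrolled.
#'
#' @param label character vector of cycle labels.
#' @param effective_month `"YYYY-MM"` strings, strictly increasing, all
#'   within the horizon.
#' @param n_physicians non-negative, non-increasing integer counts.
#' @param horizon_start,horizon_end `"YYYY-MM"` horizon bounds, inclusive.
#' @return an object of class `cycle_schedule` with elements `entries` (a
#'   data frame) and `horizon` (length-2 character).
#' @seealso [expand_schedule()], [sp_cycle_schedule()]
#' @examples
#' cycle_schedule("start", "2020-01", 10, "2020-01", "2020-03")
#' @export
cycle_schedule <- function(label, effective_month, n_physicians,
                           horizon_start, horizon_end) {
  stopifnot(length(label) == length(effective_month),
            length(label) == length(n_physicians),
            length(label) >= 1)
  h0 <- ym_index(horizon_start); h1 <- ym_index(horizon_end)
  if (h1 < h0) stop("horizon_end precedes horizon_start", call. = FALSE)
  mi <- ym_index(effective_month)
  if (any(diff(mi) <= 0))
    stop("effective months must be strictly increasing", call. = FALSE)
  if (mi[1] != h0)
    stop("the first schedule entry must sit at the horizon start (",
         horizon_start, "), got ", effective_month[1], call. = FALSE)
  if (any(mi < h0 | mi > h1))
    stop("schedule entries outside the horizon", call. = FALSE)
  if (any(n_physicians < 0))
    stop("physician counts must be non-negative", call. = FALSE)
  if (any(diff(n_physicians) > 0))
    stop("physician counts must be non-increasing (no-replacement scenario)",
         call. = FALSE)
  structure(list(
    entries = data.frame(label = as.character(label),
                         effective_month = effective_month,
                         n_physicians = as.integer(n_physicians),
                         stringsAsFactors = FALSE),
    horizon = c(horizon_start, horizon_end)
  ), class = "cycle_schedule")
}

#' @export
print.cycle_schedule <- function(x, ...) {
  cat(sprintf("Cycle schedule: %d entries over %s .. %s (%d months)\n",
              nrow(x$entries), x$horizon[1], x$horizon[2], n_horizon_months(x)))
  print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Number of months in a schedule's horizon
#' @param schedule a [cycle_schedule()].
#' @return integer month count (inclusive of both endpoints).
#' @export
n_horizon_months <- function(schedule) {
  stopifnot(inherits(schedule, "cycle_schedule"))
  ym_index(schedule$horizon[2]) - ym_index(schedule$horizon[1]) + 1L
}

#' Months each cycle is active
#'
#' Each entry is active from its effective month to the month before the next
#' entry's effective month (the last entry runs to the horizon end). The
#' weights always sum to the horizon length.
#'
#' @param schedule a [cycle_schedule()].
#' @return integer vector of month counts, one per schedule entry.
#' @examples
#' month_weights(sp_cycle_schedule())  # 2 1 2 2 6 4 7 11 3 1
#' @export
month_weights <- function(schedule) {
  stopifnot(inherits(schedule, "cycle_schedule"))
  mi <- ym_index(schedule$entries$effective_month)
  diff(c(mi, ym_index(schedule$horizon[2]) + 1L))
}

#' Expand a cycle schedule into a monthly cost series
#'
#' Materializes the step function: every calendar month of the horizon
#' carries the physician count of the latest schedule entry at or before it,
#' and the federal and municipal monthly costs for that count. The first
#' (baseline) entry is evaluated with the baseline formulas; all later
#' entries with the general formulas. No discounting is applied: a
#' `discount_rate_annual` hook exists for exploration but defaults to zero.
#'
#' @param schedule a [cycle_schedule()].
#' @param params a [cost_parameters()].
#' @param convention baseline municipal accounting convention, see
#'   [municipal_monthly_cost()].
#' @param discount_rate_annual annual discount rate applied monthly from the
#'   horizon start; the headline analysis uses 0.
#' @return a data frame of class `monthly_cost_series` with columns `month`,
#'   `cycle`, `n_physicians`, `mh_cost`, `municipal_cost`, one row per
#'   horizon month.
#' @examples
#' s <- expand_schedule(sp_cycle_schedule(), cost_parameters())
#' nrow(s)  # 39
#' @export
expand_schedule <- function(schedule, params,
                            convention = c("as_printed_table", "as_printed_box"),
                            discount_rate_annual = 0) {
  stopifnot(inherits(schedule, "cycle_schedule"),
            inherits(params, "cost_parameters"))
  convention <- match.arg(convention)
  months <- ym_seq(schedule$horizon[1], schedule$horizon[2])
  midx <- ym_index(months)
  eidx <- ym_index(schedule$entries$effective_month)
  which_entry <- findInterval(midx, eidx)   # >= 1 since first entry at start
  nb <- schedule$entries$n_physicians[1]
  per_entry <- lapply(seq_len(nrow(schedule$entries)), function(i) {
    st <- cycle_state(schedule$entries$n_physicians[i], nb, is_baseline = i == 1L)
    c(mh = mh_monthly_cost(st, params),
      mun = municipal_monthly_cost(st, params, convention))
  })
  mh  <- vapply(per_entry, `[[`, numeric(1), "mh")[which_entry]
  mun <- vapply(per_entry, `[[`, numeric(1), "mun")[which_entry]
  if (discount_rate_annual != 0) {
    disc <- (1 + discount_rate_annual)^(-(midx - midx[1]) / 12)
    mh <- mh * disc; mun <- mun * disc
  }
  out <- data.frame(month = months,
                    cycle = schedule$entries$label[which_entry],
                    n_physicians = schedule$entries$n_physicians[which_entry],
                    mh_cost = mh,
                    municipal_cost = mun,
                    stringsAsFactors = FALSE)
  class(out) <- c("monthly_cost_series", "data.frame")
  out
}

#' Accumulated payer totals of a monthly cost series
#'
#' @param series a `monthly_cost_series` from [expand_schedule()].
#' @return named numeric vector `c(mh = ..., municipal = ...)` in BRL.
#' @examples
#' cost_totals(expand_schedule(sp_cycle_schedule(), cost_parameters()))
#' @export
cost_totals <- function(series) {
  stopifnot(inherits(series, "monthly_cost_series"), nrow(series) >= 1)
  c(mh = sum(series$mh_cost), municipal = sum(series$municipal_cost))
}

#' Counterfactual payer totals: the program ceiling held over the horizon
#'
#' The comparator world in which the baseline physician count persists for
#' every month of the horizon: baseline monthly costs times the number of
#' horizon months. For the municipal payer this is a stream of net receipts
#' (negative) under the default convention.
#'
#' @param schedule a [cycle_schedule()] (only its baseline entry and horizon
#'   are used).
#' @param params a [cost_parameters()].
#' @param convention see [municipal_monthly_cost()].
#' @return named numeric vector `c(mh = ..., municipal = ...)` in BRL.
#' @examples
#' counterfactual_totals(sp_cycle_schedule(), cost_parameters())
#' @export
counterfactual_totals <- function(schedule, params,
                                  convention = c("as_printed_table",
                                                 "as_printed_box")) {
  stopifnot(inherits(schedule, "cycle_schedule"),
            inherits(params, "cost_parameters"))
  convention <- match.arg(convention)
  nb <- schedule$entries$n_physicians[1]
  st <- cycle_state(nb, nb, is_baseline = TRUE)
  nm <- n_horizon_months(schedule)
  c(mh = nm * mh_monthly_cost(st, params),
    municipal = nm * municipal_monthly_cost(st, params, convention))
}

#' Financial impact of the withdrawal scenario against its counterfactual
#'
#' Per payer, the impact is the difference between the scenario totals and
#' the counterfactual totals, stored as a magnitude plus a direction:
#' the federal payer *saves* (`mh_impact = mh_counterfactual - mh_actual`),
#' the municipalities carry an *extra burden*
#' (`municipal_impact = municipal_actual - municipal_counterfactual`). The
#' reporting layer renders the conventional signs (municipal impact negative,
#' federal impact positive).
#'
#' @param actual named vector `c(mh=, municipal=)` from [cost_totals()].
#' @param counterfactual named vector from [counterfactual_totals()].
#' @return an object of class `impact_summary` with the four totals, the two
#'   impact magnitudes and their direction labels; sensitivity bounds are
#'   `NULL` until [sensitivity()] is applied.
#' @examples
#' sch <- sp_cycle_schedule(); p <- cost_parameters()
#' financial_impact(cost_totals(expand_schedule(sch, p)),
#'                  counterfactual_totals(sch, p))
#' @export
financial_impact <- function(actual, counterfactual) {
  stopifnot(all(c("mh", "municipal") %in% names(actual)),
            all(c("mh", "municipal") %in% names(counterfactual)))
  structure(list(
    mh_total                 = unname(actual["mh"]),
    municipal_total          = unname(actual["municipal"]),
    mh_counterfactual        = unname(counterfactual["mh"]),
    municipal_counterfactual = unname(counterfactual["municipal"]),
    mh_impact        = unname(counterfactual["mh"] - actual["mh"]),
    municipal_impact = unname(actual["municipal"] - counterfactual["municipal"]),
    direction = c(mh = "saving", municipal = "burden"),
    sensitivity = NULL
  ), class = "impact_summary")
}

#' Fixed-percentage one-way sensitivity bounds
#'
#' Applies the study's fixed sensitivity band to both payer impacts:
#' optimistic bound `impact * (1 - f)`, pessimistic bound `impact * (1 + f)`,
#' each rounded to the cent.
#'
#' @param summary an `impact_summary` from [financial_impact()].
#' @param f fraction in `[0, 1]` (the study uses 0.30).
#' @return the `impact_summary` with a `sensitivity` element: a list with
#'   `fraction` and per-payer `c(optimistic=, pessimistic=)` bounds.
#' @examples
#' sch <- sp_cycle_schedule(); p <- cost_parameters()
#' imp <- financial_impact(cost_totals(expand_schedule(sch, p)),
#'                         counterfactual_totals(sch, p))
#' sensitivity(imp, 0.30)$sensitivity
#' @export
sensitivity <- function(summary, f) {
  stopifnot(inherits(summary, "impact_summary"), is.numeric(f), length(f) == 1)
  if (f < 0 || f > 1) stop("sensitivity fraction must lie in [0, 1]", call. = FALSE)
  bounds <- function(x) c(optimistic  = round_brl(x * (1 - f)),
                          pessimistic = round_brl(x * (1 + f)))
  summary$sensitivity <- list(fraction = f,
                              mh = bounds(summary$mh_impact),
                              municipal = bounds(summary$municipal_impact))
  summary
}

#' @export
print.impact_summary <- function(x, locale = "iso", ...) {
  fm <- function(v) format_brl(v, locale)
  cat("Budget-impact summary (BRL)\n")
  cat(sprintf("  MH total         %20s   counterfactual %20s\n",
              fm(x$mh_total), fm(x$mh_counterfactual)))
  cat(sprintf("  municipal total  %20s   counterfactual %20s\n",
              fm(x$municipal_total), fm(x$municipal_counterfactual)))
  cat(sprintf("  MH impact        %20s  (federal saving)\n", fm(x$mh_impact)))
  cat(sprintf("  municipal impact %20s  (extra municipal burden, reported as -%s)\n",
              fm(x$municipal_impact), fm(x$municipal_impact)))
  if (!is.null(x$sensitivity)) {
    s <- x$sensitivity
    cat(sprintf("  sensitivity +/- %.0f%%:\n", 100 * s$fraction))
    cat(sprintf("    MH        %20s .. %20s\n",
                fm(s$mh["optimistic"]), fm(s$mh["pessimistic"])))
    cat(sprintf("    municipal %20s .. %20s\n",
                fm(s$municipal["optimistic"]), fm(s$municipal["pessimistic"])))
  }
  invisible(x)
}
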