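#' Construct and validate a municipality roster
#'
#' A roster is a data frame with one row per participating municipality:
#'
#' * `id` — opaque identifier;
#' * `vulnerability_indicator` — integer deprivation class (1 = least
#'   deprived; the study's data carry classes 1..6);
#' * `n_fhs_teams` — number of family-health (FHS) teams;
#' * `n_pmmb_physicians` — number of program physicians allocated;
#' * `contract_end_months` — semicolon-joined `"YYYY-MM"` months, one per
#'   physician, giving the month from which that physician is gone.
#'
#' Invariants enforced: physicians never exceed teams, the number of contract
#' end months equals the physician count, and indicators lie in
#' `1..max_indicator`.
#'
#' @param df data frame with the columns above.
#' @param max_indicator largest admissible vulnerability class.
#' @return `df` with class `pmmb_roster` prepended.
#' @seealso [generate_roster()], [sp_roster()]
#' @export
as_roster <- function(df, max_indicator = 6L) {
  req <- c("id", "vulnerability_indicator", "n_fhs_teams",
           "n_pmmb_physicians", "contract_end_months")
  if (!is.data.frame(df) || !all(req %in% names(df)))
    stop("roster must be a data frame with columns: ",
         paste(req, collapse = ", "), call. = FALSE)
  ind <- df$vulnerability_indicator
  if (any(ind != as.integer(ind)) || any(ind < 1 | ind > max_indicator))
    stop("vulnerability_indicator outside 1..", max_indicator, call. = FALSE)
  if (any(df$n_pmmb_physicians > df$n_fhs_teams))
    stop("n_pmmb_physicians exceeds n_fhs_teams for municipality(ies): ",
         paste(utils::head(df$id[df$n_pmmb_physicians > df$n_fhs_teams], 5),
               collapse = ", "), call. = FALSE)
  ends <- roster_end_lists(df)
  nend <- lengths(ends)
  if (any(nend != df$n_pmmb_physicians))
    stop("contract_end_months count disagrees with n_pmmb_physicians for: ",
         paste(utils::head(df$id[nend != df$n_pmmb_physicians], 5),
               collapse = ", "), call. = FALSE)
  lapply(ends, function(e) if (length(e)) ym_check(e))
  class(df) <- unique(c("pmmb_roster", class(df)))
  df
}

# split the semicolon-joined end months into a list of character vectors
roster_end_lists <- function(df) {
  lapply(df$contract_end_months, function(s) {
    if (is.na(s) || !nzchar(s)) character(0)
    else strsplit(s, ";", fixed = TRUE)[[1]]
  })
}

#' Program dependence of a municipality
#'
#' Program physicians as a percentage of the municipality's family-health
#' teams — the share of primary-care coverage that vanishes if the program
#' withdraws and nobody is replaced.
#'
#' @param n_pmmb_physicians,n_fhs_teams counts (vectorized); teams must be
#'   positive.
#' @return percentage in `[0, 100]` (values above 100 are impossible for a
#'   valid roster).
#' @examples
#' dependence_percent(4, 10)  # 40
#' @export
dependence_percent <- function(n_pmmb_physicians, n_fhs_teams) {
  if (any(n_fhs_teams <= 0))
    stop("municipality with zero FHS teams is not assessable", call. = FALSE)
  100 * n_pmmb_physicians / n_fhs_teams
}

#' Dependence bins
#'
#' The five classes used to stratify municipalities: half-open intervals
#' `[0,20), [20,40), [40,60), [60,80)` and the closed top bin `[80,100]`.
#' Bin edges are configurable.
#'
#' @param p dependence percentage(s) in `[0, 100]`.
#' @param breaks increasing numeric edges from 0 to 100.
#' @return factor of bin labels (`"0-20"`, ..., `"80-100"`).
#' @examples
#' bin_dependence(c(0, 40, 100))
#' @export
bin_dependence <- function(p, breaks = c(0, 20, 40, 60, 80, 100)) {
  stopifnot(is.numeric(breaks), length(breaks) >= 2,
            breaks[1] == 0, breaks[length(breaks)] == 100,
            all(diff(breaks) > 0))
  if (any(p < 0 | p > 100))
    stop("dependence percentage outside [0, 100]", call. = FALSE)
  labs <- paste(breaks[-length(breaks)], breaks[-1], sep = "-")
  idx <- findInterval(p, breaks[-length(breaks)])  # 100 lands in the top bin
  factor(labs[idx], levels = labs)
}

#' Cross-tabulate municipalities by dependence bin and vulnerability class
#'
#' @param roster a `pmmb_roster` (see [as_roster()]).
#' @param breaks dependence bin edges, see [bin_dependence()].
#' @param indicator_levels vector of indicator classes to tabulate over
#'   (defaults to `1..max` observed, or 1..6 for an empty roster).
#' @return an object of class `dependence_table`: list with the `counts`
#'   matrix (bins x indicators), `row_totals`, `col_totals` and
#'   `grand_total`.
#' @examples
#' tab <- cross_tab(sp_roster())
#' tab$grand_total  # 373
#' @export
cross_tab <- function(roster, breaks = c(0, 20, 40, 60, 80, 100),
                      indicator_levels = NULL) {
  roster <- as_roster(roster, max_indicator =
                        max(6L, if (nrow(roster)) max(roster$vulnerability_indicator) else 0L))
  if (is.null(indicator_levels))
    indicator_levels <- seq_len(max(6L, if (nrow(roster))
      max(roster$vulnerability_indicator) else 0L))
  labs <- paste(breaks[-length(breaks)], breaks[-1], sep = "-")
  if (nrow(roster)) {
    bins <- bin_dependence(
      dependence_percent(roster$n_pmmb_physicians, roster$n_fhs_teams), breaks)
    counts <- table(bin = bins,
                    indicator = factor(roster$vulnerability_indicator,
                                       levels = indicator_levels))
  } else {
    counts <- table(bin = factor(character(0), levels = labs),
                    indicator = factor(integer(0), levels = indicator_levels))
  }
  counts <- unclass(counts)
  structure(list(counts = counts,
                 row_totals = rowSums(counts),
                 col_totals = colSums(counts),
                 grand_total = sum(counts)),
            class = "dependence_table")
}

#' @export
print.dependence_table <- function(x, ...) {
  cat("Municipalities by program dependence (%) and vulnerability indicator\n")
  m <- cbind(x$counts, Total = x$row_totals)
  m <- rbind(m, Total = c(x$col_totals, x$grand_total))
  print(m)
  invisible(x)
}

#' @export
as.data.frame.dependence_table <- function(x, ...) {
  m <- cbind(x$counts, Total = x$row_totals)
  m <- rbind(m, Total = c(x$col_totals, x$grand_total))
  data.frame(dependence_bin = rownames(m), m, check.names = FALSE,
             row.names = NULL)
}

#' Replacement eligibility of a vulnerability class
#'
#' Under the 2019 allocation rule, only municipalities in vulnerability
#' classes at or above the threshold (default 4) keep physician replacement;
#' classes 1-3 lose their physicians at contract end.
#'
#' @param indicator integer class(es).
#' @param threshold smallest class retaining replacement.
#' @return logical vector.
#' @examples
#' eligible_for_replacement(1:6)
#' @export
eligible_for_replacement <- function(indicator, threshold = 4L) {
  stopifnot(is.numeric(indicator), is.numeric(threshold))
  indicator >= threshold
}

#' Project physician and municipality exit without replacement
#'
#' For every month of the horizon, counts the physicians still present and
#' the municipalities still participating (holding at least one physician).
#' Municipalities in eligible vulnerability classes retain their physicians
#' (departures are replaced); in ineligible classes each physician is gone
#' from their contract end month onward and never replaced. Both series are
#' monotone non-increasing.
#'
#' @param roster a `pmmb_roster`.
#' @param horizon length-2 `"YYYY-MM"` vector, inclusive.
#' @param threshold replacement-eligibility threshold, see
#'   [eligible_for_replacement()].
#' @return data frame of class `exit_projection` with columns `month`,
#'   `n_physicians`, `n_municipalities`.
#' @examples
#' ep <- exit_projection(sp_roster(), c("2019-01", "2022-03"))
#' ep[c(1, nrow(ep)), ]
#' @export
exit_projection <- function(roster, horizon = c("2019-01", "2022-03"),
                            threshold = 4L) {
  roster <- as_roster(roster, max_indicator =
                        max(6L, if (nrow(roster)) max(roster$vulnerability_indicator) else 0L))
  stopifnot(length(horizon) == 2)
  months <- ym_seq(horizon[1], horizon[2])
  midx <- ym_index(months)
  elig <- eligible_for_replacement(roster$vulnerability_indicator, threshold)
  ends <- roster_end_lists(roster)
  present <- matrix(0L, nrow = nrow(roster), ncol = length(midx))
  for (i in seq_len(nrow(roster))) {
    if (elig[i]) {
      present[i, ] <- roster$n_pmmb_physicians[i]
    } else if (roster$n_pmmb_physicians[i] > 0) {
      ei <- ym_index(ends[[i]])
      present[i, ] <- vapply(midx, function(m) sum(ei > m), integer(1))
    }
  }
  out <- data.frame(month = months,
                    n_physicians = colSums(present),
                    n_municipalities = colSums(present >= 1L),
                    stringsAsFactors = FALSE)
  class(out) <- c("exit_projection", "data.frame")
  out
}

#' Plot an exit projection
#'
#' Simple two-line rendering of the physician and municipality series over
#' the horizon.
#'
#' @param projection an `exit_projection` from [exit_projection()].
#' @return a ggplot object.
#' @export
plot_exit_projection <- function(projection) {
  stopifnot(inherits(projection, "exit_projection"))
  d <- rbind(
    data.frame(month = projection$month, count = projection$n_physicians,
               series = "physicians"),
    data.frame(month = projection$month, count = projection$n_municipalities,
               series = "municipalities"))
  d$month <- as.Date(paste0(d$month, "-01"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$month, y = .data$count,
                                  colour = .data$series)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = NULL, y = "count",
                  title = "Projected exit without physician replacement") +
    ggplot2::theme_minimal()
}
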