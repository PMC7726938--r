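#' Read and write pipeline inputs
#'
#' All tabular inputs travel as plain delimited text (comma-separated,
#' RFC-4180 quoting via [utils::read.csv()]/[utils::write.csv()]) and the
#' structured parameter sets as YAML, so every input is inspectable and
#' diffable.
#'
#' @name pmmb_io
NULL

#' @describeIn pmmb_io write a [cycle_schedule()] as CSV (columns `label`,
#'   `effective_month`, `n_physicians`; the horizon is stored in a leading
#'   `# horizon:` comment line).
#' @param schedule a [cycle_schedule()].
#' @param file path.
#' @export
write_cycle_schedule <- function(schedule, file) {
  stopifnot(inherits(schedule, "cycle_schedule"))
  con <- file(file, "w"); on.exit(close(con))
  writeLines(sprintf("# horizon: %s %s", schedule$horizon[1],
                     schedule$horizon[2]), con)
  utils::write.csv(schedule$entries, con, row.names = FALSE, quote = TRUE)
  invisible(file)
}

#' @describeIn pmmb_io read a schedule CSV back; if the file lacks the
#'   horizon comment, `horizon_start`/`horizon_end` default to the first and
#'   last entry months.
#' @param horizon_start,horizon_end optional `"YYYY-MM"` overrides.
#' @export
read_cycle_schedule <- function(file, horizon_start = NULL, horizon_end = NULL) {
  first <- readLines(file, n = 1)
  if (grepl("^# horizon:", first)) {
    h <- strsplit(sub("^# horizon:\\s*", "", first), "\\s+")[[1]]
    if (is.null(horizon_start)) horizon_start <- h[1]
    if (is.null(horizon_end))   horizon_end <- h[2]
  }
  d <- utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE,
                       colClasses = c(label = "character",
                                      effective_month = "character",
                                      n_physicians = "integer"))
  if (is.null(horizon_start)) horizon_start <- d$effective_month[1]
  if (is.null(horizon_end))   horizon_end <- d$effective_month[nrow(d)]
  cycle_schedule(d$label, d$effective_month, d$n_physicians,
                 horizon_start, horizon_end)
}

#' @describeIn pmmb_io write a roster as CSV (contract end months
#'   semicolon-joined within one field).
#' @param roster a `pmmb_roster`.
#' @export
write_roster <- function(roster, file) {
  roster <- as_roster(roster, max_indicator =
                        max(6L, if (nrow(roster)) max(roster$vulnerability_indicator) else 0L))
  utils::write.csv(as.data.frame(roster), file, row.names = FALSE, quote = TRUE)
  invisible(file)
}

#' @describeIn pmmb_io read a roster CSV and validate it.
#' @export
read_roster <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE,
                       colClasses = c(id = "character",
                                      vulnerability_indicator = "integer",
                                      n_fhs_teams = "integer",
                                      n_pmmb_physicians = "integer",
                                      contract_end_months = "character"))
  d$contract_end_months[is.na(d$contract_end_months)] <- ""
  as_roster(d, max_indicator = max(6L, max(d$vulnerability_indicator)))
}

#' @describeIn pmmb_io write [cost_parameters()] as YAML (the derived
#'   `pcf_dif` is written for reference but re-derived on read).
#' @param params a [cost_parameters()].
#' @export
write_cost_parameters <- function(params, file) {
  stopifnot(inherits(params, "cost_parameters"))
  yaml::write_yaml(unclass(params), file, precision = 12)
  invisible(file)
}

#' @describeIn pmmb_io read and validate cost parameters from YAML; unknown
#'   keys are rejected.
#' @export
read_cost_parameters <- function(file) {
  x <- yaml::read_yaml(file)
  x$pcf_dif <- NULL                      # derived, never trusted from disk
  known <- setdiff(names(formals(cost_parameters)), "payroll")
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown cost parameter key(s) in ", file, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  do.call(cost_parameters, x)
}

#' @describeIn pmmb_io write [payroll_rules()] as YAML.
#' @param rules a [payroll_rules()].
#' @export
write_payroll_rules <- function(rules, file) {
  stopifnot(inherits(rules, "payroll_rules"))
  x <- unclass(rules)
  x$tax_brackets <- lapply(seq_len(nrow(rules$tax_brackets)), function(i)
    list(upper_bound = if (is.infinite(rules$tax_brackets$upper_bound[i]))
           ".inf" else rules$tax_brackets$upper_bound[i],
         marginal_rate = rules$tax_brackets$marginal_rate[i],
         deduction_parcel = rules$tax_brackets$deduction_parcel[i]))
  yaml::write_yaml(x, file, precision = 12)
  invisible(file)
}

#' @describeIn pmmb_io read and validate payroll rules from YAML.
#' @export
read_payroll_rules <- function(file) {
  x <- yaml::read_yaml(file)
  known <- names(formals(payroll_rules))
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown payroll rule key(s) in ", file, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(x$tax_brackets)) {
    ub <- vapply(x$tax_brackets, function(b)
      if (identical(b$upper_bound, ".inf")) Inf else as.numeric(b$upper_bound),
      numeric(1))
    x$tax_brackets <- data.frame(
      upper_bound = ub,
      marginal_rate = vapply(x$tax_brackets, function(b)
        as.numeric(b$marginal_rate), numeric(1)),
      deduction_parcel = vapply(x$tax_brackets, function(b)
        as.numeric(b$deduction_parcel), numeric(1)))
  }
  do.call(payroll_rules, x)
}
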