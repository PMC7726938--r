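#' Configuration for a full pipeline run
#'
#' Collects the file paths, convention flags and output location of an
#' end-to-end run. Any input path left `NULL` falls back to the packaged
#' São Paulo fixture object, so `run_config()` with no arguments reproduces
#' the headline analysis.
#'
#' @param params_file,rules_file YAML files for [read_cost_parameters()] /
#'   [read_payroll_rules()], or `NULL` for the fixtures.
#' @param schedule_file,roster_file CSV files for [read_cycle_schedule()] /
#'   [read_roster()], or `NULL` for the fixtures.
#' @param convention baseline municipal accounting convention, see
#'   [municipal_monthly_cost()].
#' @param bin_breaks dependence bin edges, see [bin_dependence()].
#' @param eligibility_threshold replacement-eligibility threshold.
#' @param sensitivity_fraction override of the parameter set's fraction, or
#'   `NULL` to use it.
#' @param out_dir output directory (created if missing), or `NULL` to skip
#'   writing files.
#' @param seed integer seed for the fixture roster draw.
#' @param locale currency locale for the human-readable report, `"iso"` or
#'   `"br"`.
#' @param verbose print progress.
#' @return an object of class `run_config`.
#' @export
run_config <- function(params_file = NULL, rules_file = NULL,
                       schedule_file = NULL, roster_file = NULL,
                       convention = c("as_printed_table", "as_printed_box"),
                       bin_breaks = c(0, 20, 40, 60, 80, 100),
                       eligibility_threshold = 4L,
                       sensitivity_fraction = NULL,
                       out_dir = NULL, seed = 20190131L,
                       locale = c("iso", "br"), verbose = FALSE) {
  convention <- match.arg(convention)
  locale <- match.arg(locale)
  for (f in c(params_file, rules_file, schedule_file, roster_file))
    if (!is.null(f) && !file.exists(f))
      stop("configured input file does not exist: ", f, call. = FALSE)
  structure(list(params_file = params_file, rules_file = rules_file,
                 schedule_file = schedule_file, roster_file = roster_file,
                 convention = convention, bin_breaks = bin_breaks,
                 eligibility_threshold = as.integer(eligibility_threshold),
                 sensitivity_fraction = sensitivity_fraction,
                 out_dir = out_dir, seed = as.integer(seed),
                 locale = locale, verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Run the full budget-impact pipeline
#'
#' Orchestrates every stage: load (or default) the payroll rules, cost
#' parameters, cycle schedule and roster; expand the schedule into the
#' monthly cost series; accumulate payer totals, counterfactual totals,
#' impacts and sensitivity bounds; cross-tabulate the roster; project the
#' physician/municipality exit. When `cfg$out_dir` is set, each product is
#' written as both CSV and JSON alongside an audit log holding one row per
#' computed cell and a dump of every parameter used; machine outputs are
#' always ISO-decimal.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) an object of class `pmmb_report`: a list with
#'   `per_cycle`, `monthly_series`, `impact` (an `impact_summary`),
#'   `dependence_table`, `exit_projection`, `parameters`, `audit_log` and
#'   `files` (paths written, if any). Stage failures propagate with the
#'   stage name prefixed.
#' @examples
#' rep <- run_pipeline(run_config())
#' round_brl(rep$impact$municipal_impact)
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (cfg$verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))
  }

  say("loading inputs")
  rules <- stage("payroll_rules",
                 if (is.null(cfg$rules_file)) sp_payroll_rules()
                 else read_payroll_rules(cfg$rules_file))
  params <- stage("cost_parameters",
                  if (is.null(cfg$params_file)) cost_parameters(payroll = rules)
                  else read_cost_parameters(cfg$params_file))
  schedule <- stage("cycle_schedule",
                    if (is.null(cfg$schedule_file)) sp_cycle_schedule()
                    else read_cycle_schedule(cfg$schedule_file))
  roster <- stage("roster",
                  if (is.null(cfg$roster_file)) sp_roster(cfg$seed)
                  else read_roster(cfg$roster_file))
  f <- if (is.null(cfg$sensitivity_fraction)) params$sensitivity_fraction
       else cfg$sensitivity_fraction

  say("projecting costs")
  series <- stage("projection",
                  expand_schedule(schedule, params, cfg$convention))
  actual <- cost_totals(series)
  cf     <- stage("counterfactual",
                  counterfactual_totals(schedule, params, cfg$convention))
  impact <- sensitivity(financial_impact(actual, cf), f)

  say("stratifying roster")
  dep  <- stage("stratification", cross_tab(roster, cfg$bin_breaks))
  exit <- stage("exit_projection",
                exit_projection(roster, schedule$horizon,
                                cfg$eligibility_threshold))

  w <- month_weights(schedule)
  per_cycle <- data.frame(
    cycle = schedule$entries$label,
    effective_month = schedule$entries$effective_month,
    months_active = w,
    n_physicians = schedule$entries$n_physicians,
    mh_cost = round_brl(vapply(seq_along(w), function(i)
      series$mh_cost[match(schedule$entries$effective_month[i], series$month)],
      numeric(1))),
    municipal_cost = round_brl(vapply(seq_along(w), function(i)
      series$municipal_cost[match(schedule$entries$effective_month[i],
                                  series$month)], numeric(1))),
    stringsAsFactors = FALSE)

  audit <- rbind(
    data.frame(stage = "per_cycle",
               quantity = paste0(rep(per_cycle$cycle, each = 2),
                                 c(":mh", ":municipal")),
               value = as.vector(rbind(per_cycle$mh_cost,
                                       per_cycle$municipal_cost))),
    data.frame(stage = "totals",
               quantity = c("mh_total", "municipal_total"),
               value = round_brl(unname(actual))),
    data.frame(stage = "counterfactual",
               quantity = c("mh_counterfactual", "municipal_counterfactual"),
               value = round_brl(unname(cf))),
    data.frame(stage = "impact",
               quantity = c("mh_impact", "municipal_impact"),
               value = round_brl(c(impact$mh_impact, impact$municipal_impact))),
    data.frame(stage = "sensitivity",
               quantity = c("mh_optimistic", "mh_pessimistic",
                            "municipal_optimistic", "municipal_pessimistic"),
               value = unname(c(impact$sensitivity$mh,
                                impact$sensitivity$municipal))))

  report <- structure(list(
    per_cycle = per_cycle,
    monthly_series = series,
    impact = impact,
    dependence_table = dep,
    exit_projection = exit,
    parameters = list(cost = unclass(params), payroll = unclass(rules),
                      convention = cfg$convention,
                      bin_breaks = cfg$bin_breaks,
                      eligibility_threshold = cfg$eligibility_threshold,
                      sensitivity_fraction = f, seed = cfg$seed),
    audit_log = audit,
    files = character(0)
  ), class = "pmmb_report")

  if (!is.null(cfg$out_dir)) {
    say("writing report to ", cfg$out_dir)
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(cfg$out_dir, ...)
    wcsv <- function(d, f) { utils::write.csv(d, p(f), row.names = FALSE); p(f) }
    wjson <- function(x, f) {
      jsonlite::write_json(x, p(f), auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", pretty = TRUE)
      p(f)
    }
    imp <- impact
    impact_block <- list(
      mh_total = round_brl(imp$mh_total),
      municipal_total = round_brl(imp$municipal_total),
      mh_counterfactual = round_brl(imp$mh_counterfactual),
      municipal_counterfactual = round_brl(imp$municipal_counterfactual),
      mh_impact = round_brl(imp$mh_impact),
      municipal_impact_signed = -round_brl(imp$municipal_impact),
      sensitivity = imp$sensitivity)
    files <- c(
      wcsv(per_cycle, "per_cycle.csv"),
      wcsv(within(series, { mh_cost <- round_brl(mh_cost)
                            municipal_cost <- round_brl(municipal_cost) }),
           "monthly_series.csv"),
      wcsv(as.data.frame(dep), "dependence_table.csv"),
      wcsv(exit, "exit_projection.csv"),
      wcsv(audit, "audit_log.csv"),
      wjson(impact_block, "impact.json"),
      wjson(list(per_cycle = per_cycle,
                 monthly_series = data.frame(unclass(series),
                                             stringsAsFactors = FALSE),
                 exit_projection = data.frame(unclass(exit),
                                              stringsAsFactors = FALSE)),
            "series.json"),
      wjson(report$parameters, "parameters.json"))
    report$files <- files
  }
  invisible(report)
}

#' @export
print.pmmb_report <- function(x, locale = "iso", ...) {
  cat("Budget-impact report\n\nPer-cycle costs:\n")
  pc <- x$per_cycle
  pc$mh_cost <- format_brl(pc$mh_cost, locale)
  pc$municipal_cost <- format_brl(pc$municipal_cost, locale)
  print(pc, row.names = FALSE)
  cat("\n")
  print(x$impact, locale = locale)
  cat("\n")
  print(x$dependence_table)
  ep <- x$exit_projection
  cat(sprintf("\nExit projection: %s (%d physicians, %d municipalities) -> %s (%d, %d)\n",
              ep$month[1], ep$n_physicians[1], ep$n_municipalities[1],
              ep$month[nrow(ep)], ep$n_physicians[nrow(ep)],
              ep$n_municipalities[nrow(ep)]))
  invisible(x)
}
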