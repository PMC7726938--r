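#' Specification for a synthetic municipality roster
#'
#' Describes the statistical structure a generated roster must carry: how
#' many municipalities and physicians, how municipalities distribute over
#' vulnerability classes and dependence bins (either as marginals or as an
#' exact bin x class cell matrix), and how the contract end months of
#' physicians in non-eligible municipalities distribute over the horizon.
#' The generator stands in for the public-registry extraction the real
#' analysis starts from, so every pipeline stage is testable offline.
#'
#' @param n_municipalities number of municipalities.
#' @param total_physicians total program physicians across the roster.
#' @param indicator_marginals named integer vector, vulnerability class ->
#'   municipality count; must sum to `n_municipalities`. Ignored when
#'   `cross_tab_cells` is supplied.
#' @param dependence_marginals optional named integer vector, dependence bin
#'   label -> municipality count (same sum constraint). When omitted and no
#'   cell matrix is given, bins are assigned uniformly at random.
#' @param cross_tab_cells optional exact cell matrix (dependence bins in
#'   rows, vulnerability classes in columns) that the generated roster's
#'   [cross_tab()] must reproduce exactly.
#' @param contract_end_profile named integer vector, `"YYYY-MM"` -> count of
#'   non-eligible physicians whose contract ends that month. If its sum
#'   equals the non-eligible physician total the counts are honored exactly;
#'   otherwise it is used as sampling weights.
#' @param eligibility_threshold replacement-eligibility threshold (see
#'   [eligible_for_replacement()]).
#' @param retained_end_month placeholder contract end month recorded for
#'   physicians in eligible municipalities (their departures are replaced, so
#'   the month never drives the projection).
#' @param attrition_rate optional first-year dropout fraction carried as
#'   metadata for scenario runs (the headline analysis assumes 0).
#' @param seed integer seed; generation is fully deterministic given the
#'   spec and seed.
#' @return an object of class `roster_spec`.
#' @seealso [generate_roster()], [sp_roster_spec()]
#' @export
roster_spec <- function(n_municipalities,
                        total_physicians,
                        indicator_marginals,
                        dependence_marginals = NULL,
                        cross_tab_cells = NULL,
                        contract_end_profile,
                        eligibility_threshold = 4L,
                        retained_end_month = "2022-03",
                        attrition_rate = 0,
                        seed = 1L) {
  stopifnot(n_municipalities >= 1, total_physicians >= 1)
  if (attrition_rate < 0 || attrition_rate > 1)
    stop("attrition_rate must lie in [0, 1]", call. = FALSE)
  if (!is.null(cross_tab_cells)) {
    stopifnot(is.matrix(cross_tab_cells))
    if (sum(cross_tab_cells) != n_municipalities)
      stop("infeasible spec: cross_tab_cells sum to ", sum(cross_tab_cells),
           " but n_municipalities is ", n_municipalities, call. = FALSE)
  } else {
    if (sum(indicator_marginals) != n_municipalities)
      stop("infeasible spec: indicator_marginals sum to ",
           sum(indicator_marginals), " but n_municipalities is ",
           n_municipalities, call. = FALSE)
    if (!is.null(dependence_marginals) &&
        sum(dependence_marginals) != n_municipalities)
      stop("infeasible spec: dependence_marginals sum to ",
           sum(dependence_marginals), " but n_municipalities is ",
           n_municipalities, call. = FALSE)
  }
  if (total_physicians < n_municipalities)
    stop("infeasible spec: every participating municipality needs at least ",
         "one physician (total_physicians < n_municipalities)", call. = FALSE)
  ym_check(names(contract_end_profile))
  ym_check(retained_end_month)
  structure(list(n_municipalities = as.integer(n_municipalities),
                 total_physicians = as.integer(total_physicians),
                 indicator_marginals = indicator_marginals,
                 dependence_marginals = dependence_marginals,
                 cross_tab_cells = cross_tab_cells,
                 contract_end_profile = contract_end_profile,
                 eligibility_threshold = as.integer(eligibility_threshold),
                 retained_end_month = retained_end_month,
                 attrition_rate = attrition_rate,
                 seed = as.integer(seed)),
            class = "roster_spec")
}

# smallest team count t >= max(p, 1) with dependence 100 p / t in `bin`,
# optionally jittered upward within the feasible range
team_count_for_bin <- function(p, bin, breaks, jitter = TRUE) {
  labs <- paste(breaks[-length(breaks)], breaks[-1], sep = "-")
  k <- match(as.character(bin), labs)
  lo <- breaks[k]; hi <- breaks[k + 1]
  t <- max(p, 1L)
  while (as.character(bin_dependence(100 * p / t, breaks)) != as.character(bin)) {
    t <- t + 1L
    if (t > 1000L * max(p, 1L) + 100L)
      stop("no feasible team count for p = ", p, " in bin ", bin, call. = FALSE)
  }
  if (jitter && lo > 0) {
    t_max <- floor(100 * p / lo)
    if (t_max > t) {
      cand <- t + sample.int(t_max - t + 1L, 1L) - 1L
      if (as.character(bin_dependence(100 * p / cand, breaks)) ==
          as.character(bin)) t <- cand
    }
  }
  t
}

#' Generate a synthetic municipality roster
#'
#' Deterministic given the spec and its seed. Allocation follows a
#' quota-first scheme: municipalities are placed into (dependence bin,
#' vulnerability class) cells exactly as requested (or by seeded random
#' pairing of the marginals); physicians are split within the eligible and
#' non-eligible groups by equal quota with the remainder assigned to a
#' seeded random subset, every municipality receiving at least one; team
#' counts are then chosen so each municipality's dependence falls in its
#' assigned bin; finally the contract end months of non-eligible physicians
#' are drawn from (or matched exactly to) the requested profile.
#'
#' @param spec a [roster_spec()].
#' @return a `pmmb_roster` data frame (see [as_roster()]).
#' @examples
#' r <- generate_roster(sp_roster_spec())
#' cross_tab(r)$grand_total  # 373
#' @export
generate_roster <- function(spec) {
  stopifnot(inherits(spec, "roster_spec"))
  breaks <- c(0, 20, 40, 60, 80, 100)
  labs <- paste(breaks[-length(breaks)], breaks[-1], sep = "-")
  with_local_seed(spec$seed, {
    # 1. cell placement -----------------------------------------------------
    if (!is.null(spec$cross_tab_cells)) {
      cells <- spec$cross_tab_cells
      if (is.null(rownames(cells))) rownames(cells) <- labs[seq_len(nrow(cells))]
      if (is.null(colnames(cells))) colnames(cells) <- seq_len(ncol(cells))
      idx <- which(cells > 0, arr.ind = TRUE)
      bin <- rep(rownames(cells)[idx[, 1]], cells[idx])
      ind <- rep(as.integer(colnames(cells)[idx[, 2]]), cells[idx])
    } else {
      ind <- rep(as.integer(names(spec$indicator_marginals)),
                 spec$indicator_marginals)
      if (!is.null(spec$dependence_marginals)) {
        bin <- rep(names(spec$dependence_marginals), spec$dependence_marginals)
      } else {
        bin <- sample(labs, spec$n_municipalities, replace = TRUE)
      }
      bin <- sample(bin)   # random pairing of the two marginals
    }
    n <- length(ind)
    elig <- eligible_for_replacement(ind, spec$eligibility_threshold)

    # 2. physician allocation ----------------------------------------------
    prof_sum <- sum(spec$contract_end_profile)
    n_inel <- sum(!elig)
    if (n_inel == 0 && prof_sum > 0 && prof_sum != 0)
      stop("infeasible spec: contract_end_profile names departures but no ",
           "municipality is below the eligibility threshold", call. = FALSE)
    exact_profile <- n_inel > 0 && prof_sum >= n_inel &&
      prof_sum <= spec$total_physicians - sum(elig)
    inel_total <- if (n_inel == 0) 0L
      else if (exact_profile) as.integer(prof_sum)
      else round(spec$total_physicians * n_inel / n)
    inel_total <- max(inel_total, n_inel)                      # >= 1 each
    elig_total <- spec$total_physicians - inel_total
    if (sum(elig) > 0 && elig_total < sum(elig))
      stop("infeasible spec: not enough physicians to give each eligible ",
           "municipality at least one (need ", sum(elig), ", have ",
           elig_total, ")", call. = FALSE)
    quota <- function(total, k) {
      if (k == 0) return(integer(0))
      base <- total %/% k; rem <- total %% k
      out <- rep(base, k)
      if (rem > 0) out[sample.int(k, rem)] <- base + 1L
      out
    }
    p <- integer(n)
    p[!elig] <- quota(inel_total, n_inel)
    p[elig]  <- quota(elig_total, sum(elig))

    # 3. team counts consistent with the assigned dependence bin ------------
    t <- mapply(team_count_for_bin, p, bin,
                MoreArgs = list(breaks = breaks, jitter = TRUE))

    # 4. contract end months -------------------------------------------------
    months <- names(spec$contract_end_profile)
    ends <- character(n)
    inel_idx <- which(!elig)
    pool <- rep(inel_idx, p[inel_idx])          # one slot per physician
    if (length(pool)) {
      pool <- sample(pool)                      # seeded shuffle of slots
      slot_month <- if (exact_profile && length(pool) == prof_sum) {
        rep(months, spec$contract_end_profile)
      } else {
        sample(months, length(pool), replace = TRUE,
               prob = spec$contract_end_profile / prof_sum)
      }
      per_muni <- split(slot_month, pool)
      ends[as.integer(names(per_muni))] <-
        vapply(per_muni, function(m) paste(sort(m), collapse = ";"),
               character(1))
    }
    ends[elig] <- vapply(p[elig], function(k)
      paste(rep(spec$retained_end_month, k), collapse = ";"), character(1))
    ends[p == 0] <- ""

    as_roster(data.frame(
      id = sprintf("M%04d", seq_len(n)),
      vulnerability_indicator = ind,
      n_fhs_teams = as.integer(t),
      n_pmmb_physicians = as.integer(p),
      contract_end_months = ends,
      stringsAsFactors = FALSE
    ), max_indicator = max(6L, max(ind)))
  })
}

#' Stochastic first-year attrition scenario
#'
#' Exploratory departure scenario: evidence on the program suggests a
#' substantial share of physicians drop out within their first contract
#' year, while the headline analysis fixes a no-attrition assumption. This
#' helper thins the standing cohort by a binomial draw applied after the
#' first 12 horizon months, preserving the non-increasing count invariant.
#'
#' @param schedule a [cycle_schedule()].
#' @param rate first-year dropout fraction in `[0, 1]`; 0 returns the
#'   schedule unchanged.
#' @param seed integer seed for the binomial draw.
#' @return a [cycle_schedule()] with the extra departures folded in.
#' @examples
#' apply_attrition(sp_cycle_schedule(), 0.208, seed = 1)
#' @export
apply_attrition <- function(schedule, rate, seed = 1L) {
  stopifnot(inherits(schedule, "cycle_schedule"))
  if (rate < 0 || rate > 1)
    stop("attrition rate must lie in [0, 1]", call. = FALSE)
  if (rate == 0) return(schedule)
  nm <- n_horizon_months(schedule)
  if (nm <= 12L) return(schedule)   # no month beyond the first year
  midx <- seq.int(ym_index(schedule$horizon[1]), ym_index(schedule$horizon[2]))
  eidx <- ym_index(schedule$entries$effective_month)
  which_entry <- findInterval(midx, eidx)
  counts <- schedule$entries$n_physicians[which_entry]
  cohort <- counts[min(12L, length(counts))]
  extra <- with_local_seed(seed, stats::rbinom(1L, cohort, rate))
  counts[-seq_len(12L)] <- pmax(0L, counts[-seq_len(12L)] - extra)
  counts <- cummin(counts)
  keep <- c(TRUE, diff(counts) != 0)
  labels <- ifelse(midx[keep] %in% eidx,
                   schedule$entries$label[match(midx[keep], eidx)],
                   "attrition")
  cycle_schedule(labels, ym_from_index(midx[keep]), counts[keep],
                 schedule$horizon[1], schedule$horizon[2])
}
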