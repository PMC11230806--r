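# Costing of a cohort trace: per-cycle component costs with half-cycle
# correction, and mid-cycle discounting.

#' Cost components for one model cycle
#'
#' Person-year–based costs (hemodialysis while wait-listed, post-transplant
#' follow-up) use trapezoidal half-cycle correction: the person-years billed
#' are the mean of the cycle-start and cycle-end occupancies. Event-based
#' costs are booked per event: the transplant episode per transplant
#' performed, and preservation per kidney recovered — static cold storage for
#' every SCD kidney and, under the comparator, for ECD kidneys too; under
#' machine perfusion, the per-kidney perfusion cost for every ECD kidney plus
#' the annual program-level training cost.
#'
#' @param start,end Cohort states at the cycle boundaries.
#' @param events Cycle events from [step_cohort()].
#' @param costs Cost parameters (`p$costs`).
#' @param strategy One of [strategy_ids()].
#' @return Named list of undiscounted USD amounts: `dialysis_usd`,
#'   `transplant_episode_usd`, `preservation_usd`, `followup_usd`,
#'   `total_usd`.
#' @export
cycle_costs <- function(start, end, events, costs, strategy) {
  check_strategy(strategy)
  wl_py <- (start$waitlist + end$waitlist) / 2
  graft_py <- (sum(start$graft_scd) + sum(start$graft_ecd) +
               sum(end$graft_scd) + sum(end$graft_ecd)) / 2
  dialysis <- costs$hd_session_usd * costs$hd_sessions_per_year * wl_py
  episode <- costs$transplant_episode_usd *
    (events$transplants_scd + events$transplants_ecd)
  ecd_per_kidney <- if (strategy == "HMP_FOR_ECD") costs$hmp_per_kidney_usd else
    costs$cold_storage_per_kidney_usd
  preservation <- events$offers_scd * costs$cold_storage_per_kidney_usd +
    events$offers_ecd * ecd_per_kidney +
    if (strategy == "HMP_FOR_ECD") costs$hmp_training_annual_usd else 0
  followup <- costs$followup_annual_usd * graft_py
  list(
    dialysis_usd = dialysis,
    transplant_episode_usd = episode,
    preservation_usd = preservation,
    followup_usd = followup,
    total_usd = dialysis + episode + preservation + followup
  )
}

#' Per-cycle cost table for a trace
#'
#' @param trace A `cohort_trace`.
#' @param costs Cost parameters; defaults to the ones carried by the trace.
#' @return A tibble, one row per cycle, columns per cost component plus
#'   `total_usd`, all undiscounted.
#' @export
cost_trace <- function(trace, costs = trace$params$costs) {
  stopifnot(inherits(trace, "cohort_trace"))
  rows <- lapply(seq_len(trace$horizon), function(t) {
    cc <- cycle_costs(trace$states[[t]], trace$states[[t + 1]],
                      trace$events[[t]], costs, trace$strategy)
    tibble::tibble(cycle = t, !!!cc)
  })
  do.call(rbind, rows)
}

#' Discount a per-cycle series at mid-cycle timing
#'
#' Cycle `t` (1-based) is divided by `(1 + rate)^(t - 0.5)`: amounts accrue
#' mid-cycle on average, consistent with the half-cycle correction applied to
#' occupancies.
#'
#' @param values Per-cycle amounts (cycle 1 first).
#' @param rate Annual discount rate (fraction, >= 0).
#' @return Numeric vector of discounted per-cycle amounts.
#' @examples
#' sum(discount_series(rep(100, 5), 0.05))
#' @export
discount_series <- function(values, rate) {
  values * discount_factors(length(values), rate)
}

#' Discounted and undiscounted component totals
#'
#' @param cost_tbl Per-cycle cost table from [cost_trace()].
#' @param rate Annual discount rate.
#' @return A tibble with one row per component (and `total_usd`), columns
#'   `undiscounted_usd` and `discounted_usd`.
#' @export
discount_totals <- function(cost_tbl, rate) {
  comp <- setdiff(names(cost_tbl), "cycle")
  rows <- lapply(comp, function(cn) {
    v <- cost_tbl[[cn]]
    tibble::tibble(component = cn,
                   undiscounted_usd = sum(v),
                   discounted_usd = sum(discount_series(v, rate)))
  })
  do.call(rbind, rows)
}
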