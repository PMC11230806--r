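# Strategy summaries, ICERs, and cost-effectiveness-plane classification.

#' Summarize one strategy run
#'
#' Aggregates a cohort trace and its costs into the outcome set of the
#' cost-effectiveness comparison: total discounted cost, transplants
#' performed, deaths (on the list and with a functioning graft), dialysis
#' dependence, and patients alive at the end of the horizon.
#' `dialysis_dependent` is, by default, half-cycle-corrected waiting-list
#' person-years summed over the horizon — the model's measure of time spent
#' dependent on dialysis; `dialysis_basis = "headcount"` reports the
#' end-of-horizon waiting-list size instead. With `discount_outcomes = TRUE`
#' the per-cycle event counts and person-years are discounted like costs.
#'
#' @param trace A `cohort_trace`.
#' @param cost_tbl Per-cycle costs from [cost_trace()] for the same run.
#' @param rate Annual discount rate for costs (and outcomes if requested).
#' @param discount_outcomes Discount outcome counts as well as costs?
#' @param dialysis_basis `"person_years"` (default) or `"headcount"`.
#' @return A `strategy_result` list.
#' @export
summarize_strategy <- function(trace, cost_tbl, rate = trace$params$econ$discount_rate,
                               discount_outcomes = trace$params$econ$discount_outcomes,
                               dialysis_basis = c("person_years", "headcount")) {
  stopifnot(inherits(trace, "cohort_trace"))
  dialysis_basis <- match.arg(dialysis_basis)
  H <- trace$horizon
  ev <- trace$events
  tx <- vapply(ev, function(e) e$transplants_scd + e$transplants_ecd, numeric(1))
  d_list <- vapply(ev, function(e) e$deaths_list, numeric(1))
  d_graft <- vapply(ev, function(e) e$deaths_graft, numeric(1))
  wl_py <- vapply(seq_len(H), function(t) {
    (trace$states[[t]]$waitlist + trace$states[[t + 1]]$waitlist) / 2
  }, numeric(1))
  agg <- if (isTRUE(discount_outcomes)) {
    function(v) sum(discount_series(v, rate))
  } else sum
  dialysis <- if (dialysis_basis == "headcount") {
    trace$states[[H + 1]]$waitlist
  } else agg(wl_py)
  deaths_total <- agg(d_list) + agg(d_graft)
  entrants <- trace$params$demography$initial_waitlist +
    trace$states[[H + 1]]$entrants_cum
  totals <- discount_totals(cost_tbl, rate)
  total_cost <- totals$discounted_usd[totals$component == "total_usd"]
  structure(list(
    strategy = trace$strategy,
    total_cost_usd = total_cost,
    cost_totals = totals,
    transplants_total = agg(tx),
    deaths_on_list = agg(d_list),
    deaths_with_graft = agg(d_graft),
    deaths_total = deaths_total,
    dialysis_dependent = dialysis,
    patients_alive = entrants - deaths_total
  ), class = "strategy_result")
}

#' Incremental cost-effectiveness ratio with dominance classification
#'
#' Classifies a (delta cost, delta effect) pair on the cost-effectiveness
#' plane, where a positive `delta_effect` is an improvement. A cheaper,
#' better strategy is *dominant*; a dearer, worse one *dominated*; a dearer,
#' better one is a tradeoff, cost-effective when the ratio does not exceed
#' the willingness-to-pay threshold. The ratio is reported only for
#' tradeoffs (both deltas nonzero with an interpretable sign pattern).
#'
#' @param delta_cost Incremental cost (intervention minus comparator), USD.
#' @param delta_effect Incremental effect (positive = better).
#' @param threshold Willingness-to-pay threshold, USD per effect unit.
#' @return An `icer_result` list: `delta_cost_usd`, `delta_effect`,
#'   `ratio_usd_per_unit` (`NA` when no ratio applies),
#'   `classification`, `threshold_used_usd`.
#' @examples
#' icer(4486009, 815, 19570.52)
#' @export
icer <- function(delta_cost, delta_effect, threshold = 19570.52) {
  stopifnot(is.finite(delta_cost), is.finite(delta_effect), threshold > 0)
  ratio <- NA_real_
  if (delta_effect == 0) {
    # same effect: classification rests on the cost sign alone
    classification <- if (delta_cost > 0) "dominated"
      else if (delta_cost < 0) "dominant" else "tradeoff_cost_effective"
  } else if (delta_effect > 0 && delta_cost <= 0) {
    classification <- "dominant"
  } else if (delta_effect < 0 && delta_cost >= 0) {
    classification <- "dominated"
  } else {
    ratio <- delta_cost / delta_effect
    if (delta_effect > 0) {
      classification <- if (ratio <= threshold) "tradeoff_cost_effective"
        else "tradeoff_not_cost_effective"
    } else {
      # cheaper but worse: cost-effective when savings per effect lost
      # exceed the threshold
      classification <- if (ratio >= threshold) "tradeoff_cost_effective"
        else "tradeoff_not_cost_effective"
    }
  }
  structure(list(
    delta_cost_usd = delta_cost,
    delta_effect = delta_effect,
    ratio_usd_per_unit = ratio,
    classification = classification,
    threshold_used_usd = threshold
  ), class = "icer_result")
}

#' Assemble the main cost-effectiveness results table
#'
#' Builds the four-outcome comparison table (patients alive, transplants
#' performed, dialysis dependence, total cost) from two strategy summaries:
#' intervention and comparator columns, their difference oriented so that a
#' positive value favors the intervention, and the ICER in USD per unit of
#' each health outcome gained.
#'
#' @param mp `strategy_result` for the machine-perfusion strategy.
#' @param cs `strategy_result` for the cold-storage comparator.
#' @return A tibble with columns `outcome`, `machine_perfusion`,
#'   `cold_storage`, `difference`, `icer_usd`.
#' @export
cea_table <- function(mp, cs) {
  d_cost <- mp$total_cost_usd - cs$total_cost_usd
  d_alive <- mp$patients_alive - cs$patients_alive
  d_tx <- mp$transplants_total - cs$transplants_total
  d_dial <- cs$dialysis_dependent - mp$dialysis_dependent  # avoided
  ratio <- function(eff) if (eff == 0) NA_real_ else d_cost / eff
  tibble::tibble(
    outcome = c("patients_alive", "transplants_performed",
                "dialysis_dependent", "total_cost_usd"),
    machine_perfusion = c(mp$patients_alive, mp$transplants_total,
                          mp$dialysis_dependent, mp$total_cost_usd),
    cold_storage = c(cs$patients_alive, cs$transplants_total,
                     cs$dialysis_dependent, cs$total_cost_usd),
    difference = c(d_alive, d_tx, d_dial, d_cost),
    icer_usd = c(ratio(d_alive), ratio(d_tx), ratio(d_dial), NA_real_)
  )
}

#' Run and compare both preservation strategies
#'
#' Runs the cohort model under universal static cold storage and under
#' machine perfusion for ECD kidneys, costs both traces, and returns the
#' per-outcome incremental results with cost-effectiveness-plane
#' classification against the 3-GDP-per-capita threshold.
#'
#' @param p A `perfuse_params` object.
#' @param dialysis_basis Passed to [summarize_strategy()].
#' @return A `cea_comparison` list: strategy summaries `mp` and `cs`, the
#'   assembled `table`, and `icers` (one [icer()] result per health outcome:
#'   `per_transplant`, `per_dialysis_avoided`, `per_death_avoided`).
#' @export
compare_strategies <- function(p, dialysis_basis = "person_years") {
  validate_params(p)
  tr_cs <- run_strategy(p, "ALL_SCS")
  tr_mp <- run_strategy(p, "HMP_FOR_ECD")
  rate <- p$econ$discount_rate
  res_cs <- summarize_strategy(tr_cs, cost_trace(tr_cs), rate,
                               dialysis_basis = dialysis_basis)
  res_mp <- summarize_strategy(tr_mp, cost_trace(tr_mp), rate,
                               dialysis_basis = dialysis_basis)
  d_cost <- res_mp$total_cost_usd - res_cs$total_cost_usd
  thr <- p$econ$threshold_3gdp_usd
  icers <- list(
    per_transplant = icer(d_cost, res_mp$transplants_total - res_cs$transplants_total, thr),
    per_dialysis_avoided = icer(d_cost, res_cs$dialysis_dependent - res_mp$dialysis_dependent, thr),
    per_death_avoided = icer(d_cost, res_cs$deaths_total - res_mp$deaths_total, thr)
  )
  structure(list(
    mp = res_mp, cs = res_cs,
    trace_mp = tr_mp, trace_cs = tr_cs,
    table = cea_table(res_mp, res_cs),
    icers = icers,
    threshold_usd = thr
  ), class = "cea_comparison")
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat("<cea_comparison> machine perfusion for ECD kidneys vs universal cold storage\n")
  print(x$table)
  cl <- x$icers$per_transplant$classification
  cat(sprintf("  per transplant gained: %s (threshold USD %.2f)\n", cl, x$threshold_usd))
  invisible(x)
}
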