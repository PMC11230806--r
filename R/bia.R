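# Five-year undiscounted budget impact of adopting machine perfusion for
# ECD kidneys.

#' Assemble a budget-impact table from yearly scenario costs
#'
#' Computes the yearly impact (proposed minus current), the five-year totals
#' of both scenarios, and the total impact. All arithmetic is exact on the
#' unrounded inputs; rounding happens only in [render_bia()].
#'
#' @param current_usd Yearly costs of the current scenario (universal static
#'   cold storage), undiscounted USD.
#' @param proposed_usd Yearly costs of the proposed scenario (machine
#'   perfusion for ECD kidneys), same length.
#' @param years Calendar labels for the rows (cosmetic).
#' @return A `bia_table` tibble with columns `year`, `current_usd`,
#'   `proposed_usd`, `impact_usd` and a final `"total"` row.
#' @export
bia_table <- function(current_usd, proposed_usd,
                      years = seq(2023, length.out = length(current_usd))) {
  stopifnot(length(current_usd) == length(proposed_usd),
            length(years) == length(current_usd))
  impact <- proposed_usd - current_usd
  out <- tibble::tibble(
    year = c(as.character(years), "total"),
    current_usd = c(current_usd, sum(current_usd)),
    proposed_usd = c(proposed_usd, sum(proposed_usd)),
    impact_usd = c(impact, sum(impact))
  )
  structure(out, class = c("bia_table", class(out)))
}

#' Run the budget impact analysis
#'
#' Runs both strategies over the horizon and tabulates their undiscounted
#' per-year total costs: the current scenario is universal static cold
#' storage, the proposed scenario preserves ECD kidneys with machine
#' perfusion. No discounting is applied anywhere in the budget impact.
#'
#' @param p A `perfuse_params` object.
#' @return A `bia_table`.
#' @export
run_bia <- function(p) {
  validate_params(p)
  tr_cs <- run_strategy(p, "ALL_SCS")
  tr_mp <- run_strategy(p, "HMP_FOR_ECD")
  cur <- cost_trace(tr_cs)$total_usd
  prop <- cost_trace(tr_mp)$total_usd
  bia_table(cur, prop,
            years = seq(p$econ$bia_start_year, length.out = p$econ$horizon_years))
}

#' Render a budget-impact table for presentation
#'
#' Rounds all monetary cells to whole USD, half away from zero — matching
#' the per-cell rounding convention of published budget-impact tables — and
#' optionally writes the result as CSV.
#'
#' @param table A `bia_table`.
#' @param path Optional CSV destination.
#' @return The rounded tibble (invisibly when `path` is given).
#' @export
render_bia <- function(table, path = NULL) {
  stopifnot(inherits(table, "bia_table"))
  out <- tibble::as_tibble(table)
  for (cn in c("current_usd", "proposed_usd", "impact_usd"))
    out[[cn]] <- round_half_away(out[[cn]])
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
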