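# One-way deterministic sensitivity analysis (tornado ordering) and
# second-order Monte Carlo probabilistic sensitivity analysis.

#' Default one-way sensitivity ranges
#'
#' Every uncertain scalar gets a low/high bound: costs, utilizations and the
#' waiting-list mortality move plus/minus 20% of base (probabilities clipped
#' to \[0, 1\], with `util_ecd_mp` floored at `util_ecd_cs` and vice versa so
#' each bound is a valid parameter set on its own); the discount rate spans
#' the 0%--10% range. All ranges can be overridden.
#'
#' @param p A `perfuse_params` object.
#' @return Named list of `c(low, high)` pairs keyed by parameter path.
#' @export
default_dsa_ranges <- function(p) {
  validate_params(p)
  tab <- psa_parameter_table()
  ranges <- list()
  for (i in seq_len(nrow(tab))) {
    path <- tab$param[i]
    base <- get_param_path(p, path)
    if (tab$family[i] == "uniform") {
      ranges[[path]] <- p$econ$discount_rate_range
    } else if (tab$family[i] == "beta") {
      lo <- max(0, base * 0.8); hi <- min(1, base * 1.2)
      if (path == "donors.util_ecd_mp") lo <- max(lo, p$donors$util_ecd_cs)
      if (path == "donors.util_ecd_cs") hi <- min(hi, p$donors$util_ecd_mp)
      ranges[[path]] <- c(lo, hi)
    } else {
      ranges[[path]] <- c(base * 0.8, base * 1.2)
    }
  }
  # donor mix: share_scd moves with share_ecd tied to 1 - share_scd
  ranges[["donors.share_scd"]] <- c(max(0, p$donors$share_scd * 0.8),
                                    min(1, p$donors$share_scd * 1.2))
  ranges
}

dsa_outcome_value <- function(cmp, outcome) {
  switch(outcome,
    icer_per_transplant = cmp$icers$per_transplant$delta_cost_usd /
      cmp$icers$per_transplant$delta_effect,
    icer_per_dialysis_avoided = cmp$icers$per_dialysis_avoided$delta_cost_usd /
      cmp$icers$per_dialysis_avoided$delta_effect,
    icer_per_death_avoided = cmp$icers$per_death_avoided$delta_cost_usd /
      cmp$icers$per_death_avoided$delta_effect,
    delta_cost = cmp$mp$total_cost_usd - cmp$cs$total_cost_usd,
    delta_transplants = cmp$mp$transplants_total - cmp$cs$transplants_total,
    stop("unknown DSA outcome: ", outcome, call. = FALSE)
  )
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the strategy comparison with each parameter at its low and high
#' bound, all others held at base, and orders parameters by the width of the
#' induced swing in the chosen outcome (the tornado-diagram ordering). The
#' ICER outcomes are reported as the signed ratio delta-cost / delta-effect
#' so dominant results remain on a continuous scale.
#'
#' @param p A `perfuse_params` object.
#' @param ranges Named list of `c(low, high)` bounds per parameter path;
#'   defaults to [default_dsa_ranges()].
#' @param outcome One of `"icer_per_transplant"` (default),
#'   `"icer_per_dialysis_avoided"`, `"icer_per_death_avoided"`,
#'   `"delta_cost"`, `"delta_transplants"`.
#' @return A `dsa_result` tibble: `param`, `low`, `high`, `outcome_low`,
#'   `outcome_high`, `width`, sorted by decreasing `width` (ties broken
#'   alphabetically by parameter path).
#' @export
one_way_dsa <- function(p, ranges = default_dsa_ranges(p),
                        outcome = "icer_per_transplant") {
  validate_params(p)
  rows <- lapply(sort(names(ranges)), function(path) {
    b <- ranges[[path]]
    if (length(b) != 2 || anyNA(b) || b[1] > b[2])
      stop("invalid bounds for parameter: ", path, call. = FALSE)
    vals <- vapply(b, function(v) {
      pv <- set_param_path(p, path, v)
      validate_params(pv)
      dsa_outcome_value(compare_strategies(pv), outcome)
    }, numeric(1))
    tibble::tibble(param = path, low = b[1], high = b[2],
                   outcome_low = vals[1], outcome_high = vals[2],
                   width = abs(vals[2] - vals[1]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width, out$param), ]
  structure(out, class = c("dsa_result", class(out)), outcome = outcome)
}

# Deterministic per-iteration seed derived from the user seed by counter,
# kept inside the 32-bit integer range R requires.
iteration_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + as.numeric(i) * 1000003) %% 2147483647)
}

sample_psa_params <- function(p, dists, max_retry = 100L) {
  for (attempt in seq_len(max_retry)) {
    cand <- p
    for (d in dists) cand <- set_param_path(cand, d$param, draw_psa_value(d))
    ok <- tryCatch({ validate_params(cand); TRUE }, error = function(e) FALSE)
    if (ok) return(cand)
  }
  stop("could not draw a valid parameter set after ", max_retry, " attempts",
       call. = FALSE)
}

#' Second-order Monte Carlo probabilistic sensitivity analysis
#'
#' For each iteration, draws one value per uncertain parameter from its
#' distribution, re-runs the full strategy comparison, and records the
#' incremental cost and the three incremental health outcomes. Draws use one
#' seeded stream per iteration (derived from `seed` by counter) with a fixed
#' parameter order, so results are bit-identical across reruns with the same
#' seed and unchanged when iterations are reordered. An iteration whose draw
#' violates parameter constraints (e.g. ECD utilization under machine
#' perfusion below the cold-storage one) is redrawn within the same stream.
#'
#' @param p Base-case `perfuse_params`.
#' @param dists Distributions from [gen_psa_distributions()].
#' @param n Number of iterations.
#' @param seed Integer seed.
#' @return A `psa_result` list: `iterations` tibble (per-iteration deltas),
#'   `param_draws` tibble (per-iteration parameter values), and `summary`
#'   (per outcome: mean signed cost-effectiveness ratio, proportion dominant,
#'   proportions below the 3-GDP and 1-GDP thresholds), plus `seed` and `n`.
#' @export
run_psa <- function(p, dists = gen_psa_distributions(p), n = p$econ$psa_iterations,
                    seed = p$econ$rng_seed) {
  validate_params(p)
  stopifnot(n >= 1)
  iter_rows <- vector("list", n)
  draw_rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(iteration_seed(seed, i))
    pi_ <- sample_psa_params(p, dists)
    cmp <- compare_strategies(pi_)
    iter_rows[[i]] <- tibble::tibble(
      iteration = i,
      delta_cost_usd = cmp$mp$total_cost_usd - cmp$cs$total_cost_usd,
      delta_transplants = cmp$mp$transplants_total - cmp$cs$transplants_total,
      delta_dialysis_avoided = cmp$cs$dialysis_dependent - cmp$mp$dialysis_dependent,
      delta_deaths_avoided = cmp$cs$deaths_total - cmp$mp$deaths_total
    )
    draw_rows[[i]] <- tibble::tibble(
      iteration = i,
      !!!setNames(lapply(dists, function(d) get_param_path(pi_, d$param)),
                  vapply(dists, `[[`, character(1), "param"))
    )
  }
  iterations <- do.call(rbind, iter_rows)
  structure(list(
    iterations = iterations,
    param_draws = do.call(rbind, draw_rows),
    summary = psa_summary(iterations, p$econ$threshold_3gdp_usd,
                          p$econ$threshold_1gdp_usd),
    threshold_3gdp_usd = p$econ$threshold_3gdp_usd,
    threshold_1gdp_usd = p$econ$threshold_1gdp_usd,
    seed = seed, n = n
  ), class = "psa_result")
}

psa_summary <- function(iterations, thr3, thr1) {
  outcomes <- c(transplants = "delta_transplants",
                dialysis_avoided = "delta_dialysis_avoided",
                deaths_avoided = "delta_deaths_avoided")
  rows <- lapply(names(outcomes), function(nm) {
    eff <- iterations[[outcomes[[nm]]]]
    cost <- iterations$delta_cost_usd
    ratio <- ifelse(eff == 0, NA_real_, cost / eff)
    cls3 <- mapply(function(dc, de) icer(dc, de, thr3)$classification, cost, eff)
    cls1 <- mapply(function(dc, de) icer(dc, de, thr1)$classification, cost, eff)
    tibble::tibble(
      outcome = nm,
      mean_ratio_usd = mean(ratio, na.rm = TRUE),
      icer_of_means_usd = mean(cost) / mean(eff),
      prop_dominant = mean(cls3 == "dominant"),
      prop_below_3gdp = mean(cls3 %in% c("dominant", "tradeoff_cost_effective")),
      prop_below_1gdp = mean(cls1 %in% c("dominant", "tradeoff_cost_effective")),
      prop_dominated = mean(cls3 == "dominated")
    )
  })
  do.call(rbind, rows)
}

#' Cost-effectiveness-plane scatter table
#'
#' One row per PSA iteration with the incremental effect, incremental cost,
#' and the quadrant/threshold classification for the chosen outcome; this is
#' the layout of the CE-plane CSV export.
#'
#' @param psa A `psa_result`.
#' @param outcome `"transplants"`, `"dialysis_avoided"`, or
#'   `"deaths_avoided"`.
#' @return A tibble with columns `iteration`, `delta_effect`,
#'   `delta_cost_usd`, `classification`.
#' @export
ce_plane_table <- function(psa, outcome = "transplants") {
  stopifnot(inherits(psa, "psa_result"))
  col <- switch(outcome,
    transplants = "delta_transplants",
    dialysis_avoided = "delta_dialysis_avoided",
    deaths_avoided = "delta_deaths_avoided",
    stop("unknown outcome: ", outcome, call. = FALSE)
  )
  it <- psa$iterations
  if (nrow(it) == 0) {
    return(tibble::tibble(iteration = integer(), delta_effect = numeric(),
                          delta_cost_usd = numeric(), classification = character()))
  }
  cls <- mapply(function(dc, de) icer(dc, de, psa$threshold_3gdp_usd)$classification,
                it$delta_cost_usd, it[[col]])
  tibble::tibble(iteration = it$iteration, delta_effect = it[[col]],
                 delta_cost_usd = it$delta_cost_usd, classification = cls)
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations, seed %d\n", x$n, x$seed))
  print(x$summary)
  invisible(x)
}
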