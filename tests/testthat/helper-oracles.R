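# Test-only oracles and fixture generators. These deliberately re-derive
# expected behaviour by independent routes (enumeration, stochastic
# individual-level simulation) rather than calling the code paths they check.

# Random but valid parameter set; populations kept at realistic scale.
make_random_params <- function(seed, horizon = 5L) {
  set.seed(seed)
  p <- default_params()
  p$econ$horizon_years <- horizon
  p$demography$initial_waitlist <- round(runif(1, 5000, 30000))
  p$demography$yearly_entrants <- round(runif(horizon, 2000, 18000))
  p$demography$yearly_transplants_comparator <- round(runif(horizon, 1000, 6000))
  p$demography$waitlist_annual_mortality <- runif(1, 0.02, 0.15)
  share_scd <- runif(1, 0.5, 0.95)
  p$donors$share_scd <- share_scd
  p$donors$share_ecd <- 1 - share_scd
  p$donors$util_scd <- runif(1, 0.6, 0.95)
  p$donors$util_ecd_cs <- runif(1, 0.3, 0.8)
  p$donors$util_ecd_mp <- runif(1, p$donors$util_ecd_cs, 0.95)
  s5 <- function(lo, hi) runif(1, lo, hi)
  scd_pat <- s5(0.85, 0.97); ecd_pat <- runif(1, 0.75, scd_pat)
  scd_gr <- s5(0.80, 0.95); ecd_gr <- runif(1, 0.70, scd_gr)
  spec <- list(family = "exponential", weibull_shape = 1,
               scd = list(survival_5y_patient = scd_pat, survival_5y_graft_censored = scd_gr),
               ecd = list(survival_5y_patient = ecd_pat, survival_5y_graft_censored = ecd_gr))
  p$survival <- gen_survival_curves(spec, horizon = horizon)
  p$costs$transplant_episode_usd <- runif(1, 4000, 15000)
  p$costs$followup_annual_usd <- runif(1, 1000, 5000)
  p$costs$hd_session_usd <- runif(1, 20, 80)
  p$costs$cold_storage_per_kidney_usd <- runif(1, 100, 600)
  p$costs$hmp_per_kidney_usd <- runif(1, 800, 4000)
  p$costs$hmp_training_annual_usd <- runif(1, 0, 200000)
  validate_params(p)
}

# Individual-level (integer-person) stochastic simulation of one strategy,
# mirroring the documented within-cycle event order but drawing every
# probabilistic transition as a Bernoulli outcome per person (aggregated
# through binomial draws, which is distributionally identical). Returns
# end-of-cycle occupancies per cycle.
microsim_strategy <- function(p, strategy) {
  H <- p$econ$horizon_years
  d <- p$demography
  wl <- round(d$initial_waitlist)
  g <- list(scd = rep(0L, H), ecd = rep(0L, H))
  dead_list <- 0L; dead_graft <- 0L
  out <- matrix(0, nrow = H, ncol = 4,
                dimnames = list(NULL, c("waitlist", "graft", "dead_on_list", "dead_with_graft")))
  for (t in seq_len(H)) {
    wl <- wl + round(d$yearly_entrants[t])
    offers <- derive_offers(d$yearly_transplants_comparator[t], p$donors)
    tx <- allocate_transplants(offers, p$donors, strategy, wl)
    tx_int <- c(scd = round(unname(tx["scd"])), ecd = round(unname(tx["ecd"])))
    if (sum(tx_int) > wl) tx_int <- floor(tx_int * wl / sum(tx_int))
    wl <- wl - sum(tx_int)
    deaths <- rbinom(1, wl, d$waitlist_annual_mortality)
    dead_list <- dead_list + deaths
    wl <- wl - deaths
    losses_total <- 0L
    for (type in c("scd", "ecd")) {
      gg <- g[[type]]
      gg[1] <- gg[1] + tx_int[[type]]
      p_death <- p$survival[[type]]$annual_death_with_graft[seq_len(H)]
      p_loss <- p$survival[[type]]$annual_graft_loss[seq_len(H)]
      dd <- rbinom(H, gg, p_death)
      ll <- rbinom(H, gg - dd, p_loss)
      remain <- gg - dd - ll
      dead_graft <- dead_graft + sum(dd)
      losses_total <- losses_total + sum(ll)
      g2 <- c(0L, remain[-H])
      g2[H] <- g2[H] + remain[H]
      g[[type]] <- g2
    }
    wl <- wl + losses_total
    out[t, ] <- c(wl, sum(g$scd) + sum(g$ecd), dead_list, dead_graft)
  }
  out
}

# Mean and standard error of microsim occupancies over replicates.
microsim_reference <- function(p, strategy, reps) {
  sims <- replicate(reps, microsim_strategy(p, strategy), simplify = "array")
  list(mean = apply(sims, c(1, 2), mean),
       se = apply(sims, c(1, 2), stats::sd) / sqrt(reps))
}

# End-of-cycle occupancies of a cohort trace, matching microsim layout.
trace_occupancies <- function(trace) {
  H <- trace$horizon
  t(vapply(seq_len(H), function(t) {
    s <- trace$states[[t + 1]]
    c(waitlist = s$waitlist,
      graft = sum(s$graft_scd) + sum(s$graft_ecd),
      dead_on_list = s$dead_on_list,
      dead_with_graft = s$dead_with_graft)
  }, numeric(4)))
}

# Independent CE-plane classifier: an explicit rule table over the signs of
# the deltas and the threshold comparison, written from the quadrant
# definitions rather than shared with icer().
classify_oracle <- function(delta_cost, delta_effect, threshold) {
  se <- sign(delta_effect); sc <- sign(delta_cost)
  if (se > 0 && sc <= 0) return("dominant")
  if (se < 0 && sc >= 0) return("dominated")
  if (se == 0) {
    if (sc > 0) return("dominated")
    if (sc < 0) return("dominant")
    return("tradeoff_cost_effective")
  }
  r <- delta_cost / delta_effect
  if (se > 0) {
    if (r <= threshold) "tradeoff_cost_effective" else "tradeoff_not_cost_effective"
  } else {
    if (r >= threshold) "tradeoff_cost_effective" else "tradeoff_not_cost_effective"
  }
}

# Three-outcome enumeration for one compartment-year under sequential
# hazards: die first with p_death, otherwise lose the graft with p_loss.
enumerate_compartment <- function(n, p_death, p_loss) {
  c(deaths = n * p_death,
    losses = n * (1 - p_death) * p_loss,
    remain = n * (1 - p_death) * (1 - p_loss))
}
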