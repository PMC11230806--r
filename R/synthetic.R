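# Synthetic stand-ins for the model inputs that are not public: per-year
# post-transplant survival probabilities by donor type, and the PSA
# uncertainty distributions. Magnitudes here are documented fixtures, not
# registry or literature values.

#' Default synthetic survival specification
#'
#' Five-year patient survival of 0.90 (SCD) / 0.85 (ECD) and death-censored
#' graft survival of 0.88 (SCD) / 0.80 (ECD), with an exponential (constant
#' annual hazard) shape. These are plausible round numbers chosen once for
#' reproducible fixtures; they are synthetic, not extracted from any
#' registry or meta-analysis.
#'
#' @param family `"exponential"` or `"weibull"`.
#' @param weibull_shape Weibull shape parameter; 1 reduces to exponential.
#' @return A survival generator specification list.
#' @export
default_survival_spec <- function(family = "exponential", weibull_shape = 1) {
  list(
    family = family,
    weibull_shape = weibull_shape,
    scd = list(survival_5y_patient = 0.90, survival_5y_graft_censored = 0.88),
    ecd = list(survival_5y_patient = 0.85, survival_5y_graft_censored = 0.80)
  )
}

validate_survival_spec <- function(spec) {
  if (!spec$family %in% c("exponential", "weibull"))
    stop("survival family must be 'exponential' or 'weibull'", call. = FALSE)
  if (spec$family == "weibull" && (!is.numeric(spec$weibull_shape) || spec$weibull_shape <= 0))
    stop("weibull_shape must be > 0", call. = FALSE)
  for (type in c("scd", "ecd")) {
    for (f in c("survival_5y_patient", "survival_5y_graft_censored")) {
      s <- spec[[type]][[f]]
      if (!is.numeric(s) || s <= 0 || s > 1)
        stop(sprintf("%s.%s must be in (0, 1]", type, f), call. = FALSE)
    }
  }
  for (f in c("survival_5y_patient", "survival_5y_graft_censored")) {
    if (spec$ecd[[f]] > spec$scd[[f]] + 1e-12)
      stop(sprintf("ECD %s must not exceed the SCD value", f), call. = FALSE)
  }
  invisible(spec)
}

# Annual conditional event probabilities whose cumulative survival hits the
# 5-year target exactly. Weibull: S(t) = exp(-lambda * t^k) with lambda
# anchored at S(5); shape 1 collapses to the exponential constant hazard.
annual_probs_from_s5 <- function(s5, horizon, shape) {
  if (s5 == 1) return(rep(0, horizon))
  lambda <- -log(s5) / 5^shape
  t <- 0:horizon
  surv <- exp(-lambda * t^shape)
  1 - surv[-1] / surv[-length(surv)]
}

#' Generate per-year post-transplant survival probabilities
#'
#' Turns five-year patient and death-censored graft survival targets into the
#' per-year conditional annual probabilities the cohort engine consumes. The
#' cumulative product of annual survival equals the five-year target exactly
#' (to floating-point precision). Patient death and graft loss are emitted as
#' separate competing annual probabilities, applied sequentially by the
#' engine (death first, then graft loss among survivors).
#'
#' @param spec A specification as returned by [default_survival_spec()].
#' @param horizon Number of post-transplant years to emit (>= model horizon).
#' @return A list with elements `scd` and `ecd`, each holding
#'   `annual_death_with_graft` and `annual_graft_loss` vectors, plus
#'   `source = "synthetic"`.
#' @examples
#' sc <- gen_survival_curves(default_survival_spec())
#' prod(1 - sc$scd$annual_death_with_graft[1:5])  # 0.90
#' @export
gen_survival_curves <- function(spec = default_survival_spec(), horizon = 5L) {
  validate_survival_spec(spec)
  shape <- if (spec$family == "exponential") 1 else spec$weibull_shape
  out <- list(source = "synthetic")
  for (type in c("scd", "ecd")) {
    death <- annual_probs_from_s5(spec[[type]]$survival_5y_patient, horizon, shape)
    loss <- annual_probs_from_s5(spec[[type]]$survival_5y_graft_censored, horizon, shape)
    if (any(death + loss > 1))
      stop(sprintf("infeasible spec: %s death + graft-loss probability exceeds 1", type),
           call. = FALSE)
    out[[type]] <- list(annual_death_with_graft = death, annual_graft_loss = loss)
  }
  out
}

# ---------------------------------------------------------------------------
# PSA distributions

# Uncertain scalar parameters, in the documented draw order used by run_psa().
psa_parameter_table <- function() {
  tibble::tribble(
    ~param,                               ~family,
    "demography.waitlist_annual_mortality", "beta",
    "donors.util_scd",                      "beta",
    "donors.util_ecd_cs",                   "beta",
    "donors.util_ecd_mp",                   "beta",
    "costs.transplant_episode_usd",         "gamma",
    "costs.followup_annual_usd",            "gamma",
    "costs.hd_session_usd",                 "gamma",
    "costs.cold_storage_per_kidney_usd",    "gamma",
    "costs.hmp_per_kidney_usd",             "gamma",
    "costs.hmp_training_annual_usd",        "gamma",
    "econ.discount_rate",                   "uniform"
  )
}

#' Generate PSA parameter distributions from a base case
#'
#' Builds one uncertainty distribution per uncertain scalar parameter:
#' beta for probabilities and gamma for costs, moment-matched so that each
#' distribution's mean equals the base-case value and its standard deviation
#' is `cv` times the mean; the discount rate gets a uniform(0, 0.10)
#' distribution reflecting the 0%--10% range explored deterministically.
#' With `cv = 0` all distributions are degenerate at the base values, which
#' makes the PSA collapse onto the deterministic result.
#'
#' @param base A `perfuse_params` object supplying the means.
#' @param cv Coefficient of variation (sd / mean), `0 <= cv < 1`.
#' @return A `psa_dists` object: a named list of distribution descriptors
#'   with elements `param`, `family`, and the family's parameters.
#' @examples
#' d <- gen_psa_distributions(default_params(), cv = 0.1)
#' d[["donors.util_ecd_cs"]]
#' @export
gen_psa_distributions <- function(base, cv = 0.1) {
  validate_params(base)
  if (!is.numeric(cv) || cv < 0 || cv >= 1)
    stop("cv must satisfy 0 <= cv < 1", call. = FALSE)
  tab <- psa_parameter_table()
  dists <- vector("list", nrow(tab))
  names(dists) <- tab$param
  for (i in seq_len(nrow(tab))) {
    param <- tab$param[i]
    family <- tab$family[i]
    m <- get_param_path(base, param)
    d <- list(param = param, family = family, mean = m)
    if (family == "uniform") {
      rng <- base$econ$discount_rate_range
      d$min <- rng[1]; d$max <- rng[2]
      d$mean <- mean(rng)
    } else if (cv == 0 || m == 0) {
      d$family <- "degenerate"
    } else if (family == "beta") {
      s <- cv * m
      nu <- m * (1 - m) / s^2 - 1
      if (nu <= 0)
        stop(sprintf("beta moment-matching infeasible for `%s` (mean %.4g, sd %.4g)",
                     param, m, s), call. = FALSE)
      d$shape1 <- m * nu
      d$shape2 <- (1 - m) * nu
    } else { # gamma
      d$shape <- 1 / cv^2
      d$rate <- d$shape / m
    }
    dists[[i]] <- d
  }
  structure(dists, class = "psa_dists")
}

# One draw from a distribution descriptor.
draw_psa_value <- function(d) {
  switch(d$family,
    degenerate = d$mean,
    beta = rbeta(1, d$shape1, d$shape2),
    gamma = rgamma(1, shape = d$shape, rate = d$rate),
    uniform = runif(1, d$min, d$max),
    stop("unknown distribution family: ", d$family, call. = FALSE)
  )
}

#' Theoretical mean and standard deviation of a PSA distribution
#'
#' @param d A single distribution descriptor from [gen_psa_distributions()].
#' @return Named numeric vector with elements `mean` and `sd`.
#' @export
psa_dist_moments <- function(d) {
  switch(d$family,
    degenerate = c(mean = d$mean, sd = 0),
    beta = {
      a <- d$shape1; b <- d$shape2
      c(mean = a / (a + b), sd = sqrt(a * b / ((a + b)^2 * (a + b + 1))))
    },
    gamma = c(mean = d$shape / d$rate, sd = sqrt(d$shape) / d$rate),
    uniform = c(mean = (d$min + d$max) / 2, sd = (d$max - d$min) / sqrt(12)),
    stop("unknown distribution family: ", d$family, call. = FALSE)
  )
}
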