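# Parameter containers, validation, defaults, and YAML/JSON configuration I/O.

#' Build donor mix and utilization parameters from raw activity counts
#'
#' Converts yearly organ-recovery and transplant counts for a donor service
#' area into the proportions the cohort model consumes: the share of recovered
#' kidneys coming from standard (SCD) versus expanded criteria (ECD) donors,
#' and the utilization probability (transplanted / offered) for each donor
#' type under static cold storage.
#'
#' @param recovered_scd,recovered_ecd Number of kidneys recovered from SCD and
#'   ECD donors.
#' @param transplanted_scd,transplanted_ecd Number of those kidneys actually
#'   transplanted under static cold storage.
#' @param util_ecd_mp Assumed ECD utilization probability once machine
#'   perfusion is adopted. Defaults to the SCD utilization computed from the
#'   counts (the "perfused ECD kidneys are used like SCD kidneys" assumption).
#' @return A list with elements `share_scd`, `share_ecd`, `util_scd`,
#'   `util_ecd_cs`, `util_ecd_mp`.
#' @examples
#' donor_mix_from_counts(1279, 307, 1127, 191)
#' @export
donor_mix_from_counts <- function(recovered_scd, recovered_ecd,
                                  transplanted_scd, transplanted_ecd,
                                  util_ecd_mp = NULL) {
  stopifnot(recovered_scd > 0, recovered_ecd > 0,
            transplanted_scd >= 0, transplanted_ecd >= 0)
  total <- recovered_scd + recovered_ecd
  util_scd <- transplanted_scd / recovered_scd
  out <- list(
    share_scd   = recovered_scd / total,
    share_ecd   = recovered_ecd / total,
    util_scd    = util_scd,
    util_ecd_cs = transplanted_ecd / recovered_ecd,
    util_ecd_mp = if (is.null(util_ecd_mp)) util_scd else util_ecd_mp
  )
  out
}

#' Base-case model parameters
#'
#' Returns the complete parameter set for the base case: the December-2021
#' Brazilian deceased-donor kidney waiting list (27 613 patients), the
#' five-year forecasts of waiting-list entrants and comparator transplant
#' counts, the Sao Paulo donor mix (81% SCD / 19% ECD) with utilization
#' probabilities 0.88 (SCD), 0.62 (ECD under cold storage) and 0.88 (ECD under
#' machine perfusion), an annual waiting-list mortality of 8.08%, unit costs
#' in USD (8254.39 per transplant episode, 2715.60 per graft-year of
#' follow-up, 40.53 per hemodialysis session at 156 sessions/year), a 5%
#' annual discount rate and a willingness-to-pay threshold of USD 19 570.52
#' (3 GDP per capita).
#'
#' Post-transplant survival curves and preservation/machine-perfusion costs
#' are not public inputs; the defaults for those fields are synthetic
#' stand-ins generated by [gen_survival_curves()] and flagged with
#' `source = "synthetic"` so they cannot be mistaken for registry values.
#'
#' @return A validated `perfuse_params` object (a named list with components
#'   `demography`, `donors`, `survival`, `costs`, `econ`).
#' @seealso [load_params()], [save_params()], [validate_params()]
#' @examples
#' p <- default_params()
#' p$demography$initial_waitlist
#' @export
default_params <- function() {
  survival <- gen_survival_curves(default_survival_spec(), horizon = 5L)
  p <- structure(list(
    demography = list(
      initial_waitlist = 27613,
      yearly_entrants = c(9949, 16132, 10913, 17096, 11877),
      yearly_transplants_comparator = c(4994, 5117, 5242, 5370, 5502),
      waitlist_annual_mortality = 0.0808,
      background_mortality = 0,
      apply_background_to_graft = FALSE
    ),
    donors = list(
      share_scd = 0.81,
      share_ecd = 0.19,
      util_scd = 0.88,
      util_ecd_cs = 0.62,
      util_ecd_mp = 0.88
    ),
    survival = survival,
    costs = list(
      transplant_episode_usd = 8254.39,
      followup_annual_usd = 2715.60,
      hd_session_usd = 40.53,
      hd_sessions_per_year = 156,
      cold_storage_per_kidney_usd = 250,
      hmp_per_kidney_usd = 1800,
      hmp_training_annual_usd = 50000,
      fx_brl_per_usd = 5.39,
      preservation_source = "synthetic"
    ),
    econ = list(
      horizon_years = 5L,
      discount_rate = 0.05,
      discount_rate_range = c(0, 0.10),
      threshold_3gdp_usd = 19570.52,
      threshold_1gdp_usd = 19570.52 / 3,
      psa_iterations = 1000L,
      rng_seed = 1L,
      discount_outcomes = FALSE,
      bia_start_year = 2023L
    )
  ), class = "perfuse_params")
  validate_params(p)
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the parameter object: positive
#' waiting list, non-negative entrant/transplant counts with length equal to
#' the horizon, probabilities in \[0, 1\], donor shares summing to one,
#' machine-perfusion ECD utilization at least the cold-storage one,
#' per-year post-transplant death + graft-loss probability at most one,
#' non-negative costs, and a positive exchange rate.
#'
#' @param p A `perfuse_params` object (or plain list with the same shape).
#' @return `p` invisibly cast to `perfuse_params`, or an error naming the
#'   offending field.
#' @export
validate_params <- function(p) {
  fail <- function(field, msg) {
    stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
  }
  chk_prob <- function(x, field) {
    if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
      fail(field, "must be a probability in [0, 1]")
  }
  d <- p$demography; dn <- p$donors; sv <- p$survival; cs <- p$costs; ec <- p$econ
  H <- ec$horizon_years
  if (!is.numeric(H) || H < 1) fail("econ.horizon_years", "must be >= 1")
  if (!is.numeric(d$initial_waitlist) || d$initial_waitlist <= 0)
    fail("demography.initial_waitlist", "must be > 0")
  if (length(d$yearly_entrants) != H)
    fail("demography.yearly_entrants", sprintf("must have length %d (the horizon)", H))
  if (length(d$yearly_transplants_comparator) != H)
    fail("demography.yearly_transplants_comparator",
         sprintf("must have length %d (the horizon)", H))
  if (any(d$yearly_entrants < 0)) fail("demography.yearly_entrants", "must be >= 0")
  if (any(d$yearly_transplants_comparator < 0))
    fail("demography.yearly_transplants_comparator", "must be >= 0")
  chk_prob(d$waitlist_annual_mortality, "demography.waitlist_annual_mortality")
  chk_prob(d$background_mortality, "demography.background_mortality")
  if (abs(dn$share_scd + dn$share_ecd - 1) > 1e-9)
    fail("donors.share_scd", "share_scd + share_ecd must equal 1")
  chk_prob(dn$share_scd, "donors.share_scd")
  for (f in c("util_scd", "util_ecd_cs", "util_ecd_mp"))
    chk_prob(dn[[f]], paste0("donors.", f))
  if (dn$util_ecd_mp < dn$util_ecd_cs)
    fail("donors.util_ecd_mp", "must be >= util_ecd_cs")
  for (type in c("scd", "ecd")) {
    death <- sv[[type]]$annual_death_with_graft
    loss <- sv[[type]]$annual_graft_loss
    fd <- sprintf("survival.%s.annual_death_with_graft", type)
    fl <- sprintf("survival.%s.annual_graft_loss", type)
    if (length(death) < H) fail(fd, sprintf("needs >= %d annual probabilities", H))
    if (length(loss) < H) fail(fl, sprintf("needs >= %d annual probabilities", H))
    chk_prob(death, fd)
    chk_prob(loss, fl)
    extra <- if (isTRUE(d$apply_background_to_graft)) d$background_mortality else 0
    if (any(death[seq_len(H)] + extra + loss[seq_len(H)] > 1 + 1e-12))
      fail(fd, "death + graft-loss probability exceeds 1 in some year")
  }
  cost_fields <- c("transplant_episode_usd", "followup_annual_usd", "hd_session_usd",
                   "hd_sessions_per_year", "cold_storage_per_kidney_usd",
                   "hmp_per_kidney_usd", "hmp_training_annual_usd")
  for (f in cost_fields) {
    if (!is.numeric(cs[[f]]) || length(cs[[f]]) != 1 || is.na(cs[[f]]) || cs[[f]] < 0)
      fail(paste0("costs.", f), "must be a single cost >= 0")
  }
  if (!is.numeric(cs$fx_brl_per_usd) || cs$fx_brl_per_usd <= 0)
    fail("costs.fx_brl_per_usd", "must be > 0")
  chk_prob(ec$discount_rate, "econ.discount_rate")
  if (any(ec$discount_rate_range < 0) || length(ec$discount_rate_range) != 2)
    fail("econ.discount_rate_range", "must be two non-negative rates")
  if (ec$threshold_3gdp_usd <= 0) fail("econ.threshold_3gdp_usd", "must be > 0")
  if (ec$threshold_1gdp_usd <= 0) fail("econ.threshold_1gdp_usd", "must be > 0")
  if (ec$psa_iterations < 1) fail("econ.psa_iterations", "must be >= 1")
  if (!inherits(p, "perfuse_params")) class(p) <- c("perfuse_params", class(p))
  invisible(p)
}

#' @export
print.perfuse_params <- function(x, ...) {
  d <- x$demography; dn <- x$donors; ec <- x$econ
  cat("<perfuse_params>\n")
  cat(sprintf("  horizon: %d y, discount %.1f%%/y, waitlist %s, mortality %.2f%%/y\n",
              ec$horizon_years, 100 * ec$discount_rate,
              format(d$initial_waitlist, big.mark = " "),
              100 * d$waitlist_annual_mortality))
  cat(sprintf("  donors: %.0f%% SCD / %.0f%% ECD; utilization SCD %.0f%%, ECD %.0f%% (SCS) -> %.0f%% (HMP)\n",
              100 * dn$share_scd, 100 * dn$share_ecd, 100 * dn$util_scd,
              100 * dn$util_ecd_cs, 100 * dn$util_ecd_mp))
  cat(sprintf("  survival curves: %s; preservation costs: %s\n",
              x$survival$source %||% "config", x$costs$preservation_source %||% "config"))
  invisible(x)
}

# Recursively check that `cfg` introduces no keys absent from the reference
# structure, then merge it over the reference. Leaf values in cfg replace
# defaults wholesale (vectors included).
merge_config <- function(ref, cfg, path = character()) {
  if (!is.list(cfg)) return(cfg)
  extra <- setdiff(names(cfg), c(names(ref), brl_aliases(names(ref))))
  if (length(extra) > 0) {
    stop(sprintf("unknown configuration key: %s",
                 paste(c(path, extra[1]), collapse = ".")), call. = FALSE)
  }
  for (k in names(cfg)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
      ref[[k]] <- merge_config(ref[[k]], cfg[[k]], c(path, k))
    } else {
      ref[[k]] <- cfg[[k]]
    }
  }
  ref
}

brl_aliases <- function(nms) sub("_usd$", "_brl", nms[grepl("_usd$", nms)])

# Costs may be given in BRL using a `_brl` key suffix; convert once at load
# using the configured exchange rate.
convert_brl <- function(costs) {
  fx <- costs$fx_brl_per_usd %||% 5.39
  brl_keys <- grep("_brl$", names(costs), value = TRUE)
  for (k in brl_keys) {
    usd <- sub("_brl$", "_usd", k)
    costs[[usd]] <- costs[[k]] / fx
    costs[[k]] <- NULL
  }
  costs
}

#' Load model parameters from a YAML or JSON configuration file
#'
#' The configuration mirrors the structure of [default_params()]; any field
#' left unspecified keeps its base-case default. Unknown keys are rejected so
#' typos cannot silently fall back to defaults. Cost fields may be supplied in
#' Brazilian reais with a `_brl` suffix (e.g. `hd_session_brl`); they are
#' converted to USD once at load time using `costs.fx_brl_per_usd`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated `perfuse_params` object.
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    "yaml" = , "yml" = yaml::read_yaml(path),
    "json" = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported configuration format: .", ext, call. = FALSE)
  )
  if (!is.list(cfg)) stop("malformed configuration file: ", path, call. = FALSE)
  p <- unclass(default_params())
  p <- merge_config(p, cfg)
  p$costs <- convert_brl(p$costs)
  p$econ$horizon_years <- as.integer(p$econ$horizon_years)
  class(p) <- "perfuse_params"
  validate_params(p)
  p
}

#' Write model parameters to a configuration file
#'
#' Serializes a parameter object to YAML (or JSON, by extension) with sorted
#' keys at every level so that identical parameter sets always produce
#' byte-identical files.
#'
#' @param p A `perfuse_params` object.
#' @param path Destination file; format chosen by extension.
#' @return `path`, invisibly.
#' @export
save_params <- function(p, path) {
  validate_params(p)
  sort_rec <- function(x) {
    if (is.list(x) && !is.null(names(x))) {
      x <- x[order(names(x))]
      lapply(x, sort_rec)
    } else x
  }
  x <- sort_rec(unclass(p))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path, precision = 15)
  }
  invisible(path)
}

# Flat "section.field" access used by the sensitivity analyses.
get_param_path <- function(p, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  x <- p
  for (k in parts) {
    if (is.null(x[[k]])) stop("unknown parameter: ", path, call. = FALSE)
    x <- x[[k]]
  }
  x
}

set_param_path <- function(p, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  get_param_path(p, path)  # existence check
  p[[parts]] <- value
  # donor shares are complementary: moving one moves the other
  if (path == "donors.share_scd") p$donors$share_ecd <- 1 - value
  if (path == "donors.share_ecd") p$donors$share_scd <- 1 - value
  p
}
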