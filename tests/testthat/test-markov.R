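test_that("offer derivation inverts the comparator utilization identity", {
  dn <- default_params()$donors
  offers <- derive_offers(4994, dn)
  expect_equal(unname(sum(offers)), 6012.6, tolerance = 1e-4)
  expect_equal(unname(offers["ecd"]), 1142.4, tolerance = 1e-4)
  # the comparator recomputes the forecast count exactly
  tx <- allocate_transplants(offers, dn, "ALL_SCS", waitlist = 1e9)
  expect_equal(unname(sum(tx)), 4994, tolerance = 1e-6)

  expect_equal(unname(derive_offers(0, dn)), c(0, 0))
  sym <- list(share_scd = 0.5, share_ecd = 0.5, util_scd = 1,
              util_ecd_cs = 1, util_ecd_mp = 1)
  expect_equal(derive_offers(100, sym), c(scd = 50, ecd = 50))
  bad <- list(share_scd = 0.5, share_ecd = 0.5, util_scd = 0,
              util_ecd_cs = 0, util_ecd_mp = 0)
  expect_error(derive_offers(1, bad), "zero")
})

test_that("allocation applies strategy utilizations and the waitlist cap", {
  dn <- default_params()$donors
  offers <- c(scd = 4870.2, ecd = 1142.4)
  tx_cs <- allocate_transplants(offers, dn, "ALL_SCS", 1e9)
  expect_equal(unname(tx_cs["scd"]), 4285.8, tolerance = 1e-3)
  expect_equal(unname(tx_cs["ecd"]), 708.3, tolerance = 0.02)
  tx_mp <- allocate_transplants(offers, dn, "HMP_FOR_ECD", 1e9)
  expect_equal(unname(tx_mp["ecd"]), 1142.4 * 0.88, tolerance = 1e-9)
  expect_equal(unname(tx_mp["ecd"] - tx_cs["ecd"]),
               (0.88 - 0.62) * 1142.4, tolerance = 1e-9)
  # an empty waiting list receives nothing; a binding cap scales proportionally
  expect_equal(unname(allocate_transplants(offers, dn, "ALL_SCS", 0)), c(0, 0))
  capped <- allocate_transplants(offers, dn, "ALL_SCS", 1000)
  expect_equal(unname(sum(capped)), 1000, tolerance = 1e-9)
  expect_equal(unname(capped["scd"] / capped["ecd"]),
               unname(tx_cs["scd"] / tx_cs["ecd"]), tolerance = 1e-9)
})

null_params <- function() {
  # no entrants, no offers, no mortality: the cycle must be an identity
  p <- default_params()
  p$demography$yearly_entrants <- rep(0, 5)
  p$demography$yearly_transplants_comparator <- rep(0, 5)
  p$demography$waitlist_annual_mortality <- 0
  p$survival <- gen_survival_curves(list(
    family = "exponential", weibull_shape = 1,
    scd = list(survival_5y_patient = 1, survival_5y_graft_censored = 1),
    ecd = list(survival_5y_patient = 1, survival_5y_graft_censored = 1)))
  validate_params(p)
}

test_that("a cycle with no events leaves the state unchanged", {
  p <- null_params()
  s0 <- perfuseCE:::new_cohort_state(p)
  s0$graft_scd[2] <- 50
  stp <- step_cohort(s0, p, "ALL_SCS", 1)
  expect_equal(stp$state$waitlist, s0$waitlist)
  expect_equal(sum(stp$state$graft_scd), 50)  # advanced but conserved
  expect_equal(stp$state$dead_on_list, 0)
  expect_equal(stp$state$dead_with_graft, 0)
})

test_that("waitlist mortality applies the printed 8.08% annual probability", {
  p <- null_params()
  p$demography$initial_waitlist <- 100
  p$demography$waitlist_annual_mortality <- 0.0808
  stp <- step_cohort(perfuseCE:::new_cohort_state(p), p, "ALL_SCS", 1)
  expect_equal(stp$state$waitlist, 91.92)
  expect_equal(stp$state$dead_on_list, 8.08)
})

test_that("graft compartments follow sequential-hazard arithmetic", {
  p <- null_params()
  p$survival$scd$annual_death_with_graft <- rep(0.1, 5)
  p$survival$scd$annual_graft_loss <- rep(0.05, 5)
  s0 <- perfuseCE:::new_cohort_state(p)
  s0$waitlist <- 0
  s0$graft_scd[1] <- 100
  stp <- step_cohort(s0, p, "ALL_SCS", 1)
  oracle <- enumerate_compartment(100, 0.1, 0.05)
  expect_equal(stp$state$dead_with_graft, unname(oracle["deaths"]))
  expect_equal(stp$state$waitlist, unname(oracle["losses"]))  # returned to list
  expect_equal(sum(stp$state$graft_scd), unname(oracle["remain"]))
  expect_equal(stp$events$graft_losses, 4.5)
  expect_equal(sum(stp$state$graft_scd), 85.5)
})

test_that("the comparator reproduces the forecast transplant counts exactly", {
  p <- default_params()
  tr <- run_strategy(p, "ALL_SCS")
  tx <- vapply(tr$events, function(e) e$transplants_scd + e$transplants_ecd,
               numeric(1))
  expect_equal(tx, p$demography$yearly_transplants_comparator, tolerance = 1e-9)
})

test_that("population is conserved at every cycle for random parameter sets", {
  for (seed in 1:100) {
    p <- make_random_params(seed)
    strat <- if (seed %% 2 == 0) "ALL_SCS" else "HMP_FOR_ECD"
    tr <- run_strategy(p, strat)
    expect_lt(max(abs(conservation_error(tr))), 1e-6)
    for (s in tr$states) {
      expect_true(s$waitlist >= 0 && all(s$graft_scd >= 0) &&
                  all(s$graft_ecd >= 0) && s$dead_on_list >= 0 &&
                  s$dead_with_graft >= 0)
    }
  }
})

test_that("transplants never exceed offers times utilization", {
  for (seed in c(3, 17, 42)) {
    p <- make_random_params(seed)
    for (strat in strategy_ids()) {
      tr <- run_strategy(p, strat)
      u_ecd <- if (strat == "HMP_FOR_ECD") p$donors$util_ecd_mp else p$donors$util_ecd_cs
      for (e in tr$events) {
        expect_lte(e$transplants_scd, e$offers_scd * p$donors$util_scd + 1e-9)
        expect_lte(e$transplants_ecd, e$offers_ecd * u_ecd + 1e-9)
      }
    }
  }
})

cumulative_tx <- function(tr) {
  sum(vapply(tr$events, function(e) e$transplants_scd + e$transplants_ecd,
             numeric(1)))
}

test_that("raising perfused-ECD utilization helps monotonically", {
  p <- make_random_params(7)
  p$donors$util_ecd_cs <- 0.5
  grid <- seq(0.5, 0.95, by = 0.05)
  tx <- deaths <- numeric(length(grid))
  for (i in seq_along(grid)) {
    p$donors$util_ecd_mp <- grid[i]
    tr <- run_strategy(p, "HMP_FOR_ECD")
    tx[i] <- cumulative_tx(tr)
    deaths[i] <- tr$states[[tr$horizon + 1]]$dead_on_list
  }
  expect_true(all(diff(tx) >= -1e-9))
  expect_true(all(diff(deaths) <= 1e-9))
})

test_that("equal ECD utilizations make the strategies coincide", {
  p <- default_params()
  p$donors$util_ecd_mp <- p$donors$util_ecd_cs
  t1 <- trace_table(run_strategy(p, "ALL_SCS"))
  t2 <- trace_table(run_strategy(p, "HMP_FOR_ECD"))
  expect_equal(t1, t2, tolerance = 1e-12)
})

test_that("cumulative transplants respect the supply of candidates", {
  p <- make_random_params(11)
  p$demography$yearly_entrants <- rep(0, 5)
  p$demography$yearly_transplants_comparator <- rep(1e6, 5)  # unlimited offers
  tr <- run_strategy(p, "HMP_FOR_ECD")
  returns <- sum(vapply(tr$events, `[[`, numeric(1), "graft_losses"))
  expect_lte(cumulative_tx(tr),
             p$demography$initial_waitlist + returns + 1e-6)
})

test_that("cohort expectations match an individual-level stochastic oracle", {
  set.seed(2024)
  reps <- 24
  for (seed in 1:5) {
    p <- make_random_params(seed + 500)
    strat <- if (seed %% 2 == 0) "ALL_SCS" else "HMP_FOR_ECD"
    ref <- microsim_reference(p, strat, reps)
    coh <- trace_occupancies(run_strategy(p, strat))
    # 3 Monte Carlo standard errors, plus 3 persons for the integerized
    # transplant allocation the individual-level simulation requires
    tol <- 3 * ref$se + 3
    expect_true(all(abs(coh - ref$mean) <= tol),
                info = sprintf("seed %d strategy %s", seed, strat))
  }
})
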