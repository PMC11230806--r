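test_that("comparator transplant total equals the forecast five-year sum", {
  p <- default_params()
  tr <- run_strategy(p, "ALL_SCS")
  res <- summarize_strategy(tr, cost_trace(tr), discount_outcomes = FALSE)
  expect_equal(res$transplants_total, 26225, tolerance = 1e-9)
  expect_equal(res$transplants_total,
               sum(p$demography$yearly_transplants_comparator))
})

test_that("outcome discounting is a no-op at rate zero", {
  p <- default_params()
  tr <- run_strategy(p, "HMP_FOR_ECD")
  ct <- cost_trace(tr)
  a <- summarize_strategy(tr, ct, rate = 0, discount_outcomes = FALSE)
  b <- summarize_strategy(tr, ct, rate = 0, discount_outcomes = TRUE)
  for (f in c("transplants_total", "deaths_total", "dialysis_dependent",
              "patients_alive", "total_cost_usd"))
    expect_equal(a[[f]], b[[f]], tolerance = 1e-9)
})

test_that("dialysis-dependence bases behave as documented", {
  p <- default_params()
  tr <- run_strategy(p, "ALL_SCS")
  ct <- cost_trace(tr)
  py <- summarize_strategy(tr, ct, dialysis_basis = "person_years")
  hc <- summarize_strategy(tr, ct, dialysis_basis = "headcount")
  expect_equal(hc$dialysis_dependent, tr$states[[tr$horizon + 1]]$waitlist)
  expect_gt(py$dialysis_dependent, hc$dialysis_dependent)  # 5 years of exposure
})

test_that("quadrant classification agrees with the enumeration oracle", {
  cases <- expand.grid(dc = c(-100, 0, 100), de = c(-10, 0, 10),
                       thr = c(5, 10, 20))
  for (i in seq_len(nrow(cases))) {
    r <- icer(cases$dc[i], cases$de[i], cases$thr[i])
    expect_identical(r$classification,
                     classify_oracle(cases$dc[i], cases$de[i], cases$thr[i]),
                     info = sprintf("dc=%g de=%g thr=%g",
                                    cases$dc[i], cases$de[i], cases$thr[i]))
  }
  # random magnitudes, same agreement
  set.seed(5)
  for (i in 1:200) {
    dc <- runif(1, -1e6, 1e6); de <- runif(1, -50, 50); thr <- runif(1, 1, 1e5)
    expect_identical(icer(dc, de, thr)$classification,
                     classify_oracle(dc, de, thr))
  }
})

test_that("ICER reproduces the published incremental arithmetic", {
  r <- icer(4486009, 815, 19570.52)
  expect_equal(r$ratio_usd_per_unit, 5504.30, tolerance = 1e-5)
  expect_identical(r$classification, "tradeoff_cost_effective")
  expect_identical(icer(-1, 1)$classification, "dominant")
  expect_true(is.na(icer(-1, 1)$ratio_usd_per_unit))
  expect_identical(icer(0, 0)$classification, "tradeoff_cost_effective")
  expect_true(is.na(icer(0, 0)$ratio_usd_per_unit))
})

test_that("the ICER ratio is invariant to common rescaling of the deltas", {
  r1 <- icer(4486009, 815, 19570.52)
  r2 <- icer(4486009 * 3.7, 815 * 3.7, 19570.52)
  expect_equal(r1$ratio_usd_per_unit, r2$ratio_usd_per_unit)
  expect_identical(r1$classification, r2$classification)
})

test_that("the results assembler reproduces the published difference columns", {
  mp <- structure(list(patients_alive = 54311, transplants_total = 20008,
                       dialysis_dependent = 36445, total_cost_usd = 1570902471),
                  class = "strategy_result")
  cs <- structure(list(patients_alive = 54191, transplants_total = 18884,
                       dialysis_dependent = 37260, total_cost_usd = 1566416462),
                  class = "strategy_result")
  tab <- cea_table(mp, cs)
  expect_equal(tab$difference[tab$outcome == "patients_alive"], 120)
  expect_equal(tab$difference[tab$outcome == "dialysis_dependent"], 815)
  expect_equal(tab$difference[tab$outcome == "total_cost_usd"], 4486009)
  expect_equal(tab$icer_usd[tab$outcome == "dialysis_dependent"],
               4486009 / 815, tolerance = 1e-9)
  expect_equal(tab$icer_usd[tab$outcome == "patients_alive"],
               4486009 / 120, tolerance = 1e-9)
})

test_that("equal utilizations collapse every incremental delta to zero", {
  p <- default_params()
  p$donors$util_ecd_mp <- p$donors$util_ecd_cs
  cmp <- compare_strategies(p)
  # health-outcome deltas vanish; the cost delta is exactly the ECD
  # preservation premium (perfusion consumables + training), nothing else
  expect_equal(cmp$table$difference[1:3], rep(0, 3), tolerance = 1e-6)
  ct_cs <- cost_trace(cmp$trace_cs)
  ct_mp <- cost_trace(cmp$trace_mp)
  premium <- sum(discount_series(ct_mp$preservation_usd - ct_cs$preservation_usd,
                                 p$econ$discount_rate))
  expect_equal(cmp$table$difference[4], premium, tolerance = 1e-6)
  # with perfusion priced like cold storage the strategies fully coincide
  p$costs$hmp_per_kidney_usd <- p$costs$cold_storage_per_kidney_usd
  p$costs$hmp_training_annual_usd <- 0
  cmp2 <- compare_strategies(p)
  expect_equal(cmp2$table$difference, rep(0, 4), tolerance = 1e-6)
})

test_that("machine perfusion raises transplants and lowers waitlist deaths", {
  cmp <- compare_strategies(default_params())
  expect_gt(cmp$mp$transplants_total, cmp$cs$transplants_total)
  expect_lt(cmp$mp$deaths_on_list, cmp$cs$deaths_on_list)
  expect_lt(cmp$mp$deaths_total, cmp$cs$deaths_total)
  expect_lt(cmp$mp$dialysis_dependent, cmp$cs$dialysis_dependent)
})
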