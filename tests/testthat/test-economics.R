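params <- base_params()
conv <- calibrated_convention()

test_that("zero prevalence reduces standard care to the healthy stream", {
  p <- set_parameter(params, "pdac_incidence", 0)
  suppressWarnings(out <- strategy_outcome(p, "standard_care"))
  expect_equal(out$cost_per_person, 0)
  healthy <- oracle_stage(0.86, 1e9, 0, reward = "start",
                          dstart = "cycle1")
  expect_close(out$qalys_per_person, healthy$qalys)
})

test_that("standard-care PDAC component matches the mixture oracle", {
  lump <- accrual_convention(cost_timing = "lump_sum")
  out <- strategy_outcome(params, "standard_care", lump)
  prev <- 0.01
  mix <- mixture_outcome(params, "standard", lump)
  healthy <- oracle_stage(0.86, 1e9, 0)
  expect_close(out$cost_per_person, prev * (3087 + 30543.25))
  expect_close(out$qalys_per_person,
               prev * mix$qalys + (1 - prev) * healthy$qalys)
})

test_that("detected fractions follow the cascade arithmetic", {
  expect_close(strategy_outcome(params, "cancer_specific")$detected_fraction,
               0.01 * 0.32)
  expect_close(strategy_outcome(params, "t3cd")$detected_fraction,
               0.01 * 0.80)
  expect_close(strategy_outcome(params, "combination")$detected_fraction,
               0.01 * 0.80 * 0.32)
})

test_that("incremental comparison implements ICER, NMB and dominance", {
  # published increments: pure ratio arithmetic on given deltas
  mk <- function(cost, qalys, strategy = "a") {
    tibble::tibble(strategy = strategy, cost_per_person = cost,
                   qalys_per_person = qalys, life_years_per_person = qalys)
  }
  ref <- mk(0, 0, "standard_care")
  ce <- compare_outcomes(mk(165.88, 0.00231), ref, wtp = 30000)
  expect_equal(ce$icer, 165.88 / 0.00231, tolerance = 1e-9)
  expect_equal(ce$icer, 71810, tolerance = 1e-4)
  expect_false(ce$cost_effective)
  ce2 <- compare_outcomes(mk(63.16, 0.00185), ref, wtp = 30000)
  expect_equal(ce2$icer, 34141, tolerance = 1e-4)
  expect_false(ce2$cost_effective)

  dom <- compare_outcomes(mk(-10, 0.01), ref, wtp = 30000)
  expect_identical(dom$dominance, "intervention_dominant")
  expect_true(dom$cost_effective)
  dominated <- compare_outcomes(mk(10, -0.01), ref, wtp = 30000)
  expect_identical(dominated$dominance, "intervention_dominated")
  eqv <- compare_outcomes(mk(0, 0), ref, wtp = 30000)
  expect_identical(eqv$dominance, "equivalent")
  expect_true(is.na(eqv$icer))
  pricey <- compare_outcomes(mk(10, 0), ref, wtp = 30000)
  expect_identical(pricey$dominance, "intervention_dominated")
  expect_true(is.na(pricey$icer))
})

test_that("NMB sign agrees with the ICER-threshold comparison", {
  for (s in c("cancer_specific", "t3cd", "combination")) {
    for (wtp in c(10000, 30000, 50000, 80000)) {
      ce <- cost_effectiveness(params, s, conv, wtp = wtp)
      expect_gt(ce$delta_qalys, 0)
      expect_identical(ce$nmb > 0, ce$icer < wtp)
    }
  }
})

test_that("outcomes are per-person and invariant to population size", {
  vp <- params_to_vector(params)
  vp["population_size"] <- 1e7
  big <- params_from_vector(vp, params$ranges)
  for (s in c("standard_care", "combination")) {
    expect_equal(strategy_outcome(big, s, conv),
                 strategy_outcome(params, s, conv))
  }
})

test_that("healthy stream cancels exactly between arms", {
  # changing only the healthy utility must leave every increment untouched
  p2 <- set_parameter(params, "utility_healthy", 0.5)
  for (s in c("cancer_specific", "t3cd", "combination")) {
    a <- cost_effectiveness(params, s, conv)
    b <- cost_effectiveness(p2, s, conv)
    expect_equal(a$delta_qalys, b$delta_qalys, tolerance = 1e-12)
    expect_equal(a$delta_cost, b$delta_cost, tolerance = 1e-12)
  }
})

test_that("equal distributions and costs force zero incremental QALYs", {
  v <- params_to_vector(params)
  for (st in c("resectable", "borderline_resectable", "locally_advanced",
               "metastatic")) {
    v[paste0("dist_biomarker_", st)] <- v[paste0("dist_standard_", st)]
    v[paste0("treatment_cost_biomarker_", st)] <-
      v[paste0("treatment_cost_standard_", st)]
  }
  p <- params_from_vector(v, params$ranges)
  for (s in c("cancer_specific", "t3cd", "combination")) {
    ce <- cost_effectiveness(p, s, conv)
    expect_equal(ce$delta_qalys, 0, tolerance = 1e-12)
    expect_gt(ce$delta_cost, 0)  # tests and work-up still cost money
  }
})

test_that("zero-sensitivity screening differs only by test and work-up costs", {
  p <- set_parameter(params, "cancer_sensitivity", 0)
  ce <- cost_effectiveness(p, "cancer_specific", conv)
  expect_equal(ce$delta_qalys, 0, tolerance = 1e-12)
  pos <- 0.99 * 0.05  # only false positives remain
  expect_close(ce$delta_cost, 45 + pos * 2363)
})
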