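params <- base_params()
conv <- calibrated_convention()

test_that("tornado entries carry exact widths and ranks", {
  dsa <- one_way_dsa(params, "cancer_specific", conv)
  expect_s3_class(dsa, "pdac_tornado")
  expect_equal(dsa$bar_width, abs(dsa$icer_at_high - dsa$icer_at_low))
  expect_equal(dsa$rank, seq_len(nrow(dsa)))
  expect_true(all(diff(dsa$bar_width) <= 1e-9))
  # zero-width range: exactly zero bar, ranked last
  expect_equal(dsa$bar_width[dsa$parameter == "utility_death"], 0)
  expect_equal(dsa$bar_width[nrow(dsa)], 0)
  # parameters inert for this strategy produce zero bars
  expect_equal(dsa$bar_width[dsa$parameter == "t3cd_sensitivity"], 0)
})

test_that("tornado endpoints match a direct two-point re-evaluation", {
  dsa <- one_way_dsa(params, "combination", conv)
  row <- dsa[dsa$parameter == "cancer_specificity", ]
  lo <- cost_effectiveness(set_parameter(params, "cancer_specificity",
                                         row$low), "combination", conv)
  hi <- cost_effectiveness(set_parameter(params, "cancer_specificity",
                                         row$high), "combination", conv)
  expect_close(row$icer_at_low, lo$icer)
  expect_close(row$icer_at_high, hi$icer)
})

test_that("PSA spec validation rejects malformed inputs before sampling", {
  spec <- psa_distributions(params)
  expect_setequal(unique(spec$family), c("uniform", "fixed"))
  bad <- spec
  bad$parameter[1] <- "nonexistent"
  expect_error(run_psa(params, "t3cd", n_sims = 2, seed = 1, spec = bad),
               "nonexistent")
  bad2 <- spec
  bad2$family[2] <- "cauchy"
  expect_error(run_psa(params, "t3cd", n_sims = 2, seed = 1, spec = bad2),
               "family")
  expect_error(run_psa(params, "t3cd", n_sims = 0, seed = 1), "n_sims")
})

test_that("degenerate distributions reproduce the base case at any n", {
  spec <- psa_distributions(params)
  spec$family[] <- "fixed"
  psa <- run_psa(params, "combination", n_sims = 7, seed = 3, spec = spec,
                 convention = conv)
  bc <- cost_effectiveness(params, "combination", conv)
  expect_equal(unique(psa$draws$icer), bc$icer)
  expect_equal(unique(psa$draws$delta_cost), bc$delta_cost)
  expect_true(psa$fraction_cost_effective %in% c(0, 1))
  expect_equal(psa$fraction_cost_effective,
               as.numeric(bc$cost_effective))
  # CEAC of a point mass steps from 0 to 1 exactly at the base-case ICER
  ceac <- compute_ceac(psa, c(0, bc$icer * 0.99, bc$icer * 1.01, 1e6))
  expect_equal(ceac$probability, c(0, 0, 1, 1))
})

test_that("the same seed reproduces the PSA bitwise", {
  a <- run_psa(params, "cancer_specific", n_sims = 300, seed = 11,
               convention = conv)
  b <- run_psa(params, "cancer_specific", n_sims = 300, seed = 11,
               convention = conv)
  expect_identical(a$draws, b$draws)
  c <- run_psa(params, "cancer_specific", n_sims = 300, seed = 12,
               convention = conv)
  expect_false(identical(a$draws$delta_cost, c$draws$delta_cost))
})

test_that("per-parameter substreams are unaffected by other parameters", {
  spec <- psa_distributions(params)
  sub <- spec[spec$parameter %in% c("cancer_sensitivity",
                                    "cancer_specificity"), ]
  solo <- spec[spec$parameter == "cancer_specificity", ]
  V1 <- pdacscreen:::.psa_draws(params, sub, 50, 5)
  V2 <- pdacscreen:::.psa_draws(params, solo, 50, 5)
  expect_identical(V1[, "cancer_specificity"], V2[, "cancer_specificity"])
})

test_that("CEAC is monotone in the threshold when all QALY gains are positive", {
  psa <- run_psa(params, "combination", n_sims = 500, seed = 2,
                 convention = conv)
  expect_true(all(psa$draws$delta_qalys > 0))
  ceac <- compute_ceac(psa, seq(0, 150000, by = 5000))
  expect_true(all(diff(ceac$probability) >= 0))
  expect_equal(ceac$probability[1], mean(psa$draws$delta_cost < 0))
  expect_equal(compute_ceac(psa, 1e9)$probability, 1)
})

test_that("PSA fraction has binomial-scale seed noise", {
  fr <- vapply(1:12, function(s) {
    run_psa(params, "combination", n_sims = 250, seed = s,
            convention = conv)$fraction_cost_effective
  }, numeric(1))
  p <- mean(fr)
  se <- sqrt(p * (1 - p) / 250)
  expect_gt(stats::sd(fr), se / 4)
  expect_lt(stats::sd(fr), se * 4)
})

test_that("head-to-head comparison is symmetric and degenerates correctly", {
  spec <- psa_distributions(params)
  spec$family[] <- "fixed"
  hh <- head_to_head(params, "t3cd", "cancer_specific", n_sims = 5,
                     seed = 1, spec = spec, convention = conv)
  # point mass: preference matches the base-case ICER ordering
  bt <- cost_effectiveness(params, "t3cd", conv)
  bc <- cost_effectiveness(params, "cancer_specific", conv)
  expect_equal(hh$fraction_a, as.numeric(bt$icer < bc$icer))
  expect_true(all(hh$draws$cost_effective_a %in%
                    as.logical(bt$cost_effective)))

  same <- head_to_head(params, "t3cd", "t3cd", n_sims = 200, seed = 1,
                       convention = conv)
  expect_equal(same$fraction_a_ce, same$fraction_b_ce)

  ab <- head_to_head(params, "t3cd", "cancer_specific", n_sims = 400,
                     seed = 9, convention = conv)
  ba <- head_to_head(params, "cancer_specific", "t3cd", n_sims = 400,
                     seed = 9, convention = conv)
  expect_equal(ab$fraction_a, ba$fraction_b)
  expect_equal(ab$fraction_a + ab$fraction_b, 1)
})

test_that("two-way grid degenerates to the base case and obeys monotonicity", {
  one <- two_way_grid(params, "combination", "cancer_sensitivity",
                      "cancer_specificity", x_values = 0.32,
                      y_values = 0.95, convention = conv)
  bc <- cost_effectiveness(params, "combination", conv)
  expect_close(one$icer, bc$icer)

  grid <- two_way_grid(params, "combination", "cancer_sensitivity",
                       "cancer_specificity",
                       x_values = seq(0.30, 0.70, by = 0.05),
                       y_values = c(0.85, 0.95, 1), convention = conv)
  # at perfect specificity, NMB improves monotonically with sensitivity
  col <- grid[grid$y == 1, ]
  expect_true(all(diff(col$nmb[order(col$x)]) > 0))
  # the cost-effective region is upward-closed in specificity
  wide <- tidyr::pivot_wider(grid[, c("x", "y", "cost_effective")],
                             names_from = "y", values_from = "cost_effective")
  mat <- as.matrix(wide[, -1])
  expect_true(all(mat[, 2] >= mat[, 1]) && all(mat[, 3] >= mat[, 2]))
})

test_that("plot methods return ggplot objects", {
  psa <- run_psa(params, "combination", n_sims = 50, seed = 1,
                 convention = conv)
  expect_s3_class(ggplot2::autoplot(psa), "ggplot")
  expect_s3_class(ggplot2::autoplot(compute_ceac(psa)), "ggplot")
  dsa <- one_way_dsa(params, "combination", conv)
  expect_s3_class(ggplot2::autoplot(dsa), "ggplot")
})
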