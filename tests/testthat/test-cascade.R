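params <- base_params()

test_that("single-test classification matches the 2x2 oracle exactly", {
  cases <- list(
    list(n = 200000, prev = 0.01, se = 0.32, sp = 0.95),
    list(n = 200000, prev = 0.10, se = 0.80, sp = 0.98),
    list(n = 200000, prev = 2e-4, se = 0.32, sp = 0.95),
    list(n = 1000, prev = 0.5, se = 1, sp = 1),
    list(n = 5000, prev = 0, se = 0.6, sp = 0.7)
  )
  for (cs in cases) {
    got <- classify_cohort(cs$n, cs$prev, test_performance(cs$se, cs$sp))
    want <- oracle_2x2(cs$n, cs$prev, cs$se, cs$sp)
    expect_close(got$true_positive, want$tp)
    expect_close(got$false_positive, want$fp)
    expect_close(got$false_negative, want$fn)
    expect_close(got$true_negative, want$tn)
    expect_close(got$n_positive, want$tp + want$fp)
  }
  # zero prevalence: no diseased persons to find or miss
  z <- classify_cohort(1000, 0, test_performance(0.9, 0.9))
  expect_identical(z$true_positive, 0)
  expect_identical(z$false_negative, 0)
  # general-population scenario arithmetic (own 2x2 oracle)
  g <- run_cascade(params, "cancer_specific", population = "general")
  expect_close(g$true_positive, 12.8)
  expect_close(g$false_positive, 9998)
})

test_that("cancer-specific cascade reproduces the published cohort counts", {
  cc <- run_cascade(params, "cancer_specific")
  expect_equal(cc$n_positive, 10540)
  expect_equal(cc$true_positive, 640)
  expect_equal(cc$false_positive, 9900)
  expect_equal(cc$pdac_detected, 640)
  expect_equal(round_half_up(cc$scans_per_pdac_case, 1), 16.5)
  expect_equal(round_half_up(100 * cc$true_positive / cc$n_positive, 1),
               6.1)
})

test_that("T3cD cascade reproduces the published cohort counts", {
  tc <- run_cascade(params, "t3cd")
  expect_equal(tc$n_positive, 19600)
  expect_equal(tc$true_positive, 16000)
  expect_equal(tc$false_positive, 3600)
  expect_equal(tc$pdac_detected, 1600)
  expect_equal(tc$scans_per_pdac_case, 12.25)
  expect_equal(round_half_up(tc$scans_per_pdac_case, 1), 12.3)
  expect_equal(tc$scans_per_target_case, 1.225)
})

test_that("sequential cascade reproduces the published stage-2 counts", {
  cb <- run_cascade(params, "combination")
  expect_equal(cb$true_positive, 512)
  expect_equal(cb$false_positive, 900)
  expect_equal(cb$n_positive, 1412)
  expect_equal(cb$stage1_positive, 19600)
  # internally consistent imaging ratio (the published 2.4 is not
  # recoverable from the published counts, 1412 / 512 = 2.76)
  expect_close(cb$scans_per_pdac_case, 1412 / 512)
})

test_that("2x2 cells sum to the cohort size for every cascade", {
  grids <- expand.grid(se1 = c(0.5, 0.8), sp1 = c(0.9, 0.98),
                       se2 = c(0.32, 0.7), sp2 = c(0.7, 0.95))
  for (i in seq_len(nrow(grids))) {
    p <- set_parameter(params, "t3cd_sensitivity", grids$se1[i])
    p <- set_parameter(p, "t3cd_specificity", grids$sp1[i])
    p <- set_parameter(p, "cancer_sensitivity", grids$se2[i])
    p <- set_parameter(p, "cancer_specificity", grids$sp2[i])
    for (s in c("cancer_specific", "t3cd", "combination")) {
      cc <- run_cascade(p, s)
      expect_close(cc$true_positive + cc$false_positive +
                     cc$false_negative + cc$true_negative, cc$n_screened)
      expect_true(all(c(cc$true_positive, cc$false_positive,
                        cc$false_negative, cc$true_negative) >= -1e-12))
    }
  }
})

test_that("scans per detected case fall with specificity and prevalence", {
  sp_grid <- seq(0.7, 0.99, by = 0.03)
  scans <- vapply(sp_grid, function(sp) {
    p <- set_parameter(params, "cancer_specificity", sp)
    run_cascade(p, "cancer_specific")$scans_per_pdac_case
  }, numeric(1))
  expect_true(all(diff(scans) < 0))

  prev_grid <- seq(0.002, 0.03, by = 0.004)
  scans_prev <- vapply(prev_grid, function(pr) {
    p <- set_parameter(params, "pdac_incidence", pr)
    run_cascade(p, "cancer_specific")$scans_per_pdac_case
  }, numeric(1))
  expect_true(all(diff(scans_prev) < 0))
})

test_that("pass-through stage 1 reduces the combination to a single test", {
  p <- set_parameter(params, "t3cd_sensitivity", 1)
  p <- set_parameter(p, "t3cd_specificity", 1)
  p <- set_parameter(p, "t3cd_incidence", 1, renormalize = FALSE)
  suppressWarnings({
    cb <- run_cascade(p, "combination")
  })
  single <- classify_cohort(200000, p$context$pdac_incidence_in_t3cd,
                            p$cancer_test)
  expect_close(cb$true_positive, single$true_positive)
  expect_close(cb$false_positive, single$false_positive)
  expect_close(cb$n_positive, single$n_positive)
})

test_that("degenerate tests set the infinite-scans flag", {
  p <- set_parameter(params, "cancer_sensitivity", 0)
  cc <- run_cascade(p, "cancer_specific")
  expect_identical(cc$pdac_detected, 0)
  expect_true(cc$infinite_scans)
  expect_identical(cc$scans_per_pdac_case, Inf)

  perfect <- set_parameter(set_parameter(params, "t3cd_sensitivity", 1),
                           "t3cd_specificity", 1)
  expect_equal(run_cascade(perfect, "t3cd")$scans_per_target_case, 1)
})

test_that("cascade validates its inputs", {
  expect_error(classify_cohort(0, 0.1, test_performance(0.5, 0.5)),
               "positive")
  expect_error(classify_cohort(100, 1.2, test_performance(0.5, 0.5)),
               "prevalence")
  expect_error(run_cascade(params, "t3cd", population = "general"),
               "general")
})

test_that("cascade summary exports a per-strategy CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  export_cascade_csv(cascade_summary(params), path)
  tab <- utils::read.csv(path)
  expect_equal(nrow(tab), 3)
  expect_setequal(tab$strategy, c("cancer_specific", "t3cd", "combination"))
})
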