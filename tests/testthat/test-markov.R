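params <- base_params()

test_that("median-to-probability conversion matches the published figure", {
  p <- annual_death_probability(c(3.7, 1.4, 1.3, 0.4))
  expect_equal(round(p, 2), c(0.17, 0.39, 0.41, 0.82))
  expect_equal(annual_death_probability(1), 0.5)
})

test_that("conversion round-trips with its closed-form inverse", {
  m <- c(0.1, 0.4, 1, 1.3, 3.7, 10, 80)
  expect_equal(median_survival_from_probability(annual_death_probability(m)),
               m, tolerance = 1e-12)
  # strictly decreasing in median survival
  grid <- seq(0.05, 20, length.out = 200)
  expect_true(all(diff(annual_death_probability(grid)) < 0))
  expect_error(annual_death_probability(0), "positive")
  expect_error(median_survival_from_probability(1), "between")
})

test_that("stage trace matches a direct per-cycle oracle", {
  # default convention: start-of-cycle rewards, first cycle undiscounted
  for (cs in list(list(stage = "resectable", u = 0.83, m = 3.7, c = 47581),
                  list(stage = "metastatic", u = 0.76, m = 0.4, c = 28418),
                  list(stage = "locally_advanced", u = 0.80, m = 1.3,
                       c = 33398))) {
    tr <- stage_trace(cs$stage, params, "biomarker")
    want <- oracle_stage(cs$u, cs$m, cs$c)
    expect_close(attr(tr, "discounted_qalys"), want$qalys)
    expect_close(attr(tr, "discounted_life_years"), want$ly)
    expect_close(attr(tr, "discounted_costs"), want$cost)
  }
  # frozen oracle values for the two extreme stages
  expect_equal(attr(stage_trace("resectable", params), "discounted_qalys"),
               2.801, tolerance = 5e-4)
  expect_equal(attr(stage_trace("metastatic", params), "discounted_qalys"),
               0.920, tolerance = 5e-4)
})

test_that("stage trace matches the oracle under every convention dial", {
  grid <- expand.grid(reward = c("start", "end", "half_cycle"),
                      dstart = c("cycle1", "cycle0"),
                      ctime = c("lump_sum", "spread"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    conv <- accrual_convention(grid$reward[i], grid$dstart[i],
                               grid$ctime[i])
    tr <- stage_trace("borderline_resectable", params, "standard", conv)
    want <- oracle_stage(0.81, 1.4, 31947, reward = grid$reward[i],
                         dstart = grid$dstart[i], ctime = grid$ctime[i])
    expect_close(attr(tr, "discounted_qalys"), want$qalys)
    expect_close(attr(tr, "discounted_costs"), want$cost)
  }
})

test_that("trace obeys its structural invariants", {
  for (st in c("resectable", "metastatic")) {
    tr <- stage_trace(st, params)
    expect_equal(tr$alive_prob[1], 1)
    expect_true(all(diff(tr$alive_prob) <= 0))
    expect_true(all(tr$disc_qalys >= 0 & tr$disc_cost >= 0))
    expect_lte(attr(tr, "discounted_qalys"),
               attr(tr, "discounted_life_years"))
  }
})

test_that("undiscounted immortal cohort accrues exactly the horizon", {
  p <- set_parameter(params, "discount_rate", 0)
  p <- set_parameter(p, "utility_resectable", 1)
  p <- set_parameter(p, "median_survival_resectable", 1e9)
  tr <- stage_trace("resectable", p)
  expect_equal(attr(tr, "discounted_qalys"), 5)
  expect_equal(attr(tr, "discounted_life_years"), 5)
})

test_that("undiscounted life expectancy approaches 1/p as horizon grows", {
  p <- set_parameter(params, "discount_rate", 0)
  vp <- params_to_vector(p)
  vp["horizon"] <- 400
  p2 <- params_from_vector(vp, p$ranges)
  tr <- stage_trace("locally_advanced", p2,
                    convention = accrual_convention(transition_digits = NULL))
  pd <- annual_death_probability(1.3)
  s <- 1 - pd
  truncation <- s^400 / pd  # closed-form tail of the geometric series
  expect_equal(attr(tr, "discounted_life_years"), 1 / pd - truncation,
               tolerance = 1e-9)
})

test_that("mixture outcome reproduces hand-checked cost aggregates", {
  conv <- accrual_convention(cost_timing = "lump_sum")
  mb <- mixture_outcome(params, "biomarker", conv)
  ms <- mixture_outcome(params, "standard", conv)
  expect_close(mb$cost, 39520.45)  # 0.4*47581 + 0.25*37187 + 0.25*33398 + 0.1*28418
  expect_close(ms$cost, 30543.25)  # 0.1*44203 + 0.15*31947 + 0.2*28505 + 0.55*28418
  expect_equal(ms$qalys, 1.411, tolerance = 5e-4)
  # degenerate distribution reduces to the single-stage trace
  deg <- mixture_outcome(params, "biomarker", conv,
                         dist = c(resectable = 1, borderline_resectable = 0,
                                  locally_advanced = 0, metastatic = 0))
  tr <- stage_trace("resectable", params, "biomarker", conv)
  expect_close(deg$qalys, attr(tr, "discounted_qalys"))
  expect_close(deg$cost, attr(tr, "discounted_costs"))
})

test_that("trace export writes one block per stage", {
  path <- withr::local_tempfile(fileext = ".csv")
  export_trace_csv(params, path)
  tab <- utils::read.csv(path)
  expect_equal(nrow(tab), 4 * 5)
  expect_setequal(unique(tab$stage),
                  c("resectable", "borderline_resectable",
                    "locally_advanced", "metastatic"))
})
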