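# Individual-level Monte Carlo realisation of the cohort model: Bernoulli
# disease status at the stated incidences (PDAC nested within T3cD),
# Bernoulli test results, categorical stage assignment, geometric per-cycle
# survival (the exact individual-level counterpart of the cohort's annual
# death probability), and per-individual cost/QALY accrual mirroring the
# deterministic accrual convention. Serves as a brute-force oracle for the
# closed-form cohort expectations.

# discounted reward lookup indexed by the number of survived transitions
# capped at the horizon (gc = 0..h): element gc + 1 is the individual's
# discounted life-years under the convention's reward timing
.reward_lookup <- function(h, r, convention) {
  extra <- if (convention$discount_start == "cycle0") 1L else 0L
  d <- (1 + r)^(-(seq_len(h) - 1L + extra))
  dcum <- cumsum(d)
  gc <- 0:h
  s_look <- dcum[pmin(gc + 1L, h)]          # start-of-cycle occupancy
  e_look <- c(0, dcum)[pmin(gc, h) + 1L]    # end-of-cycle survivors
  list(start = s_look, end = e_look,
       half_cycle = (s_look + e_look) / 2,
       entry = d[1])
}

.sample_stage <- function(k, dist) {
  if (k == 0) return(integer(0))
  findInterval(stats::runif(k), cumsum(dist)[-length(dist)]) + 1L
}

# geometric number of survived one-year transitions; p = 0 means immortal
.sample_survival <- function(p) {
  g <- rep(Inf, length(p))
  pos <- p > 0
  if (any(pos)) g[pos] <- stats::rgeom(sum(pos), p[pos])
  g
}

#' Simulate an individual-level screening cohort
#'
#' Draws `n` individuals with new-onset diabetes: T3cD status Bernoulli at
#' `t3cd_incidence`, PDAC status Bernoulli at `pdac_incidence_in_t3cd`
#' *within* the T3cD subgroup (so PDAC is a subset of T3cD, and the marginal
#' PDAC prevalence is their product), biomarker test results Bernoulli at
#' the stated sensitivity/specificity, stage assignment categorical from the
#' pathway's starting-stage distribution, survival geometric with the
#' stage's annual death probability truncated at the horizon, and
#' per-individual discounted cost/QALY accrual matching the deterministic
#' accrual convention cycle for cycle.
#'
#' @param params A `pdac_parameters` object.
#' @param strategy One of `"standard_care"`, `"cancer_specific"`, `"t3cd"`,
#'   `"combination"`.
#' @param n Number of individuals (>= 1).
#' @param seed Integer seed; the same seed reproduces the identical cohort.
#' @param convention An [accrual_convention()].
#' @return A `pdac_cohort_sim` object with elements `individuals` (one row
#'   per person), `summary` (empirical cascade counts and per-person means
#'   with standard errors), and the run configuration.
#' @examples
#' sim <- simulate_cohort(default_parameters(), "t3cd", n = 2000, seed = 7)
#' sim$summary
#' @export
simulate_cohort <- function(params, strategy = .strategy_keys, n,
                            seed = 1, convention = default_convention()) {
  strategy <- match.arg(strategy)
  validate_parameters(params, warn_consistency = FALSE)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("n must be a positive number of individuals", call. = FALSE)
  }
  n <- as.integer(n)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  set.seed(as.integer(seed))
  v <- params_to_vector(params)
  h <- as.integer(v[["horizon"]])
  r <- v[["discount_rate"]]
  look <- .reward_lookup(h, r, convention)
  reward <- look[[convention$reward_timing]]
  p_stage <- .stage_survival(params$stages$median_survival, convention)
  s_stage <- 1 - p_stage
  util <- params$stages$utility
  geo_undisc <- .geo_sum(s_stage, h)

  has_t3cd <- stats::runif(n) < v[["t3cd_incidence"]]
  has_pdac <- has_t3cd & (stats::runif(n) < v[["pdac_incidence_in_t3cd"]])

  u1 <- stats::runif(n)
  u2 <- stats::runif(n)
  t1 <- t2 <- rep(NA, n)
  if (strategy %in% c("t3cd", "combination")) {
    t1 <- ifelse(has_t3cd, u1 < v[["t3cd_sensitivity"]],
                 u1 < 1 - v[["t3cd_specificity"]])
  } else if (strategy == "cancer_specific") {
    t1 <- ifelse(has_pdac, u1 < v[["cancer_sensitivity"]],
                 u1 < 1 - v[["cancer_specificity"]])
  }
  if (strategy == "combination") {
    t2 <- ifelse(t1,
                 ifelse(has_pdac, u2 < v[["cancer_sensitivity"]],
                        u2 < 1 - v[["cancer_specificity"]]),
                 NA)
  }
  detected <- switch(strategy,
                     standard_care = rep(FALSE, n),
                     cancer_specific = has_pdac & t1 %in% TRUE,
                     t3cd = has_pdac & t1 %in% TRUE,
                     combination = has_pdac & t1 %in% TRUE & t2 %in% TRUE)
  final_positive <- switch(strategy,
                           standard_care = rep(FALSE, n),
                           cancer_specific = t1 %in% TRUE,
                           t3cd = t1 %in% TRUE,
                           combination = t1 %in% TRUE & t2 %in% TRUE)

  stage_idx <- rep(NA_integer_, n)
  det_i <- which(detected)
  miss_i <- which(has_pdac & !detected)
  stage_idx[det_i] <- .sample_stage(length(det_i),
                                    params$dist_biomarker[.stage_keys])
  stage_idx[miss_i] <- .sample_stage(length(miss_i),
                                     params$dist_standard[.stage_keys])

  gsurv <- rep(Inf, n)
  pdac_i <- which(has_pdac)
  gsurv[pdac_i] <- .sample_survival(p_stage[stage_idx[pdac_i]])
  gc <- pmin(gsurv, h)

  ly <- reward[gc + 1L]
  qaly <- ifelse(has_pdac, util[stage_idx] * ly, v[["utility_healthy"]] * ly)

  # costs -------------------------------------------------------------
  cost <- rep(0, n)
  cost <- cost + switch(strategy,
                        standard_care = 0,
                        cancer_specific = v[["cancer_test_cost"]],
                        t3cd = v[["t3cd_test_cost"]],
                        combination = v[["t3cd_test_cost"]] +
                          ifelse(t1 %in% TRUE, v[["cancer_test_cost"]], 0))
  cost <- cost + ifelse(final_positive,
                        v[["diagnostic_cost_biomarker_path"]], 0)
  symptomatic <- has_pdac & !detected  # present and follow standard care
  cost <- cost + ifelse(symptomatic,
                        v[["diagnostic_cost_standard_path"]], 0)

  treat_cost <- function(idx, cost_by_stage, st_idx, g_surv) {
    if (length(idx) == 0) return(numeric(0))
    ci <- cost_by_stage[st_idx]
    if (convention$cost_timing == "lump_sum") {
      ci * look$entry
    } else {
      gci <- pmin(g_surv, h)
      ci / geo_undisc[st_idx] * look$start[gci + 1L]
    }
  }
  std_costs <- params$stages$treatment_cost_standard
  bio_costs <- params$stages$treatment_cost_biomarker
  cost[miss_i] <- cost[miss_i] +
    treat_cost(miss_i, std_costs, stage_idx[miss_i], gsurv[miss_i])
  if (length(det_i) > 0) {
    if (convention$cost_staging == "shifted") {
      cost[det_i] <- cost[det_i] +
        treat_cost(det_i, bio_costs, stage_idx[det_i], gsurv[det_i])
    } else {
      # unshifted costing: treatment costs follow the standard-care stage
      # mix; an independent costing stage (and its own survival for the
      # spread instalments) reproduces the cohort formula in expectation
      k <- .sample_stage(length(det_i), params$dist_standard[.stage_keys])
      gk <- .sample_survival(p_stage[k])
      cost[det_i] <- cost[det_i] + treat_cost(det_i, bio_costs, k, gk)
    }
  }

  death_cycle <- ifelse(is.finite(gsurv) & gsurv < h, gsurv + 1L,
                        NA_integer_)
  death_cycle[!has_pdac] <- NA_integer_

  individuals <- tibble::tibble(
    id = seq_len(n),
    has_t3cd = has_t3cd,
    has_pdac = has_pdac,
    test1_positive = as.logical(t1),
    test2_positive = as.logical(t2),
    detected = detected,
    assigned_stage = ifelse(is.na(stage_idx), NA_character_,
                            .stage_keys[stage_idx]),
    death_cycle = as.integer(death_cycle),
    accrued_cost = cost,
    accrued_qalys = qaly,
    accrued_life_years = ly
  )

  target_positive <- switch(strategy,
                            standard_care = rep(FALSE, n),
                            cancer_specific = has_pdac,
                            t3cd = has_t3cd,
                            combination = has_pdac)
  tp <- sum(final_positive & target_positive)
  fp <- sum(final_positive & !target_positive)
  se_mean <- function(x) stats::sd(x) / sqrt(n)
  summary <- tibble::tibble(
    strategy = strategy, n = n,
    n_positive = tp + fp, true_positive = tp, false_positive = fp,
    false_negative = sum(!final_positive & target_positive),
    true_negative = sum(!final_positive & !target_positive),
    pdac_detected = sum(detected),
    stage1_positive = if (strategy == "combination") sum(t1 %in% TRUE) else
      NA_integer_,
    mean_cost = mean(cost), se_cost = se_mean(cost),
    mean_qalys = mean(qaly), se_qalys = se_mean(qaly),
    mean_life_years = mean(ly), se_life_years = se_mean(ly)
  )
  structure(list(individuals = individuals, summary = summary,
                 params = params, strategy = strategy, n = n,
                 seed = as.integer(seed),
                 convention = convention,
                 convention_fingerprint = convention_fingerprint(convention)),
            class = "pdac_cohort_sim")
}

#' @export
print.pdac_cohort_sim <- function(x, ...) {
  cat(sprintf("<pdac_cohort_sim> %s, n = %d, seed = %d (%s)\n", x$strategy,
              x$n, x$seed, x$convention_fingerprint))
  print(x$summary)
  invisible(x)
}

#' Export a simulated cohort as CSV
#'
#' @param sim A `pdac_cohort_sim` object.
#' @param path Output path; a `.gz` suffix writes a gzip-compressed file.
#' @return `path`, invisibly.
#' @export
export_cohort_csv <- function(sim, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.csv(as.data.frame(sim$individuals), con, row.names = FALSE)
  invisible(path)
}

#' Check a simulated cohort against the deterministic expectations
#'
#' Recomputes the deterministic cascade counts and per-person outcomes for
#' the simulated cohort's own configuration and z-scores every matched
#' quantity against the empirical values (binomial standard errors for
#' counts, empirical standard errors for means).
#'
#' @param sim A `pdac_cohort_sim` object.
#' @param tolerance_se Pass/fail threshold in standard errors (default 4).
#' @return A `pdac_oracle_report` tibble with columns `quantity`,
#'   `expected`, `observed`, `se`, `z`, `pass`; attribute `"all_pass"`
#'   summarises it.
#' @export
oracle_check <- function(sim, tolerance_se = 4) {
  if (!inherits(sim, "pdac_cohort_sim")) {
    stop("oracle_check() expects a cohort produced by simulate_cohort()",
         call. = FALSE)
  }
  params <- sim$params
  n <- sim$n
  s <- sim$summary
  rows <- list()
  if (sim$strategy != "standard_care") {
    casc <- run_cascade(params, sim$strategy, n = n)
    count_row <- function(q, expected, observed) {
      p <- expected / n
      se <- sqrt(n * p * (1 - p))
      z <- if (se > 0) (observed - expected) / se else
        ifelse(observed == expected, 0, Inf)
      tibble::tibble(quantity = q, expected = expected, observed = observed,
                     se = se, z = z)
    }
    rows <- c(rows, list(
      count_row("n_positive", casc$n_positive, s$n_positive),
      count_row("true_positive", casc$true_positive, s$true_positive),
      count_row("false_positive", casc$false_positive, s$false_positive),
      count_row("pdac_detected", casc$pdac_detected, s$pdac_detected)))
  }
  outc <- strategy_outcome(params, sim$strategy, sim$convention)
  mean_row <- function(q, expected, observed, se) {
    tibble::tibble(quantity = q, expected = expected, observed = observed,
                   se = se,
                   z = if (se > 0) (observed - expected) / se else
                     ifelse(observed == expected, 0, Inf))
  }
  rows <- c(rows, list(
    mean_row("cost_per_person", outc$cost_per_person, s$mean_cost,
             s$se_cost),
    mean_row("qalys_per_person", outc$qalys_per_person, s$mean_qalys,
             s$se_qalys),
    mean_row("life_years_per_person", outc$life_years_per_person,
             s$mean_life_years, s$se_life_years)))
  report <- dplyr::bind_rows(rows)
  report$pass <- abs(report$z) <= tolerance_se
  structure(report, class = c("pdac_oracle_report", class(report)),
            all_pass = all(report$pass), tolerance_se = tolerance_se,
            strategy = sim$strategy, n = n)
}
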