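# Decision-tree arithmetic for the screening strategies. Counts are expected
# values kept as exact fractions; rounding happens only in the reporting
# layer.

.cascade_tibble <- function(strategy, n, n_positive, tp, fp, fn, tn,
                            pdac_detected, target_tp,
                            stage1_positive = NA_real_,
                            stage1_true_positive = NA_real_,
                            stage1_false_positive = NA_real_) {
  out <- tibble::tibble(
    strategy = strategy,
    n_screened = n,
    n_positive = n_positive,
    true_positive = tp,
    false_positive = fp,
    false_negative = fn,
    true_negative = tn,
    pdac_detected = pdac_detected,
    scans_per_target_case = ifelse(target_tp > 0, n_positive / target_tp,
                                   Inf),
    scans_per_pdac_case = ifelse(pdac_detected > 0,
                                 n_positive / pdac_detected, Inf),
    infinite_scans = pdac_detected == 0,
    stage1_positive = stage1_positive,
    stage1_true_positive = stage1_true_positive,
    stage1_false_positive = stage1_false_positive
  )
  class(out) <- c("pdac_cascade", class(out))
  out
}

#' Expected 2x2 outcomes of one test applied to a cohort
#'
#' Classifies an `n`-person cohort with disease prevalence `prevalence`
#' through a single test: `TP = n * prev * Se`, `FP = n * (1 - prev) *
#' (1 - Sp)`, `FN = n * prev * (1 - Se)`, `TN = n * (1 - prev) * Sp`. Counts
#' are expected (possibly fractional) values; the four cells sum to `n`
#' exactly.
#'
#' @param n Cohort size (> 0).
#' @param prevalence Disease prevalence in the cohort.
#' @param test A [test_performance()] object.
#' @return One-row cascade tibble.
#' @examples
#' classify_cohort(200000, 0.01, test_performance(0.32, 0.95))
#' @export
classify_cohort <- function(n, prevalence, test) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0) {
    stop("n must be a positive cohort size", call. = FALSE)
  }
  if (!inherits(test, "test_performance")) {
    test <- do.call(test_performance, as.list(test))
  }
  .check_prob(prevalence, "prevalence")
  se <- test$sensitivity
  sp <- test$specificity
  tp <- n * prevalence * se
  fp <- n * (1 - prevalence) * (1 - sp)
  fn <- n * prevalence * (1 - se)
  tn <- n * (1 - prevalence) * sp
  .cascade_tibble("single_test", n, tp + fp, tp, fp, fn, tn,
                  pdac_detected = tp, target_tp = tp)
}

#' Expected screening-cascade outcomes for a strategy
#'
#' Computes the decision-tree expectations for one screening strategy applied
#' to a cohort of people with new-onset diabetes:
#'
#' * `"cancer_specific"` — a single cancer-specific biomarker at the cohort
#'   PDAC prevalence; the target condition is PDAC.
#' * `"t3cd"` — a single T3cD biomarker at the T3cD prevalence; the target
#'   condition is pancreatogenic disease (T3cD), while detected PDAC cases
#'   are the PDAC cases captured by the test (PDAC is modelled as a subset of
#'   T3cD, so PDAC detection inherits the T3cD test's sensitivity).
#' * `"combination"` — the T3cD cascade followed by the cancer-specific test
#'   applied to the T3cD-positive pool, in which the PDAC-positive persons
#'   are those captured at stage 1 and all other pool members are PDAC-free.
#'   Imaging applies only to stage-2 positives.
#'
#' For the single-test strategies PDAC prevalence is taken directly from
#' `pdac_incidence` (or `pdac_incidence_general` for the general-population
#' scenario); the T3cD-led strategies derive it as `t3cd_incidence *
#' pdac_incidence_in_t3cd`.
#'
#' @param params A `pdac_parameters` object.
#' @param strategy One of `"cancer_specific"`, `"t3cd"`, `"combination"`.
#' @param n Cohort size; defaults to the parameter set's population size.
#' @param population `"new_onset_diabetes"` (default) or `"general"`
#'   (cancer-specific strategy only).
#' @return One-row cascade tibble with expected counts, detected PDAC cases,
#'   and persons imaged per detected case. The four 2x2 cells always sum to
#'   `n` exactly.
#' @examples
#' run_cascade(default_parameters(), "combination")
#' @export
run_cascade <- function(params, strategy = c("cancer_specific", "t3cd",
                                             "combination"),
                        n = NULL,
                        population = c("new_onset_diabetes", "general")) {
  strategy <- match.arg(strategy)
  population <- match.arg(population)
  validate_parameters(params, warn_consistency = FALSE)
  v <- params_to_vector(params)
  if (is.null(n)) n <- v[["population_size"]]
  if (population == "general" && strategy != "cancer_specific") {
    stop("the general-population scenario applies to the cancer-specific strategy",
         call. = FALSE)
  }
  se1 <- v[["t3cd_sensitivity"]]; sp1 <- v[["t3cd_specificity"]]
  se2 <- v[["cancer_sensitivity"]]; sp2 <- v[["cancer_specificity"]]
  if (strategy == "cancer_specific") {
    prev <- if (population == "general") v[["pdac_incidence_general"]] else
      v[["pdac_incidence"]]
    out <- classify_cohort(n, prev, test_performance(se2, sp2))
    out$strategy <- strategy
    return(out)
  }
  t3cd <- v[["t3cd_incidence"]]
  prev_pdac <- t3cd * v[["pdac_incidence_in_t3cd"]]
  tp1 <- n * t3cd * se1
  fp1 <- n * (1 - t3cd) * (1 - sp1)
  fn1 <- n * t3cd * (1 - se1)
  tn1 <- n * (1 - t3cd) * sp1
  pdac_det1 <- n * prev_pdac * se1
  if (strategy == "t3cd") {
    return(.cascade_tibble("t3cd", n, tp1 + fp1, tp1, fp1, fn1, tn1,
                           pdac_detected = pdac_det1, target_tp = tp1))
  }
  # sequential strategy: cancer test on the stage-1 positive pool; the
  # false-positive T3cD members are PDAC-free at stage 2
  pool <- tp1 + fp1
  tp2 <- pdac_det1 * se2
  fp2 <- (pool - pdac_det1) * (1 - sp2)
  pdac_total <- n * prev_pdac
  fn <- pdac_total - tp2
  tn <- n - tp2 - fp2 - fn
  .cascade_tibble("combination", n, tp2 + fp2, tp2, fp2, fn, tn,
                  pdac_detected = tp2, target_tp = tp2,
                  stage1_positive = pool, stage1_true_positive = tp1,
                  stage1_false_positive = fp1)
}

#' Cascade summary across all screening strategies
#'
#' @param params A `pdac_parameters` object.
#' @param n Cohort size; defaults to the population size.
#' @return Tibble with one row per strategy (cancer-specific, T3cD,
#'   combination).
#' @export
cascade_summary <- function(params, n = NULL) {
  out <- dplyr::bind_rows(lapply(c("cancer_specific", "t3cd", "combination"),
                                 function(s) run_cascade(params, s, n = n)))
  class(out) <- c("pdac_cascade", class(out))
  out
}

#' Export a cascade summary as CSV
#'
#' @param cascade A cascade tibble from [run_cascade()] or
#'   [cascade_summary()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_cascade_csv <- function(cascade, path) {
  utils::write.csv(as.data.frame(cascade), path, row.names = FALSE)
  invisible(path)
}

#' Round half away from zero
#'
#' Reporting-layer rounding matching the published tables (e.g. 12.25 persons
#' imaged per detected case prints as 12.3), unlike R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # the 1e-9 guard keeps exact halves (e.g. 49/4) that floating-point
  # cascade arithmetic lands a few ulp under the boundary rounding up
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}
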