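# Model inputs: every scalar has one canonical key; the built-in fixture
# carries the published base-case values and sensitivity ranges.

.stage_keys <- c("resectable", "borderline_resectable", "locally_advanced",
                 "metastatic")

.strategy_keys <- c("standard_care", "cancer_specific", "t3cd", "combination")

#' Canonical parameter keys
#'
#' Every scalar model input has exactly one canonical key. These keys name
#' columns of the flat parameter vector used by the evaluation engine, rows of
#' the sensitivity-range table, and entries of the configuration file.
#'
#' @return Character vector of canonical keys.
#' @export
parameter_keys <- function() {
  c("population_size", "horizon", "wtp_threshold", "discount_rate",
    "t3cd_incidence", "pdac_incidence", "pdac_incidence_general",
    "pdac_incidence_in_t3cd",
    "t3cd_sensitivity", "t3cd_specificity",
    "cancer_sensitivity", "cancer_specificity",
    "t3cd_test_cost", "cancer_test_cost",
    "diagnostic_cost_biomarker_path", "diagnostic_cost_standard_path",
    "utility_healthy", paste0("utility_", .stage_keys), "utility_death",
    paste0("treatment_cost_biomarker_", .stage_keys),
    paste0("treatment_cost_standard_", .stage_keys),
    paste0("dist_biomarker_", .stage_keys),
    paste0("dist_standard_", .stage_keys),
    paste0("median_survival_", .stage_keys))
}

#' Diagnostic test performance
#'
#' @param sensitivity Probability that a diseased person tests positive.
#' @param specificity Probability that a disease-free person tests negative.
#' @return A `test_performance` object.
#' @examples
#' test_performance(0.32, 0.95)
#' @export
test_performance <- function(sensitivity, specificity) {
  for (nm in c("sensitivity", "specificity")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || is.na(val) ||
        val < 0 || val > 1) {
      stop(nm, " must be a single probability in [0, 1], got ",
           deparse(val), call. = FALSE)
    }
  }
  structure(list(sensitivity = sensitivity, specificity = specificity),
            class = "test_performance")
}

#' @export
print.test_performance <- function(x, ...) {
  cat(sprintf("<test_performance> Se = %.3g, Sp = %.3g\n",
              x$sensitivity, x$specificity))
  invisible(x)
}

# Sensitivity ranges for the fixture, mirroring the published input table.
.default_ranges <- function() {
  tr <- function(name, base, low, high, units, source) {
    tibble::tibble(name = name, base = base, low = low, high = high,
                   units = units, source = source)
  }
  dplyr::bind_rows(
    tr("treatment_cost_biomarker_resectable", 47581, 40856, 55091, "GBP",
       "treatment cost, biomarker pathway, resectable"),
    tr("treatment_cost_biomarker_borderline_resectable", 37187, 31088, 43939,
       "GBP", "treatment cost, biomarker pathway, borderline resectable"),
    tr("treatment_cost_biomarker_locally_advanced", 33398, 29369, 37687, "GBP",
       "treatment cost, biomarker pathway, locally advanced"),
    # upper range 33 231 vs 32 231 on the standard row: asymmetry as published
    tr("treatment_cost_biomarker_metastatic", 28418, 24802, 33231, "GBP",
       "treatment cost, biomarker pathway, metastatic"),
    tr("treatment_cost_standard_resectable", 44203, 37815, 51375, "GBP",
       "treatment cost, standard pathway, resectable"),
    tr("treatment_cost_standard_borderline_resectable", 31947, 27217, 37143,
       "GBP", "treatment cost, standard pathway, borderline resectable"),
    tr("treatment_cost_standard_locally_advanced", 28505, 25855, 31217, "GBP",
       "treatment cost, standard pathway, locally advanced"),
    tr("treatment_cost_standard_metastatic", 28418, 24802, 32231, "GBP",
       "treatment cost, standard pathway, metastatic"),
    tr("t3cd_test_cost", 45, 20, 100, "GBP", "T3cD biomarker unit cost"),
    tr("cancer_test_cost", 45, 20, 100, "GBP",
       "cancer-specific biomarker unit cost"),
    tr("diagnostic_cost_biomarker_path", 2363, 2289, 2438, "GBP",
       "diagnostic work-up, biomarker pathway"),
    tr("diagnostic_cost_standard_path", 3087, 3068, 3106, "GBP",
       "diagnostic work-up, standard care pathway"),
    tr("utility_healthy", 0.86, 0.85, 0.87, "utility", "health utility, healthy"),
    tr("utility_resectable", 0.83, 0.82, 0.85, "utility",
       "health utility, resectable"),
    tr("utility_borderline_resectable", 0.81, 0.81, 0.81, "utility",
       "health utility, borderline resectable"),
    tr("utility_locally_advanced", 0.80, 0.78, 0.81, "utility",
       "health utility, locally advanced"),
    tr("utility_metastatic", 0.76, 0.75, 0.78, "utility",
       "health utility, metastatic"),
    tr("utility_death", 0, 0, 0, "utility", "health utility, death"),
    tr("t3cd_sensitivity", 0.80, 0.70, 0.99, "probability",
       "T3cD biomarker sensitivity"),
    tr("t3cd_specificity", 0.98, 0.70, 0.99, "probability",
       "T3cD biomarker specificity"),
    tr("cancer_sensitivity", 0.32, 0.30, 0.70, "probability",
       "cancer-specific biomarker sensitivity"),
    tr("cancer_specificity", 0.95, 0.70, 0.99, "probability",
       "cancer-specific biomarker specificity"),
    tr("t3cd_incidence", 0.10, 0.05, 0.15, "proportion",
       "incidence of T3cD in new-onset diabetes"),
    tr("pdac_incidence", 0.010, 0.008, 0.012, "proportion",
       "incidence of PDAC in new-onset diabetes"),
    tr("pdac_incidence_general", 0.0002, 0.0001, 0.0003, "proportion",
       "incidence of PDAC in the general population"),
    tr("pdac_incidence_in_t3cd", 0.10, 0.05, 0.15, "proportion",
       "incidence of PDAC within T3cD"),
    tr("discount_rate", 0.035, 0.03, 0.04, "annual rate", "discount rate"),
    tr("dist_biomarker_resectable", 0.40, 0.35, 0.45, "proportion",
       "starting stage proportion, biomarker pathway, resectable"),
    tr("dist_biomarker_borderline_resectable", 0.25, 0.20, 0.30, "proportion",
       "starting stage proportion, biomarker pathway, borderline resectable"),
    tr("dist_biomarker_locally_advanced", 0.25, 0.20, 0.30, "proportion",
       "starting stage proportion, biomarker pathway, locally advanced"),
    tr("dist_biomarker_metastatic", 0.10, 0.05, 0.15, "proportion",
       "starting stage proportion, biomarker pathway, metastatic"),
    tr("dist_standard_resectable", 0.10, 0.05, 0.15, "proportion",
       "starting stage proportion, standard pathway, resectable"),
    tr("dist_standard_borderline_resectable", 0.15, 0.10, 0.20, "proportion",
       "starting stage proportion, standard pathway, borderline resectable"),
    tr("dist_standard_locally_advanced", 0.20, 0.15, 0.25, "proportion",
       "starting stage proportion, standard pathway, locally advanced"),
    tr("dist_standard_metastatic", 0.55, 0.50, 0.60, "proportion",
       "starting stage proportion, standard pathway, metastatic"),
    tr("median_survival_resectable", 3.7, 2.9, 4.5, "years",
       "median survival, resectable"),
    tr("median_survival_borderline_resectable", 1.4, 1.0, 1.8, "years",
       "median survival, borderline resectable"),
    tr("median_survival_locally_advanced", 1.3, 0.8, 1.8, "years",
       "median survival, locally advanced"),
    tr("median_survival_metastatic", 0.4, 0.2, 0.6, "years",
       "median survival, metastatic")
  )
}

.new_parameters <- function(values, ranges) {
  keys <- parameter_keys()
  stopifnot(all(keys %in% names(values)))
  values <- values[keys]
  sv <- function(suffix) unname(values[paste0(suffix, .stage_keys)])
  params <- structure(list(
    context = list(
      population_size = unname(values["population_size"]),
      t3cd_incidence = unname(values["t3cd_incidence"]),
      pdac_incidence = unname(values["pdac_incidence"]),
      pdac_incidence_general = unname(values["pdac_incidence_general"]),
      pdac_incidence_in_t3cd = unname(values["pdac_incidence_in_t3cd"]),
      t3cd_test_cost = unname(values["t3cd_test_cost"]),
      cancer_test_cost = unname(values["cancer_test_cost"]),
      diagnostic_cost_biomarker_path =
        unname(values["diagnostic_cost_biomarker_path"]),
      diagnostic_cost_standard_path =
        unname(values["diagnostic_cost_standard_path"])
    ),
    t3cd_test = test_performance(unname(values["t3cd_sensitivity"]),
                                 unname(values["t3cd_specificity"])),
    cancer_test = test_performance(unname(values["cancer_sensitivity"]),
                                   unname(values["cancer_specificity"])),
    stages = tibble::tibble(
      stage = .stage_keys,
      treatment_cost_biomarker = sv("treatment_cost_biomarker_"),
      treatment_cost_standard = sv("treatment_cost_standard_"),
      utility = sv("utility_"),
      median_survival = sv("median_survival_")
    ),
    dist_biomarker = stats::setNames(sv("dist_biomarker_"), .stage_keys),
    dist_standard = stats::setNames(sv("dist_standard_"), .stage_keys),
    econ = list(
      discount_rate = unname(values["discount_rate"]),
      wtp_threshold = unname(values["wtp_threshold"]),
      horizon = unname(values["horizon"]),
      cycle_length = 1,
      healthy_utility = unname(values["utility_healthy"]),
      death_utility = unname(values["utility_death"])
    ),
    ranges = ranges
  ), class = "pdac_parameters")
  params
}

#' Built-in base-case model parameters
#'
#' Returns the full published base case: biomarker test performance
#' (T3cD 0.80/0.98; cancer-specific 0.32/0.95), incidences (T3cD 10% of
#' new-onset diabetes, PDAC 1.0% of new-onset diabetes and 0.02% of the
#' general population, PDAC 10% of T3cD), per-stage treatment costs for both
#' care pathways, health utilities (0.86 healthy down to 0.76 metastatic, 0 at
#' death), median survival per stage (3.7/1.4/1.3/0.4 years), starting stage
#' distributions (biomarker 40/25/25/10, standard care 10/15/20/55), 3.5%
#' annual discounting, a 30 000 GBP/QALY willingness-to-pay threshold, a
#' 5-cycle (5-year) horizon, and all one-way sensitivity ranges.
#'
#' The metastatic treatment-cost upper range differs between pathways
#' (33 231 biomarker vs 32 231 standard); both are stored as published.
#'
#' @return A validated `pdac_parameters` object.
#' @examples
#' p <- default_parameters()
#' p$stages
#' @export
default_parameters <- function() {
  ranges <- .default_ranges()
  values <- c(population_size = 200000, horizon = 5, wtp_threshold = 30000,
              stats::setNames(ranges$base, ranges$name))
  params <- .new_parameters(values, ranges)
  validate_parameters(params, warn_consistency = FALSE)
}

#' Flatten parameters to the canonical named vector
#'
#' @param params A `pdac_parameters` object.
#' @return Named numeric vector over [parameter_keys()].
#' @export
params_to_vector <- function(params) {
  stopifnot(inherits(params, "pdac_parameters"))
  ctx <- params$context
  st <- params$stages
  v <- c(population_size = ctx$population_size,
         horizon = params$econ$horizon,
         wtp_threshold = params$econ$wtp_threshold,
         discount_rate = params$econ$discount_rate,
         t3cd_incidence = ctx$t3cd_incidence,
         pdac_incidence = ctx$pdac_incidence,
         pdac_incidence_general = ctx$pdac_incidence_general,
         pdac_incidence_in_t3cd = ctx$pdac_incidence_in_t3cd,
         t3cd_sensitivity = params$t3cd_test$sensitivity,
         t3cd_specificity = params$t3cd_test$specificity,
         cancer_sensitivity = params$cancer_test$sensitivity,
         cancer_specificity = params$cancer_test$specificity,
         t3cd_test_cost = ctx$t3cd_test_cost,
         cancer_test_cost = ctx$cancer_test_cost,
         diagnostic_cost_biomarker_path = ctx$diagnostic_cost_biomarker_path,
         diagnostic_cost_standard_path = ctx$diagnostic_cost_standard_path,
         utility_healthy = params$econ$healthy_utility,
         stats::setNames(st$utility, paste0("utility_", st$stage)),
         utility_death = params$econ$death_utility,
         stats::setNames(st$treatment_cost_biomarker,
                         paste0("treatment_cost_biomarker_", st$stage)),
         stats::setNames(st$treatment_cost_standard,
                         paste0("treatment_cost_standard_", st$stage)),
         stats::setNames(unname(params$dist_biomarker),
                         paste0("dist_biomarker_", names(params$dist_biomarker))),
         stats::setNames(unname(params$dist_standard),
                         paste0("dist_standard_", names(params$dist_standard))),
         stats::setNames(st$median_survival,
                         paste0("median_survival_", st$stage)))
  v[parameter_keys()]
}

#' Rebuild a parameter object from a canonical flat vector
#'
#' @param values Named numeric vector over [parameter_keys()].
#' @param ranges Optional sensitivity-range tibble; defaults to the built-in
#'   fixture ranges.
#' @return A `pdac_parameters` object (not re-validated).
#' @export
params_from_vector <- function(values, ranges = .default_ranges()) {
  .new_parameters(values, ranges)
}

#' Replace one scalar parameter by canonical key
#'
#' When a starting-stage proportion is set, the remaining three proportions of
#' the same distribution are rescaled so the distribution stays on the
#' simplex; this is the convention used by the one-way sensitivity analysis.
#'
#' @param params A `pdac_parameters` object.
#' @param name Canonical key, see [parameter_keys()].
#' @param value New value.
#' @param renormalize For `dist_*` keys, rescale the other components of the
#'   same stage distribution to `1 - value` (default `TRUE`).
#' @return Modified `pdac_parameters` object.
#' @export
set_parameter <- function(params, name, value, renormalize = TRUE) {
  v <- params_to_vector(params)
  if (!name %in% names(v)) {
    stop("unknown parameter '", name, "'", call. = FALSE)
  }
  if (renormalize && grepl("^dist_", name)) {
    group <- if (grepl("^dist_biomarker_", name)) "dist_biomarker_" else
      "dist_standard_"
    keys <- paste0(group, .stage_keys)
    others <- setdiff(keys, name)
    rest <- sum(v[others])
    if (rest > 0) v[others] <- v[others] * (1 - value) / rest
    v[name] <- value
  } else {
    v[name] <- value
  }
  params_from_vector(v, params$ranges)
}

.check_prob <- function(x, field) {
  if (is.na(x) || x < 0 || x > 1) {
    stop("parameter '", field, "' must lie in [0, 1], got ", x, call. = FALSE)
  }
}

.check_nonneg <- function(x, field) {
  if (is.na(x) || x < 0) {
    stop("parameter '", field, "' must be non-negative, got ", x,
         call. = FALSE)
  }
}

#' Validate a parameter set
#'
#' Checks every structural invariant: probabilities and utilities in
#' \[0, 1\], non-negative costs, positive median survivals, stage
#' distributions summing to one, horizon of at least one cycle, zero death
#' utility, and `low <= base <= high` for every sensitivity range. The
#' incidence identity `pdac_incidence = t3cd_incidence *
#' pdac_incidence_in_t3cd` is checked and warned on, never enforced, because
#' all three quantities are independent published inputs.
#'
#' @param params A `pdac_parameters` object.
#' @param warn_consistency Emit the incidence-identity warning (default TRUE).
#' @return `params`, invisibly unchanged, if valid; otherwise an error naming
#'   the offending field.
#' @export
validate_parameters <- function(params, warn_consistency = TRUE) {
  stopifnot(inherits(params, "pdac_parameters"))
  v <- params_to_vector(params)
  prob_keys <- c("t3cd_incidence", "pdac_incidence", "pdac_incidence_general",
                 "pdac_incidence_in_t3cd", "t3cd_sensitivity",
                 "t3cd_specificity", "cancer_sensitivity", "cancer_specificity",
                 grep("^utility_|^dist_", names(v), value = TRUE))
  for (k in prob_keys) .check_prob(v[[k]], k)
  for (k in grep("cost", names(v), value = TRUE)) .check_nonneg(v[[k]], k)
  for (k in paste0("median_survival_", .stage_keys)) {
    if (is.na(v[[k]]) || v[[k]] <= 0) {
      stop("parameter '", k, "' must be positive, got ", v[[k]], call. = FALSE)
    }
  }
  if (v[["population_size"]] <= 0) stop("population_size must be positive",
                                        call. = FALSE)
  if (v[["horizon"]] < 1) stop("horizon must be at least one cycle",
                               call. = FALSE)
  .check_nonneg(v[["discount_rate"]], "discount_rate")
  if (v[["utility_death"]] != 0) stop("utility_death must equal 0",
                                      call. = FALSE)
  for (grp in c("dist_biomarker_", "dist_standard_")) {
    s <- sum(v[paste0(grp, .stage_keys)])
    if (abs(s - 1) > 1e-9) {
      stop("stage distribution '", sub("_$", "", grp),
           "' must sum to 1 (got ", format(s, digits = 12), ")",
           call. = FALSE)
    }
  }
  rg <- params$ranges
  bad <- rg$low > rg$base | rg$base > rg$high
  if (any(bad)) {
    stop("sensitivity range for '", rg$name[which(bad)[1]],
         "' violates low <= base <= high", call. = FALSE)
  }
  unknown <- setdiff(rg$name, names(v))
  if (length(unknown) > 0) {
    stop("range refers to unknown parameter '", unknown[1], "'",
         call. = FALSE)
  }
  if (warn_consistency) {
    implied <- v[["t3cd_incidence"]] * v[["pdac_incidence_in_t3cd"]]
    if (abs(implied - v[["pdac_incidence"]]) > 1e-9) {
      warning(sprintf(
        "pdac_incidence (%g) differs from t3cd_incidence * pdac_incidence_in_t3cd (%g)",
        v[["pdac_incidence"]], implied), call. = FALSE)
    }
  }
  invisible(params)
}

# Accept either a bare number (proportion) or list(value = 3.5, unit =
# "percent") -- guards against the classic 100x error on Table-style percent
# rows.
.config_scalar <- function(x, key) {
  if (is.list(x)) {
    if (is.null(x$value) || is.null(x$unit)) {
      stop("config entry '", key,
           "' must be a number or a {value, unit} pair", call. = FALSE)
    }
    val <- as.numeric(x$value)
    switch(as.character(x$unit),
           percent = val / 100,
           proportion = val,
           stop("config entry '", key, "' has unknown unit '", x$unit,
                "'", call. = FALSE))
  } else {
    if (!is.numeric(x) || length(x) != 1L) {
      stop("config entry '", key, "' must be a single number", call. = FALSE)
    }
    as.numeric(x)
  }
}

#' Load model parameters from a configuration file
#'
#' The configuration is a flat YAML document keyed by the canonical parameter
#' names (see [parameter_keys()]); any key that is omitted falls back to the
#' built-in base-case fixture. Percent-scaled entries may be written as
#' `{value: 3.5, unit: percent}`. Sensitivity ranges may be overridden under a
#' `ranges:` map of `key: {low: ..., high: ...}` entries.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `pdac_parameters` object.
#' @seealso [write_parameters()] for the inverse, [default_parameters()] for
#'   the fixture.
#' @examples
#' cfg <- system.file("extdata", "example-config.yaml",
#'                    package = "pdacscreen")
#' load_parameters(cfg)$cancer_test
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  defaults <- default_parameters()
  v <- params_to_vector(defaults)
  ranges <- defaults$ranges
  reserved <- c("schema_version", "ranges")
  unknown <- setdiff(names(cfg), c(names(v), reserved))
  if (length(unknown) > 0) {
    stop("unknown key '", unknown[1], "' in config ", path, call. = FALSE)
  }
  for (key in setdiff(names(cfg), reserved)) {
    v[key] <- .config_scalar(cfg[[key]], key)
  }
  if (!is.null(cfg$ranges)) {
    for (key in names(cfg$ranges)) {
      if (!key %in% ranges$name) {
        stop("range override for unknown parameter '", key, "'",
             call. = FALSE)
      }
      entry <- cfg$ranges[[key]]
      i <- match(key, ranges$name)
      if (!is.null(entry$low)) ranges$low[i] <- as.numeric(entry$low)
      if (!is.null(entry$high)) ranges$high[i] <- as.numeric(entry$high)
      ranges$base[i] <- v[[key]]
    }
  }
  # keep range base columns in step with any overridden scalar
  ranges$base <- unname(v[ranges$name])
  validate_parameters(params_from_vector(v, ranges))
}

#' Write model parameters to a configuration file
#'
#' Writes the flat canonical-key YAML document (with a `schema_version` key
#' and the sensitivity ranges) such that [load_parameters()] reproduces the
#' same parameter set.
#'
#' @param params A `pdac_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params, warn_consistency = FALSE)
  v <- params_to_vector(params)
  cfg <- c(list(schema_version = 1L),
           stats::setNames(as.list(unname(v)), names(v)))
  rg <- params$ranges
  cfg$ranges <- stats::setNames(
    purrr::map2(rg$low, rg$high, ~ list(low = .x, high = .y)), rg$name)
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' Tabulate all parameters with their sensitivity ranges
#'
#' @param params A `pdac_parameters` object.
#' @return Tibble with columns `name`, `base`, `low`, `high`, `units`,
#'   `source`. Parameters without a published range (cohort size, horizon,
#'   willingness-to-pay threshold) are listed with degenerate ranges.
#' @export
parameter_table <- function(params = default_parameters()) {
  v <- params_to_vector(params)
  fixed <- tibble::tibble(
    name = c("population_size", "horizon", "wtp_threshold"),
    base = unname(v[c("population_size", "horizon", "wtp_threshold")]),
    low = base, high = base,
    units = c("persons", "cycles", "GBP/QALY"),
    source = c("simulated cohort size", "time horizon",
               "willingness-to-pay threshold"))
  rg <- params$ranges
  rg$base <- unname(v[rg$name])
  dplyr::bind_rows(fixed, rg)
}

#' Export the parameter table as CSV
#'
#' @param params A `pdac_parameters` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_parameter_table <- function(params, path) {
  utils::write.csv(parameter_table(params), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.pdac_parameters <- function(x, ...) {
  v <- params_to_vector(x)
  cat("<pdac_parameters>\n")
  cat(sprintf("  cohort: %s persons with new-onset diabetes, horizon %d x %g y, discount %.1f%%\n",
              format(v[["population_size"]], big.mark = " "),
              as.integer(v[["horizon"]]), x$econ$cycle_length,
              100 * v[["discount_rate"]]))
  cat(sprintf("  incidence: T3cD %.1f%% | PDAC %.2f%% (general %.2f%%) | PDAC in T3cD %.1f%%\n",
              100 * v[["t3cd_incidence"]], 100 * v[["pdac_incidence"]],
              100 * v[["pdac_incidence_general"]],
              100 * v[["pdac_incidence_in_t3cd"]]))
  cat(sprintf("  tests: T3cD Se/Sp %.2f/%.2f @ GBP %g | cancer Se/Sp %.2f/%.2f @ GBP %g\n",
              v[["t3cd_sensitivity"]], v[["t3cd_specificity"]],
              v[["t3cd_test_cost"]], v[["cancer_sensitivity"]],
              v[["cancer_specificity"]], v[["cancer_test_cost"]]))
  cat(sprintf("  WTP threshold: GBP %s per QALY\n",
              format(v[["wtp_threshold"]], big.mark = " ")))
  cat("  stages:\n")
  print(x$stages)
  invisible(x)
}

#' Report-time currency annotation
#'
#' Stored values are GBP throughout; this helper converts for display only
#' using a constant factor (default the published 1 GBP = 1.34 USD).
#'
#' @param x Amount in GBP.
#' @param rate USD per GBP.
#' @return Amount in USD.
#' @export
gbp_to_usd <- function(x, rate = 1.34) x * rate
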