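# Canonical run outputs: manifest-stamped CSV/JSON files per analysis. GBP
# is the stored currency everywhere; the USD factor only annotates reports.

#' Run manifest
#'
#' Provenance record written next to every canonical output: the command,
#' an MD5 digest of the canonical parameter configuration, the seed, the
#' accrual-convention fingerprint, the package version and a timestamp.
#'
#' @param command Short command name (e.g. `"base_case"`).
#' @param params A `pdac_parameters` object.
#' @param seed Seed used, or `NA` for deterministic runs.
#' @param convention An [accrual_convention()], or `NULL`.
#' @param usd_per_gbp Report-time currency annotation (never applied to
#'   stored values).
#' @return A `pdac_manifest` list.
#' @export
run_manifest <- function(command, params, seed = NA,
                         convention = NULL, usd_per_gbp = 1.34) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_parameters(params, tmp)
  structure(list(
    command = command,
    config_hash = unname(tools::md5sum(tmp)),
    seed = seed,
    convention = if (is.null(convention)) NA_character_ else
      convention_fingerprint(convention),
    usd_per_gbp = usd_per_gbp,
    package_version = as.character(utils::packageVersion("pdacscreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "pdac_manifest")
}

.write_manifest <- function(manifest, out_dir) {
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA)
  path
}

.ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir, call. = FALSE)
  }
  invisible(out_dir)
}

#' Write the base-case report
#'
#' Writes the cascade summary (CSV), per-strategy outcomes and incremental
#' results (CSV + JSON) and a manifest into `out_dir`.
#'
#' @param params A `pdac_parameters` object.
#' @param out_dir Output directory (created if absent).
#' @param strategies Strategies to report.
#' @param convention An [accrual_convention()].
#' @param population `"new_onset_diabetes"` or `"general"`.
#' @param quiet Suppress progress messages.
#' @return Named character vector of file paths, invisibly.
#' @export
write_base_case_report <- function(params, out_dir,
                                   strategies = c("cancer_specific", "t3cd",
                                                  "combination"),
                                   convention = calibrated_convention(),
                                   population = "new_onset_diabetes",
                                   quiet = FALSE) {
  .ensure_dir(out_dir)
  say <- function(...) if (!quiet) message(...)
  say("base case: convention ", convention_fingerprint(convention))
  if (population == "new_onset_diabetes") {
    casc <- cascade_summary(params)
    casc_path <- file.path(out_dir, "cascade_summary.csv")
    export_cascade_csv(casc, casc_path)
  } else {
    casc_path <- NULL
  }
  bc <- base_case(params, strategies, convention, population)
  bc_path <- file.path(out_dir, "base_case.csv")
  utils::write.csv(as.data.frame(bc), bc_path, row.names = FALSE)
  ce_path <- file.path(out_dir, "ce_results.json")
  jsonlite::write_json(as.data.frame(bc), ce_path, digits = NA)
  man <- run_manifest("base_case", params, convention = convention)
  man_path <- .write_manifest(man, out_dir)
  say("base case: ICERs ",
      paste(sprintf("%s %.0f", bc$strategy, bc$icer), collapse = " | "))
  invisible(c(cascade = casc_path, base_case = bc_path, ce = ce_path,
              manifest = man_path))
}

#' Write a tornado (one-way DSA) report
#'
#' @inheritParams write_base_case_report
#' @param strategy Strategy analysed.
#' @return Named character vector of file paths, invisibly.
#' @export
write_dsa_report <- function(params, out_dir, strategy = "combination",
                             convention = calibrated_convention(),
                             quiet = FALSE) {
  .ensure_dir(out_dir)
  dsa <- one_way_dsa(params, strategy, convention)
  path <- file.path(out_dir, paste0("tornado_", strategy, ".csv"))
  utils::write.csv(as.data.frame(dsa), path, row.names = FALSE)
  man_path <- .write_manifest(
    run_manifest(paste0("dsa_", strategy), params,
                 convention = convention), out_dir)
  if (!quiet) {
    message("dsa: top parameter for ", strategy, " is ", dsa$parameter[1])
  }
  invisible(c(tornado = path, manifest = man_path))
}

#' Write a PSA report
#'
#' Writes the per-draw CSV, the acceptability curve CSV, a JSON summary and
#' a manifest.
#'
#' @inheritParams write_base_case_report
#' @param strategy Strategy analysed.
#' @param n_sims,seed Simulation size and master seed.
#' @param wtp_grid Acceptability-curve grid.
#' @return Named character vector of file paths, invisibly.
#' @export
write_psa_report <- function(params, out_dir, strategy = "cancer_specific",
                             n_sims = 10000, seed = 1,
                             convention = calibrated_convention(),
                             wtp_grid = seq(0, 100000, by = 2500),
                             quiet = FALSE) {
  .ensure_dir(out_dir)
  psa <- run_psa(params, strategy, n_sims = n_sims, seed = seed,
                 convention = convention)
  draws_path <- file.path(out_dir, paste0("psa_draws_", strategy, ".csv"))
  utils::write.csv(as.data.frame(psa$draws), draws_path, row.names = FALSE)
  ceac <- compute_ceac(psa, wtp_grid)
  ceac_path <- file.path(out_dir, paste0("ceac_", strategy, ".csv"))
  utils::write.csv(as.data.frame(ceac), ceac_path, row.names = FALSE)
  sum_path <- file.path(out_dir, paste0("psa_summary_", strategy, ".json"))
  jsonlite::write_json(list(strategy = strategy, n_sims = n_sims,
                            seed = seed, wtp = psa$wtp,
                            fraction_cost_effective =
                              psa$fraction_cost_effective),
                       sum_path, auto_unbox = TRUE, digits = NA)
  man_path <- .write_manifest(
    run_manifest(paste0("psa_", strategy), params, seed = seed,
                 convention = convention), out_dir)
  if (!quiet) {
    message(sprintf("psa: %s cost-effective in %.1f%% of %d draws",
                    strategy, 100 * psa$fraction_cost_effective, n_sims))
  }
  invisible(c(draws = draws_path, ceac = ceac_path, summary = sum_path,
              manifest = man_path))
}

#' Write a microsimulation report
#'
#' Writes the individual-level cohort CSV (gzip), the empirical summary and
#' oracle z-score report, and a manifest.
#'
#' @inheritParams write_base_case_report
#' @param strategy Strategy simulated.
#' @param n,seed Cohort size and seed.
#' @return Named character vector of file paths, invisibly.
#' @export
write_microsim_report <- function(params, out_dir, strategy = "t3cd",
                                  n = 200000, seed = 1,
                                  convention = default_convention(),
                                  quiet = FALSE) {
  .ensure_dir(out_dir)
  sim <- simulate_cohort(params, strategy, n = n, seed = seed,
                         convention = convention)
  cohort_path <- file.path(out_dir, paste0("cohort_", strategy, ".csv.gz"))
  export_cohort_csv(sim, cohort_path)
  rep <- oracle_check(sim)
  rep_path <- file.path(out_dir, paste0("oracle_report_", strategy, ".csv"))
  utils::write.csv(as.data.frame(rep), rep_path, row.names = FALSE)
  man_path <- .write_manifest(
    run_manifest(paste0("microsim_", strategy), params, seed = seed,
                 convention = convention), out_dir)
  if (!quiet) {
    message(sprintf("microsim: %s n=%d, max |z| = %.2f (%s)", strategy, n,
                    max(abs(rep$z)),
                    if (attr(rep, "all_pass")) "pass" else "FAIL"))
  }
  invisible(c(cohort = cohort_path, oracle = rep_path,
              manifest = man_path))
}
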