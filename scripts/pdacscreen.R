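#!/usr/bin/env Rscript
# Thin command-line wrapper over the pdacscreen package.
#
# Usage:
#   Rscript scripts/pdacscreen.R <command> [options]
#
# Commands:
#   base-case     cascade table, per-strategy outcomes, incremental results
#   dsa           one-way (tornado) sensitivity analysis
#   psa           probabilistic sensitivity analysis + acceptability curve
#   head-to-head  common-random-number comparison of two strategies
#   two-way       two-parameter grid analysis
#   microsim      individual-level cohort simulation + oracle report
#   export-params parameter table CSV and canonical config YAML
#
# Global options: --config <yaml> --out <dir> --seed <int>
#                 --strategy <name> --n-sims <int> --n <int>
#                 --convention <default|calibrated> --wtp <gbp>

suppressPackageStartupMessages({
  library(optparse)
  library(pdacscreen)
})

spec <- list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML parameter config (defaults to built-in fixture)"),
  make_option("--out", type = "character", default = "pdacscreen_out",
              help = "output directory [default %default]"),
  make_option("--seed", type = "integer", default = 1,
              help = "random seed [default %default]"),
  make_option("--strategy", type = "character", default = "combination",
              help = "screening strategy [default %default]"),
  make_option("--strategy-b", type = "character",
              default = "cancer_specific",
              help = "second strategy for head-to-head [default %default]"),
  make_option("--n-sims", type = "integer", default = 10000,
              help = "PSA simulations [default %default]"),
  make_option("--n", type = "integer", default = 200000,
              help = "microsimulation cohort size [default %default]"),
  make_option("--convention", type = "character", default = "calibrated",
              help = "accrual convention: calibrated or default"),
  make_option("--wtp", type = "double", default = NA,
              help = "willingness-to-pay threshold (GBP/QALY)"),
  make_option("--param-x", type = "character",
              default = "cancer_sensitivity", help = "two-way x parameter"),
  make_option("--param-y", type = "character",
              default = "cancer_specificity", help = "two-way y parameter"),
  make_option("--general-population", action = "store_true",
              default = FALSE,
              help = "use the general-population PDAC incidence")
)

parser <- OptionParser(
  usage = "%prog <base-case|dsa|psa|head-to-head|two-way|microsim|export-params> [options]",
  option_list = spec)
parsed <- parse_args(parser, positional_arguments = 1)
cmd <- parsed$args
opt <- parsed$options

params <- if (is.null(opt$config)) {
  message("config: built-in base-case fixture")
  default_parameters()
} else {
  message("config: ", opt$config)
  load_parameters(opt$config)
}
conv <- switch(opt$convention,
               calibrated = calibrated_convention(),
               default = default_convention(),
               stop("--convention must be 'calibrated' or 'default'"))
if (!is.na(opt$wtp)) params$econ$wtp_threshold <- opt$wtp
population <- if (opt[["general-population"]]) "general" else
  "new_onset_diabetes"
message("convention: ", convention_fingerprint(conv))

status <- tryCatch({
  switch(cmd,
    "base-case" = write_base_case_report(params, opt$out,
                                         convention = conv,
                                         population = population),
    "dsa" = write_dsa_report(params, opt$out, strategy = opt$strategy,
                             convention = conv),
    "psa" = write_psa_report(params, opt$out, strategy = opt$strategy,
                             n_sims = opt[["n-sims"]], seed = opt$seed,
                             convention = conv),
    "head-to-head" = {
      hh <- head_to_head(params, opt$strategy, opt[["strategy-b"]],
                         n_sims = opt[["n-sims"]], seed = opt$seed,
                         convention = conv)
      dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(as.data.frame(tidy(hh)),
                       file.path(opt$out, "head_to_head_draws.csv"),
                       row.names = FALSE)
      jsonlite::write_json(glance(hh),
                           file.path(opt$out, "head_to_head.json"),
                           auto_unbox = TRUE, digits = NA)
      print(hh)
    },
    "two-way" = {
      tw <- two_way_grid(params, opt$strategy, opt[["param-x"]],
                         opt[["param-y"]], convention = conv)
      dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(as.data.frame(tw),
                       file.path(opt$out, "two_way_grid.csv"),
                       row.names = FALSE)
    },
    "microsim" = write_microsim_report(params, opt$out,
                                       strategy = opt$strategy, n = opt$n,
                                       seed = opt$seed),
    "export-params" = {
      dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
      export_parameter_table(params,
                             file.path(opt$out, "parameters.csv"))
      write_parameters(params, file.path(opt$out, "parameters.yaml"))
    },
    {
      print_help(parser)
      stop("unknown command: ", cmd)
    })
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  1L
})
quit(status = status)
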