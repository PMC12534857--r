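# One-way (tornado) and two-way deterministic sensitivity analysis, Monte
# Carlo probabilistic sensitivity analysis, acceptability curves, and the
# head-to-head strategy comparison under common random numbers.

# assign one canonical key into a flat vector, keeping stage distributions
# on the simplex by rescaling the untouched components
.assign_flat <- function(v, name, value) {
  if (grepl("^dist_", name)) {
    group <- if (grepl("^dist_biomarker_", name)) "dist_biomarker_" else
      "dist_standard_"
    others <- setdiff(paste0(group, .stage_keys), name)
    rest <- sum(v[others])
    if (rest > 0) v[others] <- v[others] * (1 - value) / rest
  }
  v[name] <- value
  v
}

.ce_from_matrix <- function(V, strategy, convention, wtp,
                            population = "new_onset_diabetes") {
  res <- .engine(V, strategy, convention, population)
  .ce_columns(res$cost - res$comparator_cost,
              res$qalys - res$comparator_qalys,
              res$life_years - res$comparator_life_years, wtp)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-evaluates the incremental cost-effectiveness ratio of a strategy
#' against standard care with each ranged parameter set to its low and high
#' bound in turn, all other parameters at base. When a starting-stage
#' proportion is varied, the other three proportions of that distribution
#' are rescaled to keep the simplex. Entries are ranked by descending ICER
#' bar width; parameters with a degenerate (zero-width) range produce
#' zero-width bars and rank last.
#'
#' The T3cD enrichment share (`t3cd_incidence`) is treated as structural in
#' the one-way analysis by default: the T3cD-led strategies are *defined* as
#' screening the roughly 10% pancreatogenic subgroup, so varying the share
#' redefines the screened population rather than perturbing a model input
#' (PDAC risk within that subgroup is varied through
#' `pdac_incidence_in_t3cd`). Pass `parameters` explicitly to vary it
#' anyway.
#'
#' @param params A `pdac_parameters` object.
#' @param strategy Screening strategy compared against standard care.
#' @param convention An [accrual_convention()].
#' @param wtp Willingness-to-pay threshold; defaults to the parameter set's.
#' @param parameters Canonical keys to vary; defaults to every ranged
#'   parameter except `t3cd_incidence`.
#' @return A `pdac_tornado` tibble: `parameter`, `low`, `high`,
#'   `icer_at_low`, `icer_at_high`, `nmb_at_low`, `nmb_at_high`,
#'   `bar_width`, `rank`, `icer_undefined` (flag set when an endpoint gives
#'   zero incremental QALYs). Attribute `"base_icer"` holds the base-case
#'   ICER.
#' @examples
#' dsa <- one_way_dsa(default_parameters(), "cancer_specific",
#'                    calibrated_convention())
#' head(dsa, 5)
#' @export
one_way_dsa <- function(params, strategy = c("cancer_specific", "t3cd",
                                             "combination"),
                        convention = default_convention(), wtp = NULL,
                        parameters = NULL) {
  strategy <- match.arg(strategy)
  validate_parameters(params, warn_consistency = FALSE)
  if (is.null(wtp)) wtp <- params$econ$wtp_threshold
  v <- params_to_vector(params)
  rg <- params$ranges
  if (is.null(parameters)) {
    parameters <- setdiff(rg$name, "t3cd_incidence")
  }
  missing <- setdiff(parameters, rg$name)
  if (length(missing) > 0) {
    stop("no sensitivity range for parameter '", missing[1], "'",
         call. = FALSE)
  }
  rg <- rg[rg$name %in% parameters, ]
  V <- matrix(rep(v, each = 2 * nrow(rg)), nrow = 2 * nrow(rg),
              dimnames = list(NULL, names(v)))
  for (i in seq_len(nrow(rg))) {
    V[2 * i - 1, ] <- .assign_flat(v, rg$name[i], rg$low[i])
    V[2 * i, ] <- .assign_flat(v, rg$name[i], rg$high[i])
  }
  ce <- .ce_from_matrix(V, strategy, convention, wtp)
  lo <- ce[seq(1, nrow(ce), by = 2), ]
  hi <- ce[seq(2, nrow(ce), by = 2), ]
  base_ce <- .ce_from_matrix(v, strategy, convention, wtp)
  out <- tibble::tibble(
    parameter = rg$name, low = rg$low, high = rg$high,
    icer_at_low = lo$icer, icer_at_high = hi$icer,
    nmb_at_low = lo$nmb, nmb_at_high = hi$nmb,
    bar_width = abs(hi$icer - lo$icer),
    icer_undefined = is.na(lo$icer) | is.na(hi$icer))
  out <- dplyr::arrange(out, dplyr::desc(!is.na(.data$bar_width)),
                        dplyr::desc(.data$bar_width))
  out$rank <- seq_len(nrow(out))
  structure(out, class = c("pdac_tornado", class(out)),
            strategy = strategy, base_icer = base_ce$icer, wtp = wtp,
            convention = convention_fingerprint(convention))
}

#' Sampling distributions for the probabilistic sensitivity analysis
#'
#' The published analysis states only that all parameters were varied
#' simultaneously over 10 000 simulations; the distribution families are
#' unstated. The default assigns each ranged parameter an independent
#' uniform distribution on its published (low, high) range — the only family
#' fully determined by the printed ranges. `families = "beta_gamma"`
#' instead moment-matches a beta distribution (probabilities, utilities,
#' proportions; mean at base, sd a quarter of the range, rescaled to the
#' range) and a gamma distribution (costs, survival medians; mean at base,
#' sd a quarter of the range). Degenerate ranges are held fixed.
#'
#' @param params A `pdac_parameters` object.
#' @param families `"uniform"` (default), `"beta_gamma"`, or
#'   `"triangular"` (mode at base).
#' @return Tibble with columns `parameter`, `family`, `low`, `high`, `base`.
#' @export
psa_distributions <- function(params,
                              families = c("uniform", "beta_gamma",
                                           "triangular")) {
  families <- match.arg(families)
  rg <- params$ranges
  v <- params_to_vector(params)
  rg$base <- unname(v[rg$name])
  fam <- rep(switch(families, uniform = "uniform",
                    triangular = "triangular", beta_gamma = NA_character_),
             nrow(rg))
  if (families == "beta_gamma") {
    fam <- ifelse(rg$units %in% c("probability", "utility", "proportion"),
                  "beta", "gamma")
  }
  fam[rg$high == rg$low] <- "fixed"
  tibble::tibble(parameter = rg$name, family = fam, low = rg$low,
                 high = rg$high, base = rg$base)
}

.validate_psa_spec <- function(spec, v) {
  needed <- c("parameter", "family", "low", "high", "base")
  if (!all(needed %in% names(spec))) {
    stop("PSA spec must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(spec$parameter, names(v))
  if (length(unknown) > 0) {
    stop("PSA spec refers to unknown parameter '", unknown[1], "'",
         call. = FALSE)
  }
  bad_fam <- setdiff(spec$family, c("uniform", "beta", "gamma",
                                    "triangular", "fixed"))
  if (length(bad_fam) > 0) {
    stop("unknown PSA distribution family '", bad_fam[1], "'",
         call. = FALSE)
  }
  if (any(spec$low > spec$base | spec$base > spec$high)) {
    stop("PSA spec violates low <= base <= high", call. = FALSE)
  }
  invisible(spec)
}

# deterministic per-parameter substream so that adding a parameter to the
# spec does not perturb the draws of the others
.substream_seed <- function(seed, name) {
  bytes <- utf8ToInt(name)
  h <- sum(bytes * seq_along(bytes)) %% 1048573
  as.integer(((as.numeric(seed) %% 2147483647) * 1009 + h * 7919) %%
               2147483647)
}

.quantile_draw <- function(u, family, low, high, base) {
  width <- high - low
  if (family == "fixed" || width <= 0) return(rep(base, length(u)))
  switch(family,
         uniform = low + u * width,
         triangular = {
           cc <- (base - low) / width
           ifelse(u < cc,
                  low + sqrt(u * width * (base - low)),
                  high - sqrt((1 - u) * width * (high - base)))
         },
         beta = {
           m <- (base - low) / width
           vv <- 1 / 16  # sd = width / 4, on the unit scale
           if (vv >= m * (1 - m)) return(low + u * width)  # fall back
           k <- m * (1 - m) / vv - 1
           low + width * stats::qbeta(u, m * k, (1 - m) * k)
         },
         gamma = {
           sd <- width / 4
           if (base <= 0 || sd <= 0) return(rep(base, length(u)))
           shape <- (base / sd)^2
           stats::qgamma(u, shape = shape, rate = base / sd^2)
         })
}

# n_sims x parameters matrix of joint draws (common random numbers are
# obtained by reusing the same seed and spec)
.psa_draws <- function(params, spec, n_sims, seed) {
  v <- params_to_vector(params)
  .validate_psa_spec(spec, v)
  V <- matrix(rep(v, each = n_sims), nrow = n_sims,
              dimnames = list(NULL, names(v)))
  for (i in seq_len(nrow(spec))) {
    if (spec$family[i] == "fixed") next
    set.seed(.substream_seed(seed, spec$parameter[i]))
    u <- stats::runif(n_sims)
    V[, spec$parameter[i]] <- .quantile_draw(u, spec$family[i],
                                             spec$low[i], spec$high[i],
                                             spec$base[i])
  }
  # componentwise draws leave the simplex; rescale proportionally
  for (grp in c("dist_biomarker_", "dist_standard_")) {
    keys <- paste0(grp, .stage_keys)
    V[, keys] <- V[, keys] / rowSums(V[, keys])
  }
  V
}

#' Probabilistic sensitivity analysis
#'
#' Draws all ranged parameters jointly from their sampling distributions and
#' re-evaluates the full model per draw, recording the cost-effectiveness
#' plane coordinates, ICER and net monetary benefit of the strategy against
#' standard care. Each parameter has its own reproducible random substream
#' derived from the master seed, so the same seed always reproduces the
#' identical result and adding a parameter does not perturb the others'
#' draws.
#'
#' @param params A `pdac_parameters` object.
#' @param strategy Screening strategy compared against standard care.
#' @param n_sims Number of simulations (the published analysis used 10 000).
#' @param seed Master seed.
#' @param spec Distribution spec from [psa_distributions()].
#' @param convention An [accrual_convention()].
#' @param wtp Willingness-to-pay threshold; defaults to the parameter set's.
#' @return A `pdac_psa` object; `tidy()` returns the per-draw tibble,
#'   `glance()` the one-row summary, `autoplot()` the cost-effectiveness
#'   plane.
#' @examples
#' psa <- run_psa(default_parameters(), "cancer_specific", n_sims = 200,
#'                seed = 1)
#' glance(psa)
#' @export
run_psa <- function(params, strategy = c("cancer_specific", "t3cd",
                                         "combination"),
                    n_sims = 10000, seed = 1,
                    spec = psa_distributions(params),
                    convention = default_convention(), wtp = NULL) {
  strategy <- match.arg(strategy)
  validate_parameters(params, warn_consistency = FALSE)
  if (!is.numeric(n_sims) || n_sims < 1) {
    stop("n_sims must be at least 1", call. = FALSE)
  }
  if (is.null(wtp)) wtp <- params$econ$wtp_threshold
  V <- .psa_draws(params, spec, n_sims, seed)
  ce <- .ce_from_matrix(V, strategy, convention, wtp)
  draws <- dplyr::bind_cols(tibble::tibble(sim = seq_len(n_sims)), ce)
  structure(list(draws = draws, n_sims = n_sims, seed = seed,
                 strategy = strategy, wtp = wtp, spec = spec,
                 convention = convention_fingerprint(convention),
                 fraction_cost_effective = mean(draws$cost_effective)),
            class = "pdac_psa")
}

#' @export
print.pdac_psa <- function(x, ...) {
  cat(sprintf(
    "<pdac_psa> %s vs standard care: %d draws (seed %d)\n  %.1f%% cost-effective at WTP %s GBP/QALY\n",
    x$strategy, x$n_sims, x$seed, 100 * x$fraction_cost_effective,
    format(x$wtp, big.mark = " ")))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with
#' positive net monetary benefit.
#'
#' @param psa A `pdac_psa` object.
#' @param wtp_grid Vector of willingness-to-pay values (GBP/QALY).
#' @return A `pdac_ceac` tibble with columns `wtp`, `probability`.
#' @export
compute_ceac <- function(psa, wtp_grid = seq(0, 100000, by = 2500)) {
  stopifnot(inherits(psa, "pdac_psa"))
  if (length(wtp_grid) < 1) stop("wtp_grid must be non-empty",
                                 call. = FALSE)
  probs <- vapply(wtp_grid, function(l) {
    mean(l * psa$draws$delta_qalys - psa$draws$delta_cost > 0)
  }, numeric(1))
  structure(tibble::tibble(wtp = wtp_grid, probability = probs),
            class = c("pdac_ceac", "tbl_df", "tbl", "data.frame"),
            strategy = psa$strategy)
}

#' Head-to-head probabilistic comparison of two strategies
#'
#' Evaluates both strategies against standard care on the *same* joint
#' parameter draws (common random numbers) and classifies each draw by which
#' strategy achieves the more favourable incremental cost-effectiveness
#' ratio against standard care (a dominant strategy wins outright; net
#' monetary benefit breaks the comparison when an ICER is undefined). The
#' two preference fractions partition the draws. The marginal fraction of
#' draws in which each strategy is itself cost-effective at the
#' willingness-to-pay threshold is reported alongside.
#'
#' @param params A `pdac_parameters` object.
#' @param strategy_a,strategy_b Strategies to compare.
#' @inheritParams run_psa
#' @return A `pdac_head_to_head` object with preference fractions
#'   `fraction_a`/`fraction_b`, marginal cost-effectiveness fractions
#'   `fraction_a_ce`/`fraction_b_ce`, and the per-draw tibble `draws`.
#' @export
head_to_head <- function(params, strategy_a = "t3cd",
                         strategy_b = "cancer_specific",
                         n_sims = 10000, seed = 1,
                         spec = psa_distributions(params),
                         convention = default_convention(), wtp = NULL) {
  validate_parameters(params, warn_consistency = FALSE)
  if (is.null(wtp)) wtp <- params$econ$wtp_threshold
  V <- .psa_draws(params, spec, n_sims, seed)
  ce_a <- .ce_from_matrix(V, strategy_a, convention, wtp)
  ce_b <- .ce_from_matrix(V, strategy_b, convention, wtp)
  both_icer <- !is.na(ce_a$icer) & !is.na(ce_b$icer) &
    ce_a$delta_qalys > 0 & ce_b$delta_qalys > 0
  a_dominant <- ce_a$dominance == "intervention_dominant"
  b_dominant <- ce_b$dominance == "intervention_dominant"
  a_preferred <- ifelse(a_dominant & !b_dominant, TRUE,
                        ifelse(b_dominant & !a_dominant, FALSE,
                               ifelse(both_icer, ce_a$icer < ce_b$icer,
                                      ce_a$nmb > ce_b$nmb)))
  draws <- tibble::tibble(sim = seq_len(n_sims),
                          icer_a = ce_a$icer, icer_b = ce_b$icer,
                          nmb_a = ce_a$nmb, nmb_b = ce_b$nmb,
                          a_preferred = a_preferred,
                          cost_effective_a = ce_a$cost_effective,
                          cost_effective_b = ce_b$cost_effective)
  structure(list(strategy_a = strategy_a, strategy_b = strategy_b,
                 fraction_a = mean(a_preferred),
                 fraction_b = mean(!a_preferred),
                 fraction_a_ce = mean(draws$cost_effective_a),
                 fraction_b_ce = mean(draws$cost_effective_b),
                 draws = draws, n_sims = n_sims, seed = seed, wtp = wtp,
                 convention = convention_fingerprint(convention)),
            class = "pdac_head_to_head")
}

#' @export
print.pdac_head_to_head <- function(x, ...) {
  cat(sprintf(
    "<pdac_head_to_head> %d common-random-number draws (seed %d)\n  preferred: %s %.1f%% | %s %.1f%%\n  cost-effective vs standard care: %s %.1f%% | %s %.1f%%\n",
    x$n_sims, x$seed, x$strategy_a, 100 * x$fraction_a, x$strategy_b,
    100 * x$fraction_b, x$strategy_a, 100 * x$fraction_a_ce, x$strategy_b,
    100 * x$fraction_b_ce))
  invisible(x)
}

#' Two-way deterministic sensitivity analysis
#'
#' Full-factorial re-evaluation of a strategy over a grid of two parameters
#' (all others at base), from which the cost-effectiveness frontier can be
#' read off.
#'
#' @param params A `pdac_parameters` object.
#' @param strategy Screening strategy compared against standard care.
#' @param param_x,param_y Canonical parameter keys.
#' @param x_values,y_values Grid values; default to `n_grid` equally spaced
#'   points over each parameter's sensitivity range.
#' @param n_grid Grid resolution per axis when values are not supplied.
#' @param convention An [accrual_convention()].
#' @param wtp Willingness-to-pay threshold; defaults to the parameter set's.
#' @return A `pdac_two_way` tibble with columns `x`, `y`, the incremental
#'   statistics and the `cost_effective` flag.
#' @export
two_way_grid <- function(params, strategy, param_x, param_y,
                         x_values = NULL, y_values = NULL, n_grid = 21,
                         convention = default_convention(), wtp = NULL) {
  validate_parameters(params, warn_consistency = FALSE)
  if (is.null(wtp)) wtp <- params$econ$wtp_threshold
  v <- params_to_vector(params)
  rg <- params$ranges
  grid_default <- function(key) {
    i <- match(key, rg$name)
    if (is.na(i)) stop("parameter '", key, "' has no sensitivity range",
                       call. = FALSE)
    seq(rg$low[i], rg$high[i], length.out = n_grid)
  }
  if (is.null(x_values)) x_values <- grid_default(param_x)
  if (is.null(y_values)) y_values <- grid_default(param_y)
  grid <- expand.grid(x = x_values, y = y_values)
  V <- matrix(rep(v, each = nrow(grid)), nrow = nrow(grid),
              dimnames = list(NULL, names(v)))
  for (i in seq_len(nrow(grid))) {
    vi <- .assign_flat(v, param_x, grid$x[i])
    vi <- .assign_flat(vi, param_y, grid$y[i])
    V[i, ] <- vi
  }
  ce <- .ce_from_matrix(V, strategy, convention, wtp)
  out <- dplyr::bind_cols(tibble::as_tibble(grid), ce)
  structure(out, class = c("pdac_two_way", class(out)),
            strategy = strategy, param_x = param_x, param_y = param_y,
            wtp = wtp)
}
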