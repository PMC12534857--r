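# broom-style accessors for the fitted-result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname run_psa
#' @param x A `pdac_psa` object.
#' @param ... Unused.
#' @export
tidy.pdac_psa <- function(x, ...) x$draws

#' @rdname run_psa
#' @export
glance.pdac_psa <- function(x, ...) {
  tibble::tibble(strategy = x$strategy, n_sims = x$n_sims, seed = x$seed,
                 wtp = x$wtp,
                 fraction_cost_effective = x$fraction_cost_effective,
                 mean_delta_cost = mean(x$draws$delta_cost),
                 mean_delta_qalys = mean(x$draws$delta_qalys),
                 convention = x$convention)
}

#' @rdname head_to_head
#' @param x A `pdac_head_to_head` object.
#' @param ... Unused.
#' @export
tidy.pdac_head_to_head <- function(x, ...) x$draws

#' @rdname head_to_head
#' @export
glance.pdac_head_to_head <- function(x, ...) {
  tibble::tibble(strategy_a = x$strategy_a, strategy_b = x$strategy_b,
                 fraction_a = x$fraction_a, fraction_b = x$fraction_b,
                 n_sims = x$n_sims, seed = x$seed, wtp = x$wtp)
}

#' @rdname simulate_cohort
#' @param x A `pdac_cohort_sim` object.
#' @param ... Unused.
#' @export
tidy.pdac_cohort_sim <- function(x, ...) x$individuals

#' @rdname simulate_cohort
#' @export
glance.pdac_cohort_sim <- function(x, ...) x$summary
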