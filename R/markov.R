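# Stage-level survival model and cohort trace. Each diagnosed patient stays
# in the diagnosed stage until death (no inter-stage progression); survival
# within a stage is exponential, parameterised by the published median.

#' Convert median survival to an annual death probability
#'
#' Under exponential survival with median `m` years and one-year cycles, the
#' per-cycle death probability is `p = 1 - 0.5^(1/m)`. The published figure
#' values (0.17, 0.39, 0.41, 0.82 for medians 3.7, 1.4, 1.3, 0.4) are this
#' conversion rounded to two decimals.
#'
#' @param median_survival Median survival in years (> 0); vectorised.
#' @return Annual death probability in (0, 1).
#' @examples
#' annual_death_probability(c(3.7, 1.4, 1.3, 0.4))
#' @export
annual_death_probability <- function(median_survival) {
  if (any(!is.finite(median_survival)) || any(median_survival <= 0)) {
    stop("median_survival must be positive", call. = FALSE)
  }
  -expm1(log(0.5) / median_survival)
}

#' Median survival implied by an annual death probability
#'
#' Closed-form inverse of [annual_death_probability()]:
#' `m = log(0.5) / log(1 - p)`.
#'
#' @param p Annual death probability in (0, 1); vectorised.
#' @return Median survival in years.
#' @export
median_survival_from_probability <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("p must lie strictly between 0 and 1", call. = FALSE)
  }
  log(0.5) / log1p(-p)
}

#' Accrual convention for the cohort trace
#'
#' The published model description leaves reward timing, the first discounted
#' cycle, and cost timing unstated, so all are explicit dials:
#'
#' * `reward_timing` — state occupancy credited per cycle: `"start"`
#'   (occupancy at cycle start), `"end"` (survivors at cycle end), or
#'   `"half_cycle"` (average of the two).
#' * `discount_start` — `"cycle1"` leaves the first cycle undiscounted;
#'   `"cycle0"` discounts every cycle by one extra year.
#' * `cost_timing` — `"lump_sum"` applies the whole stage treatment cost at
#'   diagnosis; `"spread"` spreads it over the stage occupancy and discounts
#'   each instalment.
#' * `cost_staging` — `"shifted"` aggregates treatment costs over each arm's
#'   own starting-stage distribution; `"unshifted"` aggregates both arms'
#'   treatment costs over the standard-care stage mix, so that early
#'   detection changes the care pathway's unit costs but not the cost-side
#'   stage mix (downstaging then affects outcomes only).
#' * `transition_digits` — stage death probabilities are derived from the
#'   medians and rounded to this many decimals (`2` mirrors the published
#'   figure; `NULL` uses the exact conversion).
#'
#' The default matches the simplest spreadsheet reading (start-of-cycle
#' rewards, first cycle undiscounted, lump-sum shifted costs). The convention
#' that best reproduces the published incremental results is returned by
#' [calibrated_convention()].
#'
#' @param reward_timing,discount_start,cost_timing,cost_staging See above.
#' @param transition_digits Integer decimals for the death probabilities, or
#'   `NULL` for the exact conversion.
#' @return An `accrual_convention` object.
#' @export
accrual_convention <- function(reward_timing = c("start", "end", "half_cycle"),
                               discount_start = c("cycle1", "cycle0"),
                               cost_timing = c("lump_sum", "spread"),
                               cost_staging = c("shifted", "unshifted"),
                               transition_digits = 2) {
  structure(list(reward_timing = match.arg(reward_timing),
                 discount_start = match.arg(discount_start),
                 cost_timing = match.arg(cost_timing),
                 cost_staging = match.arg(cost_staging),
                 transition_digits = transition_digits),
            class = "accrual_convention")
}

#' @rdname accrual_convention
#' @export
default_convention <- function() accrual_convention()

#' Fingerprint string of an accrual convention
#'
#' @param convention An `accrual_convention` object.
#' @return A single string, e.g. `"start|cycle1|lump_sum|shifted|2"`.
#' @export
convention_fingerprint <- function(convention) {
  paste(convention$reward_timing, convention$discount_start,
        convention$cost_timing, convention$cost_staging,
        if (is.null(convention$transition_digits)) "exact" else
          convention$transition_digits,
        sep = "|")
}

#' @export
print.accrual_convention <- function(x, ...) {
  cat("<accrual_convention>", convention_fingerprint(x), "\n")
  invisible(x)
}

# truncated geometric series sum_{t=0}^{h-1} x^t, stable at x = 1
.geo_sum <- function(x, h) {
  out <- (1 - x^h) / (1 - x)
  out[abs(1 - x) < 1e-12] <- h
  out
}

.stage_survival <- function(median_survival, convention) {
  p <- annual_death_probability(median_survival)
  if (!is.null(convention$transition_digits)) {
    p <- round(p, convention$transition_digits)
  }
  p
}

# Discounted per-stage building blocks, vectorised over draws.
# s: per-cycle survival; r: discount rate; h: horizon. Returns life-years,
# the spread-cost discount factor, and the entry-time discount factor.
.stage_blocks <- function(s, r, h, convention) {
  x <- s / (1 + r)
  tf <- switch(convention$reward_timing,
               start = 1, end = s, half_cycle = (1 + s) / 2)
  base0 <- if (convention$discount_start == "cycle0") 1 / (1 + r) else 1
  list(ly = tf * .geo_sum(x, h) * base0,
       cost_factor = .geo_sum(x, h) / .geo_sum(s, h) * base0,
       entry = base0)
}

#' Per-stage cohort trace
#'
#' Runs the two-state (alive-in-stage / dead) trace for one disease stage
#' over the model horizon, accruing discounted life-years, QALYs and
#' treatment costs per the accrual convention. Occupancy at the start of
#' cycle `t` is `(1 - p)^t` with `p` the stage's annual death probability;
#' the dead state accrues zero utility and zero cost.
#'
#' @param stage Stage name (one of the four disease stages).
#' @param params A `pdac_parameters` object.
#' @param pathway `"biomarker"` or `"standard"` treatment-cost pathway.
#' @param convention An [accrual_convention()].
#' @return A `pdac_trace` tibble with one row per cycle (columns `cycle`,
#'   `alive_prob`, `discount`, `disc_life_years`, `disc_qalys`, `disc_cost`)
#'   and the accrual totals as attributes `annual_death_prob`,
#'   `discounted_life_years`, `discounted_qalys`, `discounted_costs`.
#' @examples
#' tr <- stage_trace("resectable", default_parameters())
#' attr(tr, "discounted_qalys")
#' @export
stage_trace <- function(stage, params, pathway = c("biomarker", "standard"),
                        convention = default_convention()) {
  pathway <- match.arg(pathway)
  stopifnot(inherits(params, "pdac_parameters"))
  if (!stage %in% .stage_keys) {
    stop("unknown stage '", stage, "'", call. = FALSE)
  }
  row <- params$stages[params$stages$stage == stage, ]
  h <- as.integer(params$econ$horizon)
  if (h < 1) stop("horizon must be at least one cycle", call. = FALSE)
  r <- params$econ$discount_rate
  p <- .stage_survival(row$median_survival, convention)
  s <- 1 - p
  cost <- if (pathway == "biomarker") row$treatment_cost_biomarker else
    row$treatment_cost_standard
  t <- seq_len(h) - 1L
  extra <- if (convention$discount_start == "cycle0") 1L else 0L
  d <- (1 + r)^(-(t + extra))
  occ <- s^t
  w <- switch(convention$reward_timing,
              start = occ, end = occ * s, half_cycle = occ * (1 + s) / 2)
  disc_ly <- w * d
  disc_q <- row$utility * disc_ly
  disc_cost <- if (convention$cost_timing == "lump_sum") {
    c(cost * d[1], rep(0, h - 1L))
  } else {
    cost * occ / sum(occ) * d
  }
  out <- tibble::tibble(cycle = t, alive_prob = occ, discount = d,
                        disc_life_years = disc_ly, disc_qalys = disc_q,
                        disc_cost = disc_cost)
  structure(out,
            class = c("pdac_trace", class(out)),
            stage = stage, pathway = pathway,
            annual_death_prob = p,
            discounted_life_years = sum(disc_ly),
            discounted_qalys = sum(disc_q),
            discounted_costs = sum(disc_cost))
}

#' Stage-trace accrual totals
#'
#' @param trace A `pdac_trace` from [stage_trace()].
#' @return One-row tibble with the stage, annual death probability, and
#'   discounted life-year/QALY/cost totals.
#' @export
trace_totals <- function(trace) {
  tibble::tibble(stage = attr(trace, "stage"),
                 pathway = attr(trace, "pathway"),
                 annual_death_prob = attr(trace, "annual_death_prob"),
                 discounted_life_years = attr(trace, "discounted_life_years"),
                 discounted_qalys = attr(trace, "discounted_qalys"),
                 discounted_costs = attr(trace, "discounted_costs"))
}

#' Export per-cycle stage traces as CSV
#'
#' @param params A `pdac_parameters` object.
#' @param path Output CSV path.
#' @param pathway Treatment-cost pathway.
#' @param convention An [accrual_convention()].
#' @return `path`, invisibly.
#' @export
export_trace_csv <- function(params, path, pathway = "biomarker",
                             convention = default_convention()) {
  rows <- lapply(.stage_keys, function(st) {
    tr <- stage_trace(st, params, pathway, convention)
    df <- as.data.frame(tr)
    df$stage <- st
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Stage-distribution-weighted outcome mixture
#'
#' Weighted sum of the per-stage trace accruals over a starting-stage
#' distribution: the expected discounted cost, QALYs and life-years of one
#' diagnosed patient.
#'
#' @param params A `pdac_parameters` object.
#' @param pathway `"biomarker"` or `"standard"` (selects both the stage
#'   distribution and the treatment-cost column, unless overridden).
#' @param convention An [accrual_convention()]. The `cost_staging` dial is
#'   deliberately *not* applied here — this is the raw own-distribution
#'   mixture; strategy-level costing applies the dial.
#' @param dist Optional stage distribution overriding the pathway default.
#' @return One-row tibble with `cost`, `qalys`, `life_years`.
#' @examples
#' mixture_outcome(default_parameters(), "standard")
#' @export
mixture_outcome <- function(params, pathway = c("biomarker", "standard"),
                            convention = default_convention(), dist = NULL) {
  pathway <- match.arg(pathway)
  if (is.null(dist)) {
    dist <- if (pathway == "biomarker") params$dist_biomarker else
      params$dist_standard
  }
  dist <- dist[.stage_keys]
  if (abs(sum(dist) - 1) > 1e-9) {
    stop("stage distribution must sum to 1", call. = FALSE)
  }
  tot <- dplyr::bind_rows(lapply(.stage_keys, function(st) {
    trace_totals(stage_trace(st, params, pathway, convention))
  }))
  tibble::tibble(
    cost = sum(dist * tot$discounted_costs),
    qalys = sum(dist * tot$discounted_qalys),
    life_years = sum(dist * tot$discounted_life_years)
  )
}
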