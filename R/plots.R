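# ggplot2 displays; the CSV/JSON outputs stay canonical.

#' @rdname one_way_dsa
#' @param object A `pdac_tornado` tibble.
#' @param top Number of highest-ranked bars to display.
#' @param ... Unused.
#' @export
autoplot.pdac_tornado <- function(object, top = 10, ...) {
  df <- dplyr::slice_head(dplyr::arrange(object, .data$rank), n = top)
  df <- dplyr::filter(df, !.data$icer_undefined)
  df$parameter <- stats::reorder(df$parameter, df$bar_width)
  base_icer <- attr(object, "base_icer")
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_at_low,
                                       xend = .data$icer_at_high,
                                       y = .data$parameter,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_icer, linetype = 2) +
    ggplot2::geom_vline(xintercept = attr(object, "wtp"), linetype = 3,
                        colour = "firebrick") +
    ggplot2::labs(x = "ICER (GBP per QALY)", y = NULL,
                  title = paste0("One-way sensitivity: ",
                                 attr(object, "strategy")),
                  subtitle = "dashed: base case; dotted: WTP threshold") +
    ggplot2::theme_minimal()
}

#' @rdname run_psa
#' @param object A `pdac_psa` object.
#' @export
autoplot.pdac_psa <- function(object, ...) {
  df <- object$draws
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_qalys,
                                   y = .data$delta_cost,
                                   colour = .data$cost_effective)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = object$wtp, intercept = 0,
                         linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Incremental QALYs per person",
                  y = "Incremental cost per person (GBP)",
                  colour = "Cost-effective",
                  title = paste0("Cost-effectiveness plane: ",
                                 object$strategy),
                  subtitle = sprintf("%d draws; dashed line: WTP %s GBP/QALY",
                                     object$n_sims,
                                     format(object$wtp, big.mark = " "))) +
    ggplot2::theme_minimal()
}

#' @rdname compute_ceac
#' @param object A `pdac_ceac` tibble.
#' @param ... Unused.
#' @export
autoplot.pdac_ceac <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wtp,
                                       y = .data$probability)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (GBP per QALY)",
                  y = "Probability cost-effective",
                  title = paste0("Acceptability curve: ",
                                 attr(object, "strategy"))) +
    ggplot2::theme_minimal()
}

#' @rdname two_way_grid
#' @param object A `pdac_two_way` tibble.
#' @param ... Unused.
#' @export
autoplot.pdac_two_way <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       fill = .data$cost_effective)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = attr(object, "param_x"), y = attr(object, "param_y"),
                  fill = "Cost-effective",
                  title = paste0("Two-way sensitivity: ",
                                 attr(object, "strategy"))) +
    ggplot2::theme_minimal()
}
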