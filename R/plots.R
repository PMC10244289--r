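# ggplot2 visualisations for the result classes.

#' Cost-effectiveness plane for a PSA
#'
#' Scatter of per-iteration incremental QALYs against incremental costs
#' (AU$ million), with the willingness-to-pay line and the share of
#' cost-saving iterations annotated.
#'
#' @param object A `cea_psa`.
#' @param wtp Willingness-to-pay per QALY for the threshold line (default
#'   from the run's configuration).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cea_psa <- function(object, wtp = object$config$wtp_threshold, ...) {
  it <- object$iterations
  cs <- object$quadrants$fraction[
    object$quadrants$quadrant == "more QALYs, cost-saving"
  ]
  ggplot2::ggplot(it, ggplot2::aes(x = .data$delta_qaly,
                                   y = .data$delta_cost / 1e6)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_abline(slope = wtp / 1e6, intercept = 0,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::annotate(
      "text", x = Inf, y = -Inf, hjust = 1.05, vjust = -0.5,
      label = paste0(round(100 * cs, 1), "% cost-saving")
    ) +
    ggplot2::labs(
      x = "Incremental QALYs", y = "Incremental cost (AU$ million)",
      title = "Cost-effectiveness plane",
      subtitle = paste0(object$n_iterations, " PSA iterations")
    ) +
    ggplot2::theme_minimal()
}

#' Tornado diagram for a one-way sensitivity analysis
#'
#' Horizontal bars spanning the incremental cost (AU$ million) obtained at
#' each parameter's lower and upper bound, widest effect on top.
#'
#' @param object A `cea_tornado` from [one_way_dsa()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cea_tornado <- function(object, ...) {
  tb <- as_tibble(object) %>%
    mutate(parameter = factor(.data$parameter,
                              levels = rev(.data$parameter)))
  base_mid <- stats::median(c(tb$delta_cost_low, tb$delta_cost_high))
  ggplot2::ggplot(tb, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$delta_cost_low / 1e6,
                   xend = .data$delta_cost_high / 1e6,
                   yend = .data$parameter),
      linewidth = 4, colour = "steelblue"
    ) +
    ggplot2::geom_vline(xintercept = base_mid / 1e6, linetype = "dashed") +
    ggplot2::labs(x = "Incremental cost (AU$ million)", y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' ROI and ICER over the avoided-GDM residual risk
#'
#' Plots the scenario-2 sweep: ROI and ICER as functions of the relative
#' risk of T2DM for women who avoided GDM through intervention, with the
#' located roots (ROI = 1; ICER = threshold) marked.
#'
#' @param object A `cea_sweep` from [scenario2_sweep()].
#' @param ... Unused.
#' @return A ggplot object (facetted: ROI panel and ICER panel).
#' @export
autoplot.cea_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object$curve, "rr_avoided", "roi", "icer"),
    c("roi", "icer"), names_to = "measure", values_to = "value"
  ) %>%
    mutate(measure = toupper(.data$measure))
  refs <- tibble(
    measure = c("ROI", "ICER"),
    ref = c(1, object$wtp)
  )
  roots <- object$roots %>%
    mutate(measure = c("ROI", "ICER")) %>%
    filter(!is.na(.data$rr))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rr_avoided, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(data = refs, ggplot2::aes(yintercept = .data$ref),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_vline(data = roots, ggplot2::aes(xintercept = .data$rr),
                        linetype = "dotted") +
    ggplot2::facet_wrap(~measure, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "RR of T2DM for women who avoided GDM (vs never GDM)",
      y = NULL, title = "Residual-risk sensitivity (scenario 2)"
    ) +
    ggplot2::theme_minimal()
}
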