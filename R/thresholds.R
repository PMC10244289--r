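# Threshold searches: the intervention cost at which cost-effectiveness is
# lost, and the scenario-2 sweep over the residual T2DM risk of women who
# avoided GDM.

#' Intervention cost threshold for cost-effectiveness
#'
#' Finds, by bisection to AU$1, the per-participant intervention cost at
#' which the ICER equals the willingness-to-pay threshold, i.e. the root of
#' the incremental net cost `delta_cost(c) - wtp * delta_qaly`. The
#' incremental cost is increasing in the intervention cost, so the
#' intervention stays cost-effective below the returned value. If the model
#' is still cost-effective at the upper bracket bound (e.g. an infinite
#' threshold), that bound is returned with a warning attribute; if it is
#' already not cost-effective at the lower bound, an error is raised.
#'
#' @param params A `parameter_set`.
#' @param config A [model_config()].
#' @param wtp Willingness-to-pay per QALY (default from `config`,
#'   AU$50,000).
#' @param bracket Search interval for the cost (AU$ per participant).
#' @param tol Absolute tolerance (default AU$1).
#' @return Threshold cost in AU$ per participant. Attribute `converged` is
#'   `FALSE` when the upper bound was returned without a crossing.
#' @export
intervention_cost_threshold <- function(params, config = model_config(),
                                        wtp = config$wtp_threshold,
                                        bracket = c(0, 20000), tol = 1) {
  cm <- compile_model(params, config)
  base <- base_theta(params, config)
  net_cost <- function(cost) {
    raw <- run_compiled(cm, apply_theta_override(base, "c_intervention", NA,
                                                 cost))
    raw$delta_cost - wtp * raw$delta_qaly
  }
  lo <- bracket[1]
  hi <- bracket[2]
  f_lo <- net_cost(lo)
  if (f_lo > 0) {
    abort("Not cost-effective at the lower bracket bound; no threshold within bracket.")
  }
  f_hi <- net_cost(hi)
  if (f_hi <= 0) {
    out <- hi
    attr(out, "converged") <- FALSE
    return(out)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_cost(mid) <= 0) lo <- mid else hi <- mid
  }
  out <- (lo + hi) / 2
  attr(out, "converged") <- TRUE
  out
}

#' Scenario-2 sweep of the avoided-GDM residual risk
#'
#' Varies the relative risk of progressing to T2DM for women who avoided GDM
#' through intervention (relative to never-GDM women) over a grid in
#' `[1, 9.5]`: 1 reproduces the base case, and the upper end (the GDM-level
#' risk) removes any long-term benefit so only perinatal effects remain. For
#' each grid point the full comparison is re-run and the ROI, signed ICER
#' (incremental cost over incremental QALYs; negative when dominant) and
#' incremental T2DM cases are recorded. Roots are located by bisection:
#' the RR at which ROI = 1, and the RR at which the ICER reaches the
#' willingness-to-pay threshold (via the net-cost root
#' `delta_cost = wtp * delta_qaly`).
#'
#' @param params A `parameter_set`.
#' @param config A [model_config()]; the scenario is forced to
#'   `"s2_rr_sweep"`.
#' @param rr_grid Grid of RR values within `[1, 9.5]`.
#' @param wtp Willingness-to-pay per QALY for the ICER root.
#' @return An object of class `cea_sweep`: `curve` tibble
#'   (`rr_avoided`, `delta_cost`, `delta_qaly`, `delta_cases_t2dm`, `roi`,
#'   `icer`) and `roots` tibble (`target`, `rr`), `rr` being `NA` when the
#'   curve does not cross the target within the grid range.
#' @export
scenario2_sweep <- function(params, config = model_config(),
                            rr_grid = seq(1, 9.5, by = 0.25),
                            wtp = config$wtp_threshold) {
  if (any(rr_grid < 1 | rr_grid > 9.51)) {
    abort("`rr_grid` must lie within [1, 9.5].")
  }
  config$scenario <- "s2_rr_sweep"
  cm <- compile_model(params, config)
  base <- base_theta(params, config)
  eval_rr <- function(rr) {
    raw <- run_compiled(cm, apply_theta_override(base, "rr_avoided", NA, rr))
    c(dc = raw$delta_cost, dq = raw$delta_qaly,
      cases = raw$incremental[["cases_t2dm"]],
      roi = roi_from_raw(raw, config))
  }
  grid <- t(vapply(rr_grid, eval_rr, numeric(4)))
  curve <- tibble(
    rr_avoided = rr_grid,
    delta_cost = grid[, "dc"],
    delta_qaly = grid[, "dq"],
    delta_cases_t2dm = grid[, "cases"],
    roi = grid[, "roi"],
    icer = grid[, "dc"] / grid[, "dq"]
  )
  lo <- min(rr_grid)
  hi <- max(rr_grid)
  root_of <- function(f) {
    f_lo <- f(lo)
    f_hi <- f(hi)
    if (is.na(f_lo) || is.na(f_hi) || f_lo * f_hi > 0) return(NA_real_)
    uniroot(f, c(lo, hi), tol = 1e-4)$root
  }
  roots <- tibble(
    target = c("roi = 1", "icer = wtp"),
    rr = c(
      root_of(function(rr) eval_rr(rr)[["roi"]] - 1),
      root_of(function(rr) {
        v <- eval_rr(rr)
        v[["dc"]] - wtp * v[["dq"]]
      })
    )
  )
  structure(list(curve = curve, roots = roots, wtp = wtp, config = config),
            class = "cea_sweep")
}

#' @export
print.cea_sweep <- function(x, ...) {
  cat("<cea_sweep>  ", nrow(x$curve), " grid points over [",
      min(x$curve$rr_avoided), ", ", max(x$curve$rr_avoided), "]\n", sep = "")
  print(x$roots)
  invisible(x)
}

#' Tidy the scenario-2 sweep curve
#'
#' @param x A `cea_sweep`.
#' @param ... Unused.
#' @return The sweep curve tibble.
#' @export
tidy.cea_sweep <- function(x, ...) {
  x$curve
}
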