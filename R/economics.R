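# Health-economic outputs: perinatal and chronic cost categories, QALYs,
# ICER with dominance handling, return on investment, efficiency frontier.

#' Intervention unit cost from staffing assumptions
#'
#' Derives the per-woman cost of delivering the structured lifestyle
#' intervention from the annual salary of the delivering health coach, a
#' salary on-cost fraction, a fixed-cost allowance (training, facilities, IT,
#' administration) and the annual caseload per coach:
#' `salary * (1 + oncost) * (1 + fixed) / caseload`. With the default
#' assumptions (AU$82,600 midpoint salary, 15% on-costs, 20% fixed allowance,
#' 500 women per coach-year) this is AU$228 per woman.
#'
#' @param salary Annual full-time salary (AU$).
#' @param oncost_rate Salary on-cost fraction (default 0.15).
#' @param fixed_rate Fixed-cost allowance fraction (default 0.20).
#' @param caseload Women served per coach per year (default 500).
#' @return Cost per woman in AU$ (unrounded).
#' @examples
#' round(intervention_unit_cost()) # 228
#' @export
intervention_unit_cost <- function(salary = 82600, oncost_rate = 0.15,
                                   fixed_rate = 0.20, caseload = 500) {
  if (caseload <= 0) abort("`caseload` must be positive.")
  salary * (1 + oncost_rate) * (1 + fixed_rate) / caseload
}

#' Expected perinatal costs for one cohort and arm
#'
#' Cycle-0 (undiscounted) expected cost per the decision tree: the GDM branch
#' incurs antenatal GDM care plus GDM-specific Caesarean/induction event
#' probabilities; the avoided-GDM and never-GDM branches share non-GDM event
#' probabilities. NICU/SCN admission costs are reported separately and only
#' counted when enabled.
#'
#' @param weights Branch weights from [pregnancy_branching()].
#' @param cohort One row of the cohorts table.
#' @param costs The costs table of a `parameter_set`.
#' @param include_nicu Include NICU/SCN admission costs.
#' @return A one-row tibble with columns `intervention_weighted_births`,
#'   `pregnancy`, `nicu_scn` (AU$ totals for the cohort).
#' @export
perinatal_costs <- function(weights, cohort, costs, include_nicu = FALSE) {
  births <- cohort$n_births[1] * (1 - cohort$preexisting_dm_prevalence[1])
  cv <- function(item) costs$value[match(item, costs$item)]
  w_gdm <- weights$weight[weights$branch == "gdm"]
  preg <- w_gdm * (cv("antenatal_gdm") +
                     cv("p_caesarean_gdm") * cv("caesarean_cost") +
                     cv("p_induction_gdm") * cv("induction_cost")) +
    (1 - w_gdm) * (cv("p_caesarean_no_gdm") * cv("caesarean_cost") +
                     cv("p_induction_no_gdm") * cv("induction_cost"))
  nicu <- if (include_nicu) {
    (w_gdm * cv("p_nicu_gdm") + (1 - w_gdm) * cv("p_nicu_no_gdm")) *
      cv("nicu_cost")
  } else {
    0
  }
  tibble(
    weighted_births = births,
    pregnancy = births * preg,
    nicu_scn = births * nicu
  )
}

#' Discounted chronic (T2DM management) costs for one trace
#'
#' In the base case, attributed annual management costs apply to T2DM
#' state-years: `sum_t t2dm_years(t) * cost(age_t) * (1+r)^-t`. Under the
#' micro-costing scenarios (`s3_microcost_health`, `s4_microcost_societal`)
#' incident cases incur the newly-diagnosed annual cost in their first cycle
#' and carried-over prevalent cases the known-diabetes cost; scenario 4 adds
#' societal components (direct non-health costs and income support) per T2DM
#' state-year, returned separately.
#'
#' @param trace A trace from [run_markov_trace()].
#' @param costs The costs table of a `parameter_set`.
#' @param representative_age Cohort entry age (to look up age-specific costs).
#' @param config A [model_config()].
#' @return A one-row tibble with columns `t2dm_management` and
#'   `societal_addons` (discounted AU$ per woman entering the branch).
#' @export
chronic_costs <- function(trace, costs, representative_age,
                          config = model_config()) {
  cv <- function(item) costs$value[match(item, costs$item)]
  disc <- (1 + config$discount_rate)^-(trace$cycle)
  scen <- config$scenario
  mgmt <- if (scen %in% c("s3_microcost_health", "s4_microcost_societal")) {
    carry <- trace$t2dm - trace$new_t2dm_cases
    sum((trace$new_t2dm_cases * cv("microcost_first_year") +
           carry * cv("microcost_subsequent_year")) * disc)
  } else {
    ages <- representative_age + trace$cycle
    sum(trace$t2dm_years * t2dm_cost_by_age(costs, ages) * disc)
  }
  societal <- if (scen == "s4_microcost_societal") {
    sum(trace$t2dm_years *
          (cv("microcost_direct_nonhealth") + cv("microcost_income_subsidy")) *
          disc)
  } else {
    0
  }
  tibble(t2dm_management = mgmt, societal_addons = societal)
}

#' Discounted QALYs for one trace
#'
#' Weights healthy state-years by the age-band utility and T2DM state-years
#' by the (age-adjusted) T2DM utility, then discounts by cycle.
#'
#' @param trace A trace from [run_markov_trace()].
#' @param utilities The utilities table of a `parameter_set`.
#' @param representative_age Cohort entry age.
#' @param config A [model_config()].
#' @return Discounted QALYs per woman entering the branch (scalar).
#' @export
discounted_qalys <- function(trace, utilities, representative_age,
                             config = model_config()) {
  ages <- representative_age + trace$cycle
  u_h <- utility_by_age(utilities, ages)
  u_t2 <- t2dm_utility_by_age(
    u_h, utilities$mean[utilities$band == "t2dm"], utilities,
    config$utility_adjustment_mode
  )
  disc <- (1 + config$discount_rate)^-(trace$cycle)
  healthy_years <- trace$life_years - trace$t2dm_years
  sum((healthy_years * u_h + trace$t2dm_years * u_t2) * disc)
}

#' Incremental cost-effectiveness ratio with dominance labels
#'
#' @param delta_cost,delta_qaly Incremental cost (AU$) and QALYs
#'   (intervention minus comparator), on the same population scale.
#' @return A list with `icer` (numeric, `NA` when labelled) and `label`
#'   (`"Dominant"` when cheaper and more effective, `"Dominated"` when
#'   costlier and less effective, `"no QALY difference"` when
#'   `delta_qaly == 0`, otherwise `NA`).
#' @examples
#' compute_icer(100, 0.02) # 5000
#' compute_icer(-50, 0.035) # Dominant
#' @export
compute_icer <- function(delta_cost, delta_qaly) {
  if (delta_qaly == 0) {
    return(list(icer = NA_real_, label = "no QALY difference"))
  }
  if (delta_cost < 0 && delta_qaly > 0) {
    return(list(icer = NA_real_, label = "Dominant"))
  }
  if (delta_cost > 0 && delta_qaly < 0) {
    return(list(icer = NA_real_, label = "Dominated"))
  }
  list(icer = delta_cost / delta_qaly, label = NA_character_)
}

#' Return on investment of the intervention
#'
#' Non-intervention cost savings per dollar of intervention spend:
#' `(pregnancy savings + T2DM management savings [+ NICU/SCN savings]
#' [+ societal savings]) / incremental intervention cost`, where savings are
#' the negated incremental category costs.
#'
#' @param intervention_increment Incremental intervention cost (AU$, > 0).
#' @param pregnancy_increment,t2dm_increment Incremental pregnancy and T2DM
#'   management costs (negative when the intervention saves money).
#' @param nicu_increment Incremental NICU/SCN cost; only counted when
#'   `include_nicu = TRUE`.
#' @param societal_increment Incremental societal add-on cost; only counted
#'   when `include_societal = TRUE`.
#' @param include_nicu,include_societal Category toggles.
#' @return ROI ratio (scalar).
#' @examples
#' compute_roi(69904575, -25187141, -60108916) # 1.22
#' compute_roi(69904575, -25187141, -60108916,
#'             nicu_increment = -24264341, include_nicu = TRUE) # 1.57
#' @export
compute_roi <- function(intervention_increment, pregnancy_increment,
                        t2dm_increment, nicu_increment = 0,
                        societal_increment = 0, include_nicu = FALSE,
                        include_societal = FALSE) {
  if (intervention_increment == 0) {
    abort("ROI undefined: zero intervention cost.")
  }
  savings <- -(pregnancy_increment + t2dm_increment +
                 (if (include_nicu) nicu_increment else 0) +
                 (if (include_societal) societal_increment else 0))
  savings / intervention_increment
}

#' Efficiency frontier with extended dominance
#'
#' Orders strategies by effectiveness, flags strictly dominated strategies
#' (another strategy is at least as effective and cheaper) and extendedly
#' dominated strategies (a convex combination of two others dominates them:
#' their incremental ICER exceeds that of the next frontier segment), and
#' returns the frontier in increasing QALY order.
#'
#' @param strategies A data frame with columns `strategy`, `delta_cost`,
#'   `delta_qaly` (all against a common comparator, which should be included
#'   as a row, typically at the origin).
#' @return The input tibble with added columns `status` (`"frontier"`,
#'   `"dominated"`, `"extendedly dominated"`) and `icer_frontier` (ICER
#'   against the previous frontier strategy, `NA` off-frontier).
#' @export
efficiency_frontier <- function(strategies) {
  st <- as_tibble(strategies)
  if (nrow(st) < 2) abort("Need at least two strategies.")
  st <- dplyr::arrange(st, .data$delta_qaly, .data$delta_cost)
  st$status <- "frontier"
  # strict dominance
  for (i in seq_len(nrow(st))) {
    dom <- any(st$delta_qaly >= st$delta_qaly[i] &
                 st$delta_cost < st$delta_cost[i]) ||
      any(st$delta_qaly > st$delta_qaly[i] &
            st$delta_cost <= st$delta_cost[i])
    if (dom) st$status[i] <- "dominated"
  }
  # extended dominance: repeatedly drop candidates whose incremental ICER
  # exceeds the next segment's
  repeat {
    idx <- which(st$status == "frontier")
    if (length(idx) < 3) break
    changed <- FALSE
    for (j in seq(2, length(idx) - 1)) {
      a <- idx[j - 1]; b <- idx[j]; d <- idx[j + 1]
      icer_ab <- (st$delta_cost[b] - st$delta_cost[a]) /
        (st$delta_qaly[b] - st$delta_qaly[a])
      icer_bd <- (st$delta_cost[d] - st$delta_cost[b]) /
        (st$delta_qaly[d] - st$delta_qaly[b])
      if (isTRUE(icer_ab > icer_bd)) {
        st$status[b] <- "extendedly dominated"
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  idx <- which(st$status == "frontier")
  st$icer_frontier <- NA_real_
  if (length(idx) > 1) {
    for (j in seq(2, length(idx))) {
      a <- idx[j - 1]; b <- idx[j]
      st$icer_frontier[b] <- (st$delta_cost[b] - st$delta_cost[a]) /
        (st$delta_qaly[b] - st$delta_qaly[a])
    }
  }
  st
}
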