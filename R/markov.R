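# Decision-tree branching and the three-state Markov cohort process.
#
# Every woman passes a decision node (intervention vs usual care) and a GDM
# chance node, then enters a Markov process over states
# {no_t2dm, t2dm, dead} in one-year cycles until age 85. Pregnancy and birth
# events sit at cycle 0 (undiscounted); Markov cycles are t = 1, 2, ... with
# discount factor (1 + r)^-t.

#' Decision-tree branch weights for one cohort and arm
#'
#' Under usual care a fraction `q` (the band's GDM prevalence) of pregnancies
#' develop GDM. Under intervention the GDM risk is multiplied by
#' `rr_gdm_intervention`, and the difference `q * (1 - rr)` moves to the
#' "avoided GDM" branch; women who would never have developed GDM are
#' unaffected.
#'
#' @param cohort One row of the cohorts table (needs `gdm_prevalence`).
#' @param arm `"usual_care"` or `"intervention"`.
#' @param rr_gdm_intervention Relative risk of developing GDM under the
#'   intervention (ignored for usual care).
#' @return A tibble with columns `arm`, `branch` (`gdm`, `avoided_gdm`,
#'   `never_gdm`) and `weight`, summing to 1.
#' @examples
#' pregnancy_branching(tibble::tibble(gdm_prevalence = 0.15), "intervention", 0.67)
#' @export
pregnancy_branching <- function(cohort, arm = c("usual_care", "intervention"),
                                rr_gdm_intervention = 1) {
  arm <- match.arg(arm)
  q <- cohort$gdm_prevalence[1]
  rr <- rr_gdm_intervention
  if (rr <= 0 || rr > 1.5) abort("`rr_gdm_intervention` must lie in (0, 1.5].")
  if (q * rr > 1) abort("GDM probability under intervention exceeds 1.")
  w <- if (arm == "usual_care") {
    c(gdm = q, avoided_gdm = 0, never_gdm = 1 - q)
  } else {
    c(gdm = q * rr, avoided_gdm = q * (1 - rr), never_gdm = 1 - q)
  }
  tibble(arm = arm, branch = names(w), weight = unname(w))
}

#' Per-cycle transition probabilities for one branch of one cohort
#'
#' Builds the cycle-indexed schedule of annual transition probabilities for a
#' woman entering the Markov process at `representative_age`. Cycle `t` covers
#' attained age `representative_age + t`. T2DM incidence depends on the
#' branch: the GDM branch uses the GDM-stratum incidence (adjusted RR x total
#' incidence), the never-GDM branch the no-GDM stratum, and the avoided-GDM
#' branch `rr_avoided` times the no-GDM stratum (1 in the base case). Under
#' scenario `s1_10yr` the GDM branch's excess risk lapses after 10 post-birth
#' cycles, reverting to the total-population incidence. Mortality is the
#' derived no-T2DM rate for the healthy state and the T2DM-population rate
#' (ages 40+) for the diseased state; rates convert to probabilities by the
#' exponential formula.
#'
#' @param branch `"gdm"`, `"avoided_gdm"` or `"never_gdm"`.
#' @param params A `parameter_set`.
#' @param config A [model_config()].
#' @param representative_age Age at entry (cohort band midpoint).
#' @return A tibble with columns `cycle`, `age`, `p_to_t2dm`,
#'   `p_death_no_t2dm`, `p_death_t2dm`.
#' @export
build_transition_schedule <- function(branch, params, config,
                                      representative_age) {
  branch <- match.arg(branch, c("gdm", "avoided_gdm", "never_gdm"))
  cm <- compile_epi(params, config)
  sched <- branch_schedule(cm, representative_age, branch,
                           rr_t2dm = rr_value(params, "rr_t2dm_after_gdm"),
                           rr_avoided = config$rr_avoided)
  tibble(
    cycle = seq_along(sched$p_inc),
    age = sched$age,
    p_to_t2dm = sched$p_inc,
    p_death_no_t2dm = sched$p_die_no,
    p_death_t2dm = sched$p_die_t2
  )
}

#' Run the three-state Markov cohort recursion
#'
#' Propagates state occupancy (no T2DM, T2DM, dead) over the schedule's
#' cycles, starting from full occupancy of the no-T2DM state. Death is
#' absorbing. Within a cycle, mortality is applied first and the incidence
#' probability then acts on survivors of the healthy state, so incident cases
#' are survivors who transition. State-years per cycle are the mean of cycle
#' start and end occupancy when half-cycle correction is on, end-of-cycle
#' occupancy otherwise.
#'
#' @param schedule A transition schedule as returned by
#'   [build_transition_schedule()] (columns `p_to_t2dm`, `p_death_no_t2dm`,
#'   `p_death_t2dm`; optional `cycle`, `age`).
#' @param config A [model_config()]; only `half_cycle_correction` and
#'   `discount_rate` are used.
#' @return A tibble with one row per cycle: occupancies `no_t2dm`, `t2dm`,
#'   `dead`, incident flux `new_t2dm_cases`, half-cycle-corrected
#'   `life_years` and `t2dm_years`, and `discount` factor.
#' @export
run_markov_trace <- function(schedule, config = model_config()) {
  p_inc <- schedule$p_to_t2dm
  p_die_no <- schedule$p_death_no_t2dm
  p_die_t2 <- schedule$p_death_t2dm
  if (any(p_inc < 0 | p_inc > 1 | p_die_no < 0 | p_die_no > 1 |
          p_die_t2 < 0 | p_die_t2 > 1)) {
    abort("Transition probabilities must lie in [0, 1].")
  }
  tr <- markov_core(p_inc, p_die_no, p_die_t2,
                    hcc = config$half_cycle_correction)
  n <- length(p_inc)
  tibble(
    cycle = seq_len(n),
    no_t2dm = tr$occ_no,
    t2dm = tr$occ_t2,
    dead = tr$occ_dead,
    new_t2dm_cases = tr$new_cases,
    life_years = tr$ly_no + tr$ly_t2,
    t2dm_years = tr$ly_t2,
    discount = (1 + config$discount_rate)^-(seq_len(n))
  )
}

#' Lifetime health outcomes for one cohort
#'
#' Combines per-branch Markov traces with decision-tree branch weights and
#' the cohort's included births into population-level outcomes: GDM cases,
#' lifetime T2DM cases, years of life, years lived with T2DM, QALYs
#' (discounted and undiscounted) and NICU/SCN admissions. Cycle-`t` quantities
#' are discounted by `(1 + r)^-t`; perinatal quantities sit at `t = 0`
#' undiscounted.
#'
#' @param traces Named list of traces from [run_markov_trace()], one per
#'   branch present in `weights`.
#' @param weights Branch weights from [pregnancy_branching()].
#' @param cohort One row of the cohorts table.
#' @param params A `parameter_set` (utilities and NICU probabilities).
#' @param config A [model_config()].
#' @return A one-row tibble of cohort outcomes.
#' @export
lifetime_outcomes <- function(traces, weights, cohort, params, config) {
  births <- cohort$n_births[1] * (1 - cohort$preexisting_dm_prevalence[1])
  u_t2 <- params$utilities$mean[params$utilities$band == "t2dm"]
  ages <- traces[[weights$branch[1]]]$cycle + cohort$representative_age[1]
  u_healthy <- utility_by_age(params$utilities, ages)
  u_t2_by_age <- t2dm_utility_by_age(u_healthy, u_t2, params$utilities,
                                     config$utility_adjustment_mode)
  disc <- (1 + config$discount_rate)^-(seq_along(ages))

  acc <- c(cases_t2dm = 0, years_of_life = 0, years_of_life_disc = 0,
           years_with_t2dm = 0, years_with_t2dm_disc = 0, qalys = 0,
           qalys_disc = 0)
  for (k in seq_len(nrow(weights))) {
    w <- weights$weight[k]
    if (w == 0) next
    tr <- traces[[weights$branch[k]]]
    ly_no <- tr$life_years - tr$t2dm_years
    q <- ly_no * u_healthy + tr$t2dm_years * u_t2_by_age
    acc <- acc + w * c(
      cases_t2dm = sum(tr$new_t2dm_cases),
      years_of_life = sum(tr$life_years),
      years_of_life_disc = sum(tr$life_years * disc),
      years_with_t2dm = sum(tr$t2dm_years),
      years_with_t2dm_disc = sum(tr$t2dm_years * disc),
      qalys = sum(q),
      qalys_disc = sum(q * disc)
    )
  }
  w_gdm <- weights$weight[weights$branch == "gdm"]
  p_nicu_g <- cost_value(params, "p_nicu_gdm")
  p_nicu_n <- cost_value(params, "p_nicu_no_gdm")
  tibble(
    cases_gdm = births * w_gdm,
    cases_t2dm = births * acc[["cases_t2dm"]],
    years_of_life = births * acc[["years_of_life"]],
    years_of_life_disc = births * acc[["years_of_life_disc"]],
    years_with_t2dm = births * acc[["years_with_t2dm"]],
    years_with_t2dm_disc = births * acc[["years_with_t2dm_disc"]],
    qalys = births * acc[["qalys"]],
    qalys_disc = births * acc[["qalys_disc"]],
    nicu_scn_admissions = births * (w_gdm * p_nicu_g + (1 - w_gdm) * p_nicu_n)
  )
}
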