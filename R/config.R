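# Run configuration: cycle structure, discounting, scenario/subgroup switches.

SCENARIOS <- c("base", "s1_10yr", "s2_rr_sweep", "s3_microcost_health",
               "s4_microcost_societal")
SUBGROUPS <- c("base", "diet", "pa", "diet_pa")

#' Model configuration
#'
#' Collects every run-time switch of the analysis in one list: cycle and
#' horizon structure, the annual discount rate (0.05 per national guidelines),
#' the willingness-to-pay threshold (AU$50,000/QALY), half-cycle correction,
#' whether NICU/SCN admission costs enter the healthcare perspective, the
#' scenario and intervention subgroup, the assumed relative risk of T2DM for
#' women who avoided GDM through intervention (1 in the base case), and the
#' seeding/size of the probabilistic sensitivity analysis.
#'
#' @param cycle_length Cycle length in years (the model is annual).
#' @param max_age Follow-up horizon in years of age (default 85).
#' @param discount_rate Annual discount rate applied to costs and outcomes.
#' @param wtp_threshold Cost-effectiveness threshold in AU$ per QALY.
#' @param half_cycle_correction Credit state membership as the mean of
#'   cycle-start and cycle-end occupancy (default `TRUE`).
#' @param include_nicu_scn Include NICU/SCN admission costs (default `FALSE`,
#'   matching the primary healthcare perspective).
#' @param scenario One of `r paste0('"', SCENARIOS, '"', collapse = ", ")`.
#' @param subgroup Intervention subgroup, one of
#'   `r paste0('"', SUBGROUPS, '"', collapse = ", ")`.
#' @param rr_avoided Relative risk of progressing to T2DM for women who
#'   avoided GDM through intervention, relative to never-GDM women; swept over
#'   `[1, 9.5]` in scenario 2.
#' @param utility_adjustment_mode How the T2DM state utility is combined with
#'   age-specific healthy utilities: `"multiplicative"` (default) rescales the
#'   healthy curve by the T2DM/reference ratio; `"absolute-decrement"`
#'   subtracts a constant decrement.
#' @param rng_seed Integer seed governing all randomness.
#' @param psa_iterations Number of probabilistic sensitivity analysis
#'   iterations (default 10,000).
#' @return A list of class `model_config`.
#' @export
model_config <- function(cycle_length = 1,
                         max_age = 85,
                         discount_rate = 0.05,
                         wtp_threshold = 50000,
                         half_cycle_correction = TRUE,
                         include_nicu_scn = FALSE,
                         scenario = "base",
                         subgroup = "base",
                         rr_avoided = 1,
                         utility_adjustment_mode = "multiplicative",
                         rng_seed = 1L,
                         psa_iterations = 10000L) {
  scenario <- match.arg(scenario, SCENARIOS)
  subgroup <- match.arg(subgroup, SUBGROUPS)
  utility_adjustment_mode <- match.arg(utility_adjustment_mode,
                                       c("multiplicative", "absolute-decrement"))
  if (discount_rate < 0) abort("`discount_rate` must be non-negative.")
  if (max_age <= 49) abort("`max_age` must exceed the oldest cohort band (49).")
  if (psa_iterations < 1) abort("`psa_iterations` must be at least 1.")
  if (rr_avoided <= 0) abort("`rr_avoided` must be positive.")
  structure(
    list(
      cycle_length = cycle_length,
      max_age = max_age,
      discount_rate = discount_rate,
      wtp_threshold = wtp_threshold,
      half_cycle_correction = isTRUE(half_cycle_correction),
      include_nicu_scn = isTRUE(include_nicu_scn),
      scenario = scenario,
      subgroup = subgroup,
      rr_avoided = rr_avoided,
      utility_adjustment_mode = utility_adjustment_mode,
      rng_seed = as.integer(rng_seed),
      psa_iterations = as.integer(psa_iterations)
    ),
    class = "model_config"
  )
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>\n")
  for (f in names(x)) cat("  ", format(f, width = 24), x[[f]], "\n")
  invisible(x)
}

#' Read or write a model configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_model_config()` returns a `model_config`;
#'   `write_model_config()` returns `path` invisibly.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(model_config)))
  if (length(unknown) > 0) {
    abort(paste0("Unknown config fields: ", paste(unknown, collapse = ", ")))
  }
  do.call(model_config, vals)
}

#' @rdname read_model_config
#' @param config A `model_config`.
#' @export
write_model_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# scenario/subgroup helpers shared by the engines
subgroup_rr_name <- function(subgroup) {
  paste0("rr_gdm_", subgroup)
}

subgroup_cost_item <- function(subgroup) {
  paste0("intervention_", subgroup)
}
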