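# Two-arm lifetime comparison across all maternal cohorts.

#' Run the full two-arm cost-effectiveness comparison
#'
#' Executes the decision tree and Markov life-table model for every maternal
#' age cohort under usual care and under the structured lifestyle
#' intervention, and aggregates health outcomes (GDM and T2DM cases, years of
#' life, years lived with T2DM, QALYs, NICU/SCN admissions) and discounted
#' cost categories (intervention, pregnancy, T2DM management, NICU/SCN,
#' societal add-ons) into arm totals, increments, per-woman increments, the
#' ICER (or a dominance label) and the ROI ratio.
#'
#' @param params A `parameter_set`.
#' @param config A [model_config()]; the `scenario`, `subgroup`,
#'   `include_nicu_scn` and `rr_avoided` fields select the analysis.
#' @return An object of class `cea_comparison` with elements `arms`
#'   (outcome-by-arm tibble), `incremental`, `per_woman`, `icer`,
#'   `icer_label`, `roi`, `total_births` and `config`.
#' @examples
#' \donttest{
#' params <- load_reference_fixture()
#' res <- run_comparison(params, model_config())
#' glance(res)
#' }
#' @export
run_comparison <- function(params, config = model_config()) {
  cm <- compile_model(params, config)
  theta <- base_theta(params, config)
  raw <- run_compiled(cm, theta)
  as_cea_comparison(raw, config)
}

OUTCOME_ROWS <- c(
  cases_gdm = "Cases of GDM",
  cases_t2dm = "Cases of type 2 diabetes",
  ly_disc = "Years of life lived (discounted)",
  t2y_disc = "Years of life lived with T2DM (discounted)",
  qaly_disc = "QALYs (discounted)",
  nicu = "NICU/SCN admissions",
  c_intervention = "Intervention cost",
  c_pregnancy = "Pregnancy costs",
  c_t2dm = "Type 2 diabetes management",
  c_nicu = "NICU/SCN costs",
  c_societal = "Societal add-on costs"
)

as_cea_comparison <- function(raw, config) {
  keys <- names(OUTCOME_ROWS)
  arms <- tibble(
    outcome = unname(OUTCOME_ROWS),
    key = keys,
    usual_care = unname(raw$usual_care[keys]),
    intervention = unname(raw$intervention[keys]),
    incremental = unname(raw$incremental[keys])
  )
  ic <- compute_icer(raw$delta_cost, raw$delta_qaly)
  inc <- raw$incremental
  roi <- if (inc[["c_intervention"]] > 0) {
    compute_roi(
      inc[["c_intervention"]], inc[["c_pregnancy"]], inc[["c_t2dm"]],
      nicu_increment = inc[["c_nicu"]],
      societal_increment = inc[["c_societal"]],
      include_nicu = config$include_nicu_scn,
      include_societal = config$scenario == "s4_microcost_societal"
    )
  } else {
    NA_real_
  }
  structure(
    list(
      arms = arms,
      incremental = tibble(
        delta_cost = raw$delta_cost,
        delta_cost_healthcare = raw$delta_cost_healthcare,
        delta_qaly = raw$delta_qaly,
        delta_cases_t2dm = inc[["cases_t2dm"]],
        delta_cases_gdm = inc[["cases_gdm"]]
      ),
      per_woman = tibble(
        delta_cost = raw$delta_cost / raw$total_births,
        delta_qaly = raw$delta_qaly / raw$total_births
      ),
      icer = ic$icer,
      icer_label = ic$label,
      roi = roi,
      total_births = raw$total_births,
      config = config
    ),
    class = "cea_comparison"
  )
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat("<cea_comparison>  scenario:", x$config$scenario,
      " subgroup:", x$config$subgroup,
      if (x$config$include_nicu_scn) " (incl. NICU/SCN)" else "", "\n")
  print(dplyr::select(x$arms, -"key"), n = nrow(x$arms))
  icer_txt <- if (is.na(x$icer)) x$icer_label else
    paste0("AU$", format(round(x$icer), big.mark = ","), "/QALY")
  cat("\n  ICER:", icer_txt, "\n")
  cat("  ROI: ", round(x$roi, 2), " per dollar invested\n", sep = "")
  cat("  Incremental cost per woman: AU$",
      round(x$per_woman$delta_cost), "\n", sep = "")
  cat("  Incremental QALYs per woman: ",
      signif(x$per_woman$delta_qaly, 3), "\n", sep = "")
  invisible(x)
}

#' Tidy a comparison result
#'
#' @param x A `cea_comparison`.
#' @param ... Unused.
#' @return A long tibble with columns `outcome`, `key`, `usual_care`,
#'   `intervention`, `incremental`.
#' @export
tidy.cea_comparison <- function(x, ...) {
  x$arms
}

#' One-row summary of a comparison result
#'
#' @param x A `cea_comparison`.
#' @param ... Unused.
#' @return A one-row tibble: incremental totals, per-woman increments, ICER
#'   value and label, ROI, births.
#' @export
glance.cea_comparison <- function(x, ...) {
  tibble(
    scenario = x$config$scenario,
    subgroup = x$config$subgroup,
    include_nicu_scn = x$config$include_nicu_scn,
    delta_cost = x$incremental$delta_cost,
    delta_qaly = x$incremental$delta_qaly,
    delta_cases_t2dm = x$incremental$delta_cases_t2dm,
    delta_cost_per_woman = x$per_woman$delta_cost,
    delta_qaly_per_woman = x$per_woman$delta_qaly,
    icer = x$icer,
    icer_label = x$icer_label,
    roi = x$roi,
    total_births = x$total_births
  )
}
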