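# Parameter-bundle data model: constructors, validation, CSV readers/writers.
# A parameter set is a list of five tibbles sharing one schema family:
#   cohorts         - maternal age-band cohorts (births, GDM prevalence)
#   epi             - single-year-of-age female epidemiology, ages 15..85
#   relative_risks  - treatment effects and progression RRs with 95% CIs
#   utilities       - age-band health utilities plus the T2DM state utility
#   costs           - unit costs, event probabilities and chronic cost schedule

PARAM_TABLES <- c("cohorts", "epi", "relative_risks", "utilities", "costs")

RR_PARAMETERS <- c(
  "rr_t2dm_after_gdm", "rr_gdm_base", "rr_gdm_diet", "rr_gdm_pa",
  "rr_gdm_diet_pa", "rr_t2dm_avoided_gdm", "gdm_prevalence_population"
)

COST_ITEMS <- c(
  "intervention_base", "intervention_diet", "intervention_pa",
  "intervention_diet_pa", "antenatal_gdm", "caesarean_cost", "induction_cost",
  "p_caesarean_gdm", "p_caesarean_no_gdm", "p_induction_gdm",
  "p_induction_no_gdm", "p_nicu_gdm", "p_nicu_no_gdm", "nicu_cost",
  "t2dm_annual_cost", "microcost_first_year", "microcost_subsequent_year",
  "microcost_direct_nonhealth", "microcost_income_subsidy"
)

COST_PROB_ITEMS <- grep("^p_", COST_ITEMS, value = TRUE)

#' Assemble a parameter set
#'
#' Bundles the five parameter tables into a single validated object, the one
#' input consumed by every downstream stage (cohort model, sensitivity
#' analyses, report writers).
#'
#' @param cohorts Tibble of maternal age-band cohorts with columns
#'   `band_label`, `age_low`, `age_high`, `representative_age`, `n_births`,
#'   `gdm_prevalence`, `preexisting_dm_prevalence`, `provenance`.
#' @param epi Tibble of single-year female epidemiology with columns `age`,
#'   `t2dm_incidence_total`, `all_cause_mortality`, `t2dm_mortality`,
#'   `t2dm_prevalence`, `population`, `provenance`, one row per age 15..85.
#' @param relative_risks Tibble with columns `parameter`, `mean`, `lower`,
#'   `upper`, `distribution`, `provenance` covering all of
#'   `r paste(RR_PARAMETERS, collapse = ", ")`.
#' @param utilities Tibble with columns `band`, `age_low`, `age_high`, `mean`,
#'   `lower`, `upper`, `distribution`, `provenance`; the T2DM state utility is
#'   the row with `band == "t2dm"`.
#' @param costs Tibble with columns `item`, `age_low`, `age_high`, `value`,
#'   `lower`, `upper`, `distribution`, `provenance`. The chronic schedule uses
#'   repeated `t2dm_annual_cost` rows with age bounds; all other items are
#'   age-free scalars.
#' @param check If `TRUE` (default), abort when [validate_parameters()] finds
#'   violations.
#' @return An object of class `parameter_set`.
#' @export
parameter_set <- function(cohorts, epi, relative_risks, utilities, costs,
                          check = TRUE) {
  ps <- structure(
    list(
      cohorts = as_tibble(cohorts),
      epi = as_tibble(epi),
      relative_risks = as_tibble(relative_risks),
      utilities = as_tibble(utilities),
      costs = as_tibble(costs)
    ),
    class = "parameter_set"
  )
  if (check) {
    v <- validate_parameters(ps)
    if (nrow(v) > 0) {
      abort(c("Invalid parameter set:",
              stats::setNames(v$message, rep("x", nrow(v)))))
    }
  }
  ps
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  cat("  cohorts:        ", nrow(x$cohorts), " age bands, ",
      format(round(sum(x$cohorts$n_births)), big.mark = ","),
      " births/year\n", sep = "")
  cat("  epi:            ages ", min(x$epi$age), "-", max(x$epi$age), "\n",
      sep = "")
  cat("  relative_risks: ", nrow(x$relative_risks), " parameters\n", sep = "")
  cat("  utilities:      ", nrow(x$utilities), " rows\n", sep = "")
  cat("  costs:          ", nrow(x$costs), " items\n", sep = "")
  invisible(x)
}

rr_value <- function(params, name) {
  i <- match(name, params$relative_risks$parameter)
  if (is.na(i)) abort(paste0("Relative-risk parameter not found: ", name))
  params$relative_risks$mean[i]
}

cost_value <- function(params, item) {
  i <- match(item, params$costs$item)
  if (is.na(i)) abort(paste0("Cost item not found: ", item))
  params$costs$value[i]
}

# per-age vector of the chronic T2DM management cost schedule
t2dm_cost_by_age <- function(costs, ages) {
  rows <- costs[costs$item == "t2dm_annual_cost", ]
  if (nrow(rows) == 0) abort("No `t2dm_annual_cost` rows in costs table.")
  out <- rep(NA_real_, length(ages))
  for (k in seq_len(nrow(rows))) {
    hit <- ages >= rows$age_low[k] & ages <= rows$age_high[k]
    out[hit] <- rows$value[k]
  }
  if (anyNA(out)) {
    abort("`t2dm_annual_cost` age bands do not cover all model ages.")
  }
  out
}

# per-age vector of healthy utility (band lookup; ages below the youngest
# band take that band's value, ages above the oldest take the oldest's)
utility_by_age <- function(utilities, ages) {
  bands <- utilities[utilities$band != "t2dm", ]
  out <- rep(NA_real_, length(ages))
  for (k in seq_len(nrow(bands))) {
    hit <- ages >= bands$age_low[k] & ages <= bands$age_high[k]
    out[hit] <- bands$mean[k]
  }
  lo <- min(bands$age_low)
  hi <- max(bands$age_high)
  out[ages < lo] <- bands$mean[which.min(bands$age_low)]
  out[ages > hi] <- bands$mean[which.max(bands$age_high)]
  out
}

#' Validate a parameter set
#'
#' Checks every structural and range invariant of the parameter bundle and
#' returns the violations as data rather than raising: probabilities and
#' utilities in `[0, 1]`, non-negative rates, costs and counts, CI bounds
#' bracketing means, cohort bands tiling ages 15-49 without overlap, the epi
#' table covering every single year of age 15-85, a non-negative derived
#' no-T2DM mortality rate, and presence of every required parameter row.
#'
#' @param params A `parameter_set` (or plain list with the same elements).
#' @return A tibble with columns `table`, `row`, `field`, `message`; zero rows
#'   when the set is valid.
#' @export
validate_parameters <- function(params) {
  out <- list()
  bad <- function(table, row, field, message) {
    out[[length(out) + 1]] <<- tibble(
      table = table, row = as.integer(row), field = field, message = message
    )
  }
  need <- function(tbl, name, cols) {
    miss <- setdiff(cols, names(tbl))
    for (m in miss) bad(name, NA, m, paste0(name, ": missing column `", m, "`"))
    length(miss) == 0
  }

  co <- params$cohorts
  if (need(co, "cohorts", c("band_label", "age_low", "age_high",
                            "representative_age", "n_births", "gdm_prevalence",
                            "preexisting_dm_prevalence"))) {
    for (i in seq_len(nrow(co))) {
      for (f in c("gdm_prevalence", "preexisting_dm_prevalence")) {
        v <- co[[f]][i]
        if (is.na(v) || v < 0 || v > 1) {
          bad("cohorts", i, f, paste0("cohorts[", co$band_label[i], "]: `", f,
                                      "` = ", v, " outside [0, 1]"))
        }
      }
      if (is.na(co$n_births[i]) || co$n_births[i] < 0) {
        bad("cohorts", i, "n_births", paste0("cohorts[", co$band_label[i],
                                             "]: negative or missing n_births"))
      }
      if (!(co$age_low[i] <= co$representative_age[i] &&
            co$representative_age[i] <= co$age_high[i])) {
        bad("cohorts", i, "representative_age",
            paste0("cohorts[", co$band_label[i],
                   "]: representative_age outside band"))
      }
    }
    ord <- order(co$age_low)
    lows <- co$age_low[ord]
    highs <- co$age_high[ord]
    tiles <- length(lows) > 0 && lows[1] == 15 && highs[length(highs)] == 49 &&
      all(lows[-1] == highs[-length(highs)] + 1)
    if (!tiles) {
      bad("cohorts", NA, "age_low",
          "cohorts: bands must tile ages 15-49 without gaps or overlap")
    }
  }

  ep <- params$epi
  if (need(ep, "epi", c("age", "t2dm_incidence_total", "all_cause_mortality",
                        "t2dm_mortality", "t2dm_prevalence", "population"))) {
    if (!identical(as.integer(sort(ep$age)), 15:85)) {
      bad("epi", NA, "age", "epi: ages must be exactly the single years 15-85")
    }
    for (f in c("t2dm_incidence_total", "all_cause_mortality",
                "t2dm_mortality", "population")) {
      i <- which(is.na(ep[[f]]) | ep[[f]] < 0)
      for (j in i) bad("epi", j, f,
                       paste0("epi[age ", ep$age[j], "]: `", f, "` negative or missing"))
    }
    i <- which(is.na(ep$t2dm_prevalence) | ep$t2dm_prevalence < 0 |
                 ep$t2dm_prevalence >= 1)
    for (j in i) bad("epi", j, "t2dm_prevalence",
                     paste0("epi[age ", ep$age[j], "]: t2dm_prevalence outside [0, 1)"))
    # derived non-T2DM mortality must be non-negative at every age >= 40
    ok <- !is.na(ep$all_cause_mortality) & !is.na(ep$t2dm_mortality) &
      !is.na(ep$t2dm_prevalence) & ep$t2dm_prevalence < 1
    neg <- which(ok & ep$age >= 40 &
                   (ep$all_cause_mortality - ep$t2dm_mortality * ep$t2dm_prevalence) < 0)
    for (j in neg) {
      bad("epi", j, "t2dm_mortality",
          paste0("epi[age ", ep$age[j],
                 "]: derived no-T2DM mortality is negative"))
    }
  }

  rr <- params$relative_risks
  if (need(rr, "relative_risks", c("parameter", "mean", "lower", "upper",
                                   "distribution"))) {
    miss <- setdiff(RR_PARAMETERS, rr$parameter)
    for (m in miss) bad("relative_risks", NA, m,
                        paste0("relative_risks: missing parameter `", m, "`"))
    for (i in seq_len(nrow(rr))) {
      p <- rr$parameter[i]
      if (is.na(rr$mean[i]) || rr$mean[i] <= 0) {
        bad("relative_risks", i, "mean",
            paste0("relative_risks[", p, "]: mean must be positive"))
      } else if (!is.na(rr$lower[i]) && !is.na(rr$upper[i]) &&
                 !(rr$lower[i] <= rr$mean[i] && rr$mean[i] <= rr$upper[i])) {
        bad("relative_risks", i, "mean",
            paste0("relative_risks[", p, "]: CI does not bracket mean"))
      }
      if (p == "gdm_prevalence_population" && !is.na(rr$mean[i]) &&
          (rr$mean[i] <= 0 || rr$mean[i] >= 1)) {
        bad("relative_risks", i, "mean",
            "relative_risks[gdm_prevalence_population]: must lie in (0, 1)")
      }
    }
  }

  ut <- params$utilities
  if (need(ut, "utilities", c("band", "age_low", "age_high", "mean", "lower",
                              "upper", "distribution"))) {
    if (!"t2dm" %in% ut$band) {
      bad("utilities", NA, "band", "utilities: missing `t2dm` state utility row")
    }
    for (i in seq_len(nrow(ut))) {
      if (is.na(ut$mean[i]) || ut$mean[i] < 0 || ut$mean[i] > 1) {
        bad("utilities", i, "mean",
            paste0("utilities[", ut$band[i], "]: utility outside [0, 1]"))
      }
    }
  }

  cs <- params$costs
  if (need(cs, "costs", c("item", "age_low", "age_high", "value", "lower",
                          "upper", "distribution"))) {
    miss <- setdiff(COST_ITEMS, cs$item)
    for (m in miss) bad("costs", NA, m,
                        paste0("costs: missing item `", m, "`"))
    for (i in seq_len(nrow(cs))) {
      v <- cs$value[i]
      if (is.na(v) || is.nan(v) || v < 0) {
        bad("costs", i, "value",
            paste0("costs[", cs$item[i], "]: value negative or missing"))
      } else if (cs$item[i] %in% COST_PROB_ITEMS && v > 1) {
        bad("costs", i, "value",
            paste0("costs[", cs$item[i], "]: probability above 1"))
      }
    }
  }

  if (length(out) == 0) {
    tibble(table = character(), row = integer(), field = character(),
           message = character())
  } else {
    bind_rows(out)
  }
}

bundle_files <- function() {
  paste0(PARAM_TABLES, ".csv")
}

bundle_col_types <- function(table) {
  switch(table,
    cohorts = readr::cols(
      band_label = readr::col_character(),
      provenance = readr::col_character(),
      .default = readr::col_double()
    ),
    epi = readr::cols(
      provenance = readr::col_character(),
      .default = readr::col_double()
    ),
    relative_risks = readr::cols(
      parameter = readr::col_character(),
      distribution = readr::col_character(),
      provenance = readr::col_character(),
      .default = readr::col_double()
    ),
    utilities = readr::cols(
      band = readr::col_character(),
      distribution = readr::col_character(),
      provenance = readr::col_character(),
      .default = readr::col_double()
    ),
    costs = readr::cols(
      item = readr::col_character(),
      distribution = readr::col_character(),
      provenance = readr::col_character(),
      .default = readr::col_double()
    )
  )
}

#' Load a parameter bundle from a directory of CSV files
#'
#' Reads `cohorts.csv`, `epi.csv`, `relative_risks.csv`, `utilities.csv` and
#' `costs.csv` from `path`, validates the assembled set and aborts with the
#' full list of violations (each naming the offending file, row and field) if
#' any invariant fails.
#'
#' @param path Directory containing the five bundle CSVs.
#' @return A validated `parameter_set`.
#' @seealso [write_parameter_bundle()], [load_reference_fixture()]
#' @export
load_parameter_bundle <- function(path) {
  files <- file.path(path, bundle_files())
  missing <- bundle_files()[!file.exists(files)]
  if (length(missing) > 0) {
    abort(paste0("Parameter bundle at `", path, "` is missing: ",
                 paste(sub("\\.csv$", "", missing), collapse = ", ")))
  }
  tabs <- lapply(PARAM_TABLES, function(tb) {
    df <- readr::read_csv(file.path(path, paste0(tb, ".csv")),
                          col_types = bundle_col_types(tb),
                          progress = FALSE)
    prob <- readr::problems(df)
    if (nrow(prob) > 0) {
      abort(paste0("Malformed ", tb, ".csv: row ", prob$row[1], ", ",
                   prob$expected[1], " expected but got `", prob$actual[1], "`"))
    }
    df
  })
  names(tabs) <- PARAM_TABLES
  ps <- parameter_set(tabs$cohorts, tabs$epi, tabs$relative_risks,
                      tabs$utilities, tabs$costs, check = FALSE)
  v <- validate_parameters(ps)
  if (nrow(v) > 0) {
    abort(c(paste0("Parameter bundle at `", path, "` failed validation:"),
            stats::setNames(v$message, rep("x", nrow(v)))))
  }
  ps
}

#' Write a parameter bundle to a directory of CSV files
#'
#' Emits the five bundle CSVs with deterministic row and column ordering, so
#' that writing the same set twice produces byte-identical files and a
#' write/load round trip reproduces the values exactly.
#'
#' @param params A valid `parameter_set`; sets containing `NaN` or missing
#'   values in required fields are refused.
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_parameter_bundle <- function(params, path) {
  v <- validate_parameters(params)
  if (nrow(v) > 0) {
    abort(c("Refusing to write an invalid parameter set:",
            stats::setNames(v$message, rep("x", nrow(v)))))
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ordered <- list(
    cohorts = dplyr::arrange(params$cohorts, .data$age_low),
    epi = dplyr::arrange(params$epi, .data$age),
    relative_risks = dplyr::arrange(params$relative_risks,
                                    match(.data$parameter, RR_PARAMETERS)),
    utilities = dplyr::arrange(params$utilities, is.na(.data$age_low),
                               .data$age_low),
    costs = dplyr::arrange(params$costs, match(.data$item, COST_ITEMS),
                           .data$age_low)
  )
  for (tb in PARAM_TABLES) {
    readr::write_csv(ordered[[tb]], file.path(path, paste0(tb, ".csv")),
                     progress = FALSE)
  }
  invisible(path)
}
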