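# Epidemiological rate machinery: relative-risk adjustment for population
# prevalence, incidence decomposition into GDM / no-GDM strata, background
# (non-diabetic) mortality derivation, Poisson-spline rate smoothing, and
# rate -> probability conversion.

#' Adjust a relative risk for exposure prevalence in the reference population
#'
#' Published relative risks for progression to type 2 diabetes after
#' gestational diabetes (GDM) compare exposed with unexposed women, whereas
#' registry incidence rates refer to the total female population (a mixture of
#' both groups). Multiplying the total-population incidence by a raw RR would
#' double-count the exposed group's contribution. The correction
#'
#' \deqn{RR_{adj} = \frac{RR}{p \, RR + (1 - p)}}
#'
#' where \eqn{p} is the population prevalence of the exposure, rescales the RR
#' so that \eqn{RR_{adj} \times i_{total}} is the incidence in the exposed
#' group and the prevalence-weighted mixture of the two strata recovers
#' \eqn{i_{total}} exactly.
#'
#' @param rr_original Relative risk (exposed vs unexposed), positive scalar or
#'   vector.
#' @param prevalence Exposure prevalence in the total population, in `[0, 1)`.
#' @return Adjusted relative risk(s), same length as `rr_original`.
#' @examples
#' adjust_relative_risk(9.51, 0.0065) # ~ 9.01
#' @export
adjust_relative_risk <- function(rr_original, prevalence) {
  stopifnot(is.numeric(rr_original), is.numeric(prevalence))
  if (any(rr_original <= 0)) {
    abort("`rr_original` must be positive.")
  }
  if (any(prevalence < 0) || any(prevalence >= 1 & rr_original != 1)) {
    abort("`prevalence` must lie in [0, 1); prevalence 1 leaves no unexposed group.")
  }
  rr_original / (prevalence * rr_original + (1 - prevalence))
}

#' Decompose a total-population incidence rate into exposure strata
#'
#' Splits the total female type 2 diabetes incidence into the incidence among
#' women with a GDM history and among women without, such that (i) their ratio
#' equals the original relative risk and (ii) the prevalence-weighted mixture
#' reproduces the total incidence:
#' `i_gdm = RR_adj * i_total`, `i_no_gdm = i_gdm / RR_original`.
#'
#' @param i_total Incidence rate in the total population (events per
#'   person-year), scalar or vector.
#' @param prevalence Population prevalence of GDM history, in `[0, 1)`.
#' @param rr_original Unadjusted relative risk (GDM vs no GDM).
#' @return A tibble with columns `i_total`, `i_gdm`, `i_no_gdm`,
#'   `rr_original`, `rr_adjusted`.
#' @examples
#' split_t2dm_incidence(0.005, 0.0065, 9.51)
#' @export
split_t2dm_incidence <- function(i_total, prevalence, rr_original) {
  if (any(i_total < 0)) abort("`i_total` must be non-negative.")
  rr_adj <- adjust_relative_risk(rr_original, prevalence)
  i_gdm <- rr_adj * i_total
  tibble(
    i_total = i_total,
    i_gdm = i_gdm,
    i_no_gdm = i_gdm / rr_original,
    rr_original = rr_original,
    rr_adjusted = rr_adj
  )
}

#' Mortality rate in the population without type 2 diabetes
#'
#' For ages 40 and over, removes prevalent type 2 diabetes cases and their
#' deaths from the all-cause totals:
#' `(all-cause deaths - T2DM deaths) / (population - T2DM prevalent cases)`.
#' Below age 40 diabetes-attributable deaths in women are negligible and the
#' all-cause rate is used unchanged for both health states.
#'
#' @param age Age in years (scalar or vector, recycled against the counts).
#' @param all_cause_deaths,population Total annual deaths and mid-year
#'   population.
#' @param t2dm_deaths,t2dm_prevalent Annual deaths among, and prevalent count
#'   of, women with type 2 diabetes.
#' @return Death rate (per person-year) for the no-T2DM state.
#' @examples
#' derive_no_t2dm_mortality(50, 500, 1e5, 50, 5000) # 450 / 95000
#' @export
derive_no_t2dm_mortality <- function(age, all_cause_deaths, population,
                                     t2dm_deaths, t2dm_prevalent) {
  if (any(c(all_cause_deaths, population, t2dm_deaths, t2dm_prevalent) < 0)) {
    abort("Counts must be non-negative.")
  }
  if (any(t2dm_prevalent >= population)) {
    abort("`t2dm_prevalent` must be smaller than `population`.")
  }
  out <- ifelse(age >= 40,
    (all_cause_deaths - t2dm_deaths) / (population - t2dm_prevalent),
    all_cause_deaths / population
  )
  if (any(out < 0)) {
    abort("Derived no-T2DM mortality is negative: T2DM deaths exceed all-cause deaths.")
  }
  out
}

#' Smooth age-banded rates to single-year-of-age rates
#'
#' Fits a Poisson regression with a restricted cubic (natural) spline in age to
#' banded event counts, with log person-year exposure as offset, and predicts
#' the fitted rate at every single year of age spanned by the bands. Knots are
#' placed at exposure-weighted age quantiles.
#'
#' @param bands A data frame with columns `age_low`, `age_high` (inclusive
#'   integer bounds), `rate` (events per person-year) and `exposure`
#'   (person-years). At least four bands are required.
#' @param n_knots Number of spline knots (default 4).
#' @return A tibble with columns `age` (every integer year covered) and `rate`
#'   (fitted events per person-year, non-negative).
#' @export
smooth_single_year_rates <- function(bands, n_knots = 4) {
  bands <- as_tibble(bands)
  req <- c("age_low", "age_high", "rate", "exposure")
  if (!all(req %in% names(bands))) {
    abort(paste0("`bands` needs columns: ", paste(req, collapse = ", ")))
  }
  if (nrow(bands) < n_knots) {
    abort("Need at least as many age bands as spline knots.")
  }
  mid <- (bands$age_low + bands$age_high) / 2
  events <- bands$rate * bands$exposure
  ord <- order(mid)
  cw <- (cumsum(bands$exposure[ord]) - bands$exposure[ord] / 2) / sum(bands$exposure)
  knots <- unique(stats::approx(cw, mid[ord], xout = seq(0, 1, length.out = n_knots),
                                rule = 2, ties = "ordered")$y)
  fit <- suppressWarnings(glm(
    events ~ splines::ns(mid, knots = knots[-c(1, length(knots))],
                         Boundary.knots = range(knots)),
    family = poisson(), offset = log(bands$exposure)
  ))
  # predict at single years from the design matrix directly: the offset is
  # log-exposure, so the linear predictor without it is the log-rate
  ages <- seq(min(bands$age_low), max(bands$age_high))
  X <- splines::ns(ages, knots = knots[-c(1, length(knots))],
                   Boundary.knots = range(knots))
  rate <- as.numeric(exp(cbind(1, X) %*% coef(fit)))
  tibble(age = ages, rate = rate)
}

#' Convert an event rate to a per-cycle transition probability
#'
#' Uses the constant-hazard (exponential) conversion `1 - exp(-rate * dt)`,
#' which guarantees a probability strictly below 1 at any rate.
#'
#' @param rate Events per year, non-negative.
#' @param dt Cycle length in years (default 1).
#' @return Probability in `[0, 1)`.
#' @examples
#' rate_to_probability(0.02) # 0.019801...
#' @export
rate_to_probability <- function(rate, dt = 1) {
  if (any(rate < 0)) abort("`rate` must be non-negative.")
  1 - exp(-rate * dt)
}
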