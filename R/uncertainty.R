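# Deterministic and probabilistic sensitivity analysis, built on the
# compiled model: each varied parameter maps onto one field of the internal
# theta vector, so re-running the full two-arm comparison per draw is cheap.

# Registry of varied parameters for the active configuration: name, the
# theta field it overrides (with index for age-band utilities), sampling
# family and range. Cost ranges follow the SE = se_frac * mean convention
# (bounds at +/- 1.96 SE); RRs and utilities use their published 95% CIs.
model_parameters <- function(params, config, cost_se_frac = 0.10) {
  rr <- params$relative_risks
  rr_row <- function(p) rr[rr$parameter == p, ]
  ut <- params$utilities[params$utilities$band != "t2dm", ]
  ut <- ut[order(ut$age_low), ]
  t2 <- params$utilities[params$utilities$band == "t2dm", ]

  rows <- list()
  add <- function(name, field, index, family, mean, lower, upper) {
    rows[[length(rows) + 1]] <<- tibble(
      name = name, field = field, index = index, family = family,
      mean = mean, lower = lower, upper = upper
    )
  }
  r1 <- rr_row("rr_t2dm_after_gdm")
  add("rr_t2dm_after_gdm", "rr_t2dm", NA, "lognormal", r1$mean, r1$lower,
      r1$upper)
  r2 <- rr_row(subgroup_rr_name(config$subgroup))
  add("rr_gdm_intervention", "rr_gdm", NA, "lognormal", r2$mean, r2$lower,
      r2$upper)
  for (i in seq_len(nrow(ut))) {
    add(paste0("utility_", ut$band[i]), "u_bands", i, "beta", ut$mean[i],
        ut$lower[i], ut$upper[i])
  }
  add("utility_t2dm", "u_t2", NA, "beta", t2$mean, t2$lower, t2$upper)

  cost_add <- function(name, field, mean) {
    se <- cost_se_frac * mean
    add(name, field, NA, "gamma", mean, mean - 1.96 * se, mean + 1.96 * se)
  }
  cost_add("intervention_cost", "c_intervention",
           cost_value(params, subgroup_cost_item(config$subgroup)))
  cost_add("antenatal_gdm", "c_antenatal", cost_value(params, "antenatal_gdm"))
  cost_add("caesarean_cost", "c_caesarean",
           cost_value(params, "caesarean_cost"))
  cost_add("induction_cost", "c_induction",
           cost_value(params, "induction_cost"))
  if (config$include_nicu_scn) {
    cost_add("nicu_cost", "c_nicu", cost_value(params, "nicu_cost"))
  }
  if (config$scenario %in% c("s3_microcost_health", "s4_microcost_societal")) {
    cost_add("microcost_first_year", "c_micro_first",
             cost_value(params, "microcost_first_year"))
    cost_add("microcost_subsequent_year", "c_micro_subseq",
             cost_value(params, "microcost_subsequent_year"))
    if (config$scenario == "s4_microcost_societal") {
      cost_add("microcost_direct_nonhealth", "c_nonhealth",
               cost_value(params, "microcost_direct_nonhealth"))
      cost_add("microcost_income_subsidy", "c_subsidy",
               cost_value(params, "microcost_income_subsidy"))
    }
  } else {
    # the chronic schedule is age-specific; vary it through a common scale
    cost_add("t2dm_annual_cost_scale", "t2dm_cost_scale", 1)
  }
  out <- bind_rows(rows)
  attr(out, "cost_se_frac") <- cost_se_frac
  out
}

apply_theta_override <- function(theta, field, index, value) {
  if (!is.na(index)) {
    theta[[field]][index] <- value
  } else {
    theta[[field]] <- value
  }
  theta
}

roi_from_raw <- function(raw, config) {
  inc <- raw$incremental
  if (inc[["c_intervention"]] <= 0) return(NA_real_)
  compute_roi(
    inc[["c_intervention"]], inc[["c_pregnancy"]], inc[["c_t2dm"]],
    nicu_increment = inc[["c_nicu"]], societal_increment = inc[["c_societal"]],
    include_nicu = config$include_nicu_scn,
    include_societal = config$scenario == "s4_microcost_societal"
  )
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the full comparison with each parameter in turn set to the lower
#' and upper bound of its declared range (published 95% CIs for relative
#' risks and utilities; +/- 1.96 SE with SE = 10% of the mean for costs),
#' holding all other parameters at base values. Entries are returned sorted
#' by the width of the incremental-cost range they induce, ready for a
#' tornado diagram.
#'
#' @param params A `parameter_set`.
#' @param config A [model_config()].
#' @param parameters Parameter table from `model_parameters()`; defaults to
#'   the full registry for the configuration.
#' @return A tibble of class `cea_tornado`: one row per parameter with the
#'   bounds, incremental cost/QALY and ICER at each bound, and the
#'   incremental-cost range width.
#' @export
one_way_dsa <- function(params, config = model_config(),
                        parameters = model_parameters(params, config)) {
  cm <- compile_model(params, config)
  base <- base_theta(params, config)
  run_at <- function(field, index, value) {
    raw <- run_compiled(cm, apply_theta_override(base, field, index, value))
    ic <- compute_icer(raw$delta_cost, raw$delta_qaly)
    c(delta_cost = raw$delta_cost, delta_qaly = raw$delta_qaly,
      icer = if (is.na(ic$icer)) {
        if (identical(ic$label, "Dominant")) -Inf else Inf
      } else {
        ic$icer
      })
  }
  res <- purrr::pmap(parameters, function(name, field, index, family, mean,
                                          lower, upper) {
    lo <- run_at(field, index, lower)
    hi <- run_at(field, index, upper)
    tibble(
      parameter = name, low_input = lower, high_input = upper,
      delta_cost_low = lo[["delta_cost"]], delta_cost_high = hi[["delta_cost"]],
      delta_qaly_low = lo[["delta_qaly"]], delta_qaly_high = hi[["delta_qaly"]],
      icer_low = lo[["icer"]], icer_high = hi[["icer"]]
    )
  })
  out <- bind_rows(res) %>%
    mutate(range_width = abs(.data$delta_cost_high - .data$delta_cost_low)) %>%
    arrange(dplyr::desc(.data$range_width))
  class(out) <- c("cea_tornado", class(out))
  out
}

#' Probabilistic sensitivity analysis distributions
#'
#' The parameter registry with fitted sampling distributions: log-normal for
#' relative risks, beta (method of moments) for utilities, gamma (SE = 10% of
#' the mean by default) for costs. Returned as data so callers can inspect or
#' modify (e.g. collapse to degenerate distributions) before [run_psa()].
#'
#' @inheritParams one_way_dsa
#' @param cost_se_frac SE of cost parameters as a fraction of the mean.
#' @return The `model_parameters()` tibble with a `dist` list-column of
#'   [fit_distribution()] objects.
#' @export
psa_distributions <- function(params, config = model_config(),
                              cost_se_frac = 0.10) {
  reg <- model_parameters(params, config, cost_se_frac = cost_se_frac)
  reg$dist <- purrr::pmap(
    reg[, c("family", "mean", "lower", "upper")],
    function(family, mean, lower, upper) {
      if (family == "gamma") {
        fit_distribution("gamma", mean, se_frac = cost_se_frac)
      } else {
        fit_distribution(family, mean, lower, upper)
      }
    }
  )
  reg
}

#' Run the probabilistic sensitivity analysis
#'
#' Draws every sampled parameter independently from its fitted distribution,
#' re-runs the full two-arm comparison per iteration, and summarises the
#' joint uncertainty: per-iteration incremental costs and QALYs (total and
#' per woman) and ROI, the fractions of iterations in each quadrant of the
#' cost-effectiveness plane, and percentile 95% CIs. Draws yielding a
#' structurally invalid model (GDM probability above 1 in any cohort, or an
#' intervention GDM RR outside the decision tree's domain) are resampled and
#' counted. Fixing the seed reproduces the summary exactly.
#'
#' @param params A `parameter_set`.
#' @param config A [model_config()].
#' @param n_iterations Number of iterations (default from `config`, 10,000).
#' @param seed Integer seed (default from `config`).
#' @param distributions Distribution table from [psa_distributions()].
#' @return An object of class `cea_psa`: `iterations` tibble, `quadrants`,
#'   percentile `ci` tibble, `n_iterations`, `n_resampled`, `seed`, `config`.
#' @export
run_psa <- function(params, config = model_config(),
                    n_iterations = config$psa_iterations,
                    seed = config$rng_seed,
                    distributions = psa_distributions(params, config)) {
  cm <- compile_model(params, config)
  base <- base_theta(params, config)
  n_par <- nrow(distributions)
  max_q <- max(vapply(cm$coh, function(x) x$q, numeric(1)))

  res <- withr::with_seed(seed, {
    draws <- vapply(distributions$dist, dist_sample, numeric(n_iterations),
                    n = n_iterations)
    # resample structurally invalid draws (kept rare by the families used)
    rr_col <- match("rr_gdm_intervention", distributions$name)
    n_resampled <- 0L
    if (!is.na(rr_col)) {
      bad <- which(draws[, rr_col] * max_q > 1 | draws[, rr_col] > 1.5 |
                     draws[, rr_col] <= 0)
      while (length(bad) > 0) {
        n_resampled <- n_resampled + length(bad)
        draws[bad, rr_col] <- dist_sample(distributions$dist[[rr_col]],
                                          length(bad))
        bad <- bad[draws[bad, rr_col] * max_q > 1 | draws[bad, rr_col] > 1.5 |
                     draws[bad, rr_col] <= 0]
      }
    }
    dc <- dq <- roi <- numeric(n_iterations)
    fields <- distributions$field
    idxs <- distributions$index
    for (it in seq_len(n_iterations)) {
      theta <- base
      for (j in seq_len(n_par)) {
        theta <- apply_theta_override(theta, fields[j], idxs[j], draws[it, j])
      }
      raw <- run_compiled(cm, theta)
      dc[it] <- raw$delta_cost
      dq[it] <- raw$delta_qaly
      roi[it] <- roi_from_raw(raw, config)
    }
    list(dc = dc, dq = dq, roi = roi, n_resampled = n_resampled)
  })

  iterations <- tibble(
    iteration = seq_len(n_iterations),
    delta_cost = res$dc,
    delta_qaly = res$dq,
    delta_cost_per_woman = res$dc / cm$total_births,
    delta_qaly_per_woman = res$dq / cm$total_births,
    roi = res$roi
  )
  quadrants <- tibble(
    quadrant = c("more QALYs, cost-saving", "more QALYs, costlier",
                 "fewer QALYs, costlier", "fewer QALYs, cost-saving"),
    fraction = c(
      mean(res$dq > 0 & res$dc < 0),
      mean(res$dq > 0 & res$dc >= 0),
      mean(res$dq <= 0 & res$dc >= 0),
      mean(res$dq <= 0 & res$dc < 0)
    )
  )
  pci <- function(x) {
    qs <- quantile(x, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    c(mean = base::mean(x, na.rm = TRUE), lower = qs[1], upper = qs[2])
  }
  ci <- bind_rows(
    tibble(quantity = "delta_cost_per_woman",
           !!!pci(iterations$delta_cost_per_woman)),
    tibble(quantity = "delta_qaly_per_woman",
           !!!pci(iterations$delta_qaly_per_woman)),
    tibble(quantity = "roi", !!!pci(iterations$roi))
  )
  structure(
    list(iterations = iterations, quadrants = quadrants, ci = ci,
         n_iterations = n_iterations, n_resampled = res$n_resampled,
         seed = as.integer(seed), config = config,
         total_births = cm$total_births),
    class = "cea_psa"
  )
}

#' @export
print.cea_psa <- function(x, ...) {
  cat("<cea_psa>  ", x$n_iterations, " iterations (seed ", x$seed, ")\n",
      sep = "")
  cs <- x$quadrants$fraction[x$quadrants$quadrant == "more QALYs, cost-saving"]
  cat("  cost-saving iterations: ", round(100 * cs, 1), "%\n", sep = "")
  print(x$ci)
  invisible(x)
}

#' Tidy PSA iterations
#'
#' @param x A `cea_psa`.
#' @param ... Unused.
#' @return The per-iteration tibble (incremental cost and QALYs, ROI).
#' @export
tidy.cea_psa <- function(x, ...) {
  x$iterations
}

#' One-row PSA summary
#'
#' @param x A `cea_psa`.
#' @param ... Unused.
#' @return A one-row tibble with iteration count, mean increments, the
#'   cost-saving quadrant fraction and the ROI percentile CI.
#' @export
glance.cea_psa <- function(x, ...) {
  roi_ci <- x$ci[x$ci$quantity == "roi", ]
  tibble(
    n_iterations = x$n_iterations,
    n_resampled = x$n_resampled,
    mean_delta_cost = base::mean(x$iterations$delta_cost),
    mean_delta_qaly = base::mean(x$iterations$delta_qaly),
    pct_cost_saving = 100 *
      x$quadrants$fraction[x$quadrants$quadrant == "more QALYs, cost-saving"],
    roi_mean = roi_ci$mean,
    roi_lower = roi_ci$lower,
    roi_upper = roi_ci$upper
  )
}
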