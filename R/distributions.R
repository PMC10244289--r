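# Parameter distributions for probabilistic sensitivity analysis: beta for
# utilities, log-normal for relative risks, gamma for costs (SE assumed 10%
# of the mean, per the deterministic cost sensitivity convention).

#' Fit a sampling distribution from a mean and 95% interval
#'
#' Fits the two-parameter family used in the probabilistic sensitivity
#' analysis for each parameter class:
#' \itemize{
#'   \item `beta` (utilities, probabilities): method of moments with
#'     `SE = (upper - lower) / 3.92`.
#'   \item `lognormal` (relative risks): `sdlog = (log(upper) - log(lower)) /
#'     3.92`, with `meanlog` chosen so the distribution's mean equals the
#'     target mean (`meanlog = log(mean) - sdlog^2 / 2`).
#'   \item `gamma` (costs): `SE = se_frac * mean` (default 10% of the mean);
#'     the interval arguments are ignored.
#' }
#' A zero-variance request (`lower == upper == mean`, or a gamma with
#' `se_frac = 0`) yields a degenerate distribution that always returns the
#' mean, so a fully degenerate PSA collapses to the deterministic run.
#'
#' @param family `"beta"`, `"lognormal"` or `"gamma"`.
#' @param mean Target mean.
#' @param lower,upper 95% interval bounds (required for beta/lognormal).
#' @param se_frac For gamma only: SE as a fraction of the mean.
#' @return An object of class `dist_spec`: family, mean, bounds and the
#'   derived shape parameters.
#' @examples
#' fit_distribution("beta", 0.785, 0.68, 0.89)
#' fit_distribution("lognormal", 9.51, 7.14, 12.67)
#' fit_distribution("gamma", 228)
#' @export
fit_distribution <- function(family = c("beta", "lognormal", "gamma"),
                             mean, lower = NA, upper = NA, se_frac = 0.10) {
  family <- match.arg(family)
  if (family %in% c("beta", "lognormal")) {
    if (is.na(lower) || is.na(upper)) {
      abort(paste0(family, " fit needs `lower` and `upper`."))
    }
    if (!(lower <= mean && mean <= upper)) {
      abort("Need lower <= mean <= upper.")
    }
  }
  pars <- switch(family,
    beta = {
      se <- (upper - lower) / 3.92
      if (se == 0) {
        list(degenerate = TRUE)
      } else {
        v <- se^2
        if (v >= mean * (1 - mean)) {
          abort("Infeasible beta moments: variance >= mean * (1 - mean).")
        }
        a <- mean * (mean * (1 - mean) / v - 1)
        list(shape1 = a, shape2 = a * (1 - mean) / mean, degenerate = FALSE)
      }
    },
    lognormal = {
      if (mean <= 0 || lower <= 0) abort("lognormal needs positive values.")
      sdlog <- (log(upper) - log(lower)) / 3.92
      list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog,
           degenerate = sdlog == 0)
    },
    gamma = {
      if (mean < 0) abort("gamma needs a non-negative mean.")
      se <- se_frac * mean
      if (se == 0) {
        list(degenerate = TRUE)
      } else {
        list(shape = (mean / se)^2, rate = mean / se^2, degenerate = FALSE)
      }
    }
  )
  structure(
    c(list(family = family, mean = mean, lower = lower, upper = upper), pars),
    class = "dist_spec"
  )
}

#' Draw from a fitted distribution
#'
#' @param spec A [fit_distribution()] object.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
dist_sample <- function(spec, n) {
  if (isTRUE(spec$degenerate)) return(rep(spec$mean, n))
  switch(spec$family,
    beta = rbeta(n, spec$shape1, spec$shape2),
    lognormal = rlnorm(n, spec$meanlog, spec$sdlog),
    gamma = rgamma(n, shape = spec$shape, rate = spec$rate)
  )
}

#' Quantiles of a fitted distribution
#'
#' @param spec A [fit_distribution()] object.
#' @param p Probabilities.
#' @return Numeric vector of quantiles.
#' @export
dist_quantile <- function(spec, p) {
  if (isTRUE(spec$degenerate)) return(rep(spec$mean, length(p)))
  switch(spec$family,
    beta = qbeta(p, spec$shape1, spec$shape2),
    lognormal = qlnorm(p, spec$meanlog, spec$sdlog),
    gamma = qgamma(p, shape = spec$shape, rate = spec$rate)
  )
}

#' @export
print.dist_spec <- function(x, ...) {
  cat("<dist_spec ", x$family, ">  mean ", x$mean, sep = "")
  if (!is.na(x$lower)) cat("  [", x$lower, ", ", x$upper, "]", sep = "")
  if (isTRUE(x$degenerate)) cat("  (degenerate)")
  cat("\n")
  invisible(x)
}
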