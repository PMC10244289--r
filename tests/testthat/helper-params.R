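# Shared fixtures, built once per test run.

ref_params <- load_reference_fixture()

# a single-cohort variant (all births in 30-34) for cheap exact checks
one_cohort_params <- local({
  p <- ref_params
  p$cohorts$n_births <- ifelse(p$cohorts$band_label == "30-34", 10000, 0)
  p
})

# utilities all equal to 1 (QALYs collapse to life-years)
unit_utilities <- function(params) {
  params$utilities$mean <- 1
  params$utilities$lower <- 1
  params$utilities$upper <- 1
  params
}

base_config <- model_config()

# independent band lookup for utility-weighting cross-checks
utility_by_age_oracle <- function(utilities, ages) {
  bands <- utilities[utilities$band != "t2dm", ]
  bands <- bands[order(bands$age_low), ]
  vapply(ages, function(a) {
    hit <- which(bands$age_low <= a & a <= bands$age_high)
    if (length(hit) == 1) return(bands$mean[hit])
    if (a < min(bands$age_low)) bands$mean[1] else bands$mean[nrow(bands)]
  }, numeric(1))
}

expect_rel_equal <- function(x, y, tol = 1e-12) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-300)), tol)
}
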