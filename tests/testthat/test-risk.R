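test_that("relative-risk prevalence adjustment matches the printed formula", {
  expect_equal(round(adjust_relative_risk(9.51, 0.0065), 2), 9.01)
  expect_equal(adjust_relative_risk(1.0, 0.30), 1.0)
  expect_equal(adjust_relative_risk(2.0, 0.50), 4 / 3, tolerance = 1e-12)
  expect_error(adjust_relative_risk(-2, 0.1))
  expect_error(adjust_relative_risk(2, 1))
})

test_that("adjusted RR decreases monotonically in prevalence for RR > 1", {
  prev <- seq(0, 0.9, by = 0.05)
  vals <- adjust_relative_risk(rep(9.51, length(prev)), prev)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals <= 9.51))
})

test_that("incidence decomposition satisfies mixture and ratio identities", {
  # brute-force oracle: solve p*x*rr + (1-p)*x = i_total for x = i_no_gdm
  sp <- split_t2dm_incidence(0.005, 0.0065, 9.51)
  x <- 0.005 / (0.0065 * 9.51 + (1 - 0.0065))
  expect_equal(sp$i_no_gdm, x, tolerance = 1e-12)
  expect_equal(sp$i_gdm, x * 9.51, tolerance = 1e-12)
  expect_equal(sp$i_no_gdm, 0.004738, tolerance = 1e-4)
  expect_equal(sp$i_gdm, 0.045058, tolerance = 1e-4)

  # trivial ends
  expect_equal(unlist(split_t2dm_incidence(0.01, 0.2, 1)[c("i_gdm", "i_no_gdm")]),
               c(i_gdm = 0.01, i_no_gdm = 0.01), tolerance = 1e-12)
  sp0 <- split_t2dm_incidence(0.01, 0, 3)
  expect_equal(sp0$i_no_gdm, 0.01, tolerance = 1e-12)
  expect_equal(sp0$i_gdm, 0.03, tolerance = 1e-12)

  # property: identities hold across random draws
  withr::with_seed(11, {
    for (k in 1:200) {
      i_tot <- runif(1, 0, 0.05)
      p <- runif(1, 0, 0.5)
      rr <- exp(runif(1, -1, 3))
      s <- split_t2dm_incidence(i_tot, p, rr)
      expect_rel_equal(s$i_gdm / s$i_no_gdm, rr)
      expect_rel_equal(p * s$i_gdm + (1 - p) * s$i_no_gdm, i_tot)
    }
  })
})

test_that("background mortality subtraction follows the age-40 rule", {
  expect_equal(derive_no_t2dm_mortality(50, 500, 1e5, 50, 5000), 450 / 95000)
  expect_equal(derive_no_t2dm_mortality(50, 500, 1e5, 0, 0), 500 / 1e5)
  # below 40 the all-cause rate is used unchanged regardless of T2DM inputs
  expect_equal(derive_no_t2dm_mortality(35, 500, 1e5, 400, 5000), 500 / 1e5)
  expect_error(derive_no_t2dm_mortality(50, 100, 1e5, 200, 5000), "negative")
})

test_that("spline smoothing recovers flat and Gompertz-shaped rate curves", {
  flat <- tibble::tibble(
    age_low = seq(40, 75, 5), age_high = seq(44, 79, 5),
    rate = 0.01, exposure = 1e5
  )
  sm <- smooth_single_year_rates(flat)
  expect_true(all(sm$rate >= 0))
  expect_equal(sm$rate, rep(0.01, nrow(sm)), tolerance = 1e-6)
  # exposure conservation: band-aggregated fitted deaths match observed
  for (b in seq_len(nrow(flat))) {
    fitted_deaths <- sum(sm$rate[sm$age >= flat$age_low[b] &
                                   sm$age <= flat$age_high[b]]) * 1e5 / 5
    expect_equal(fitted_deaths, 0.01 * 1e5, tolerance = 0.02 * 0.01 * 1e5)
  }

  gomp <- function(a) 2e-5 * exp(0.09 * (a - 40))
  ages <- 40:84
  banded <- tibble::tibble(
    age_low = seq(40, 80, 5), age_high = seq(44, 84, 5)
  )
  banded$rate <- vapply(seq_len(nrow(banded)), function(b) {
    mean(gomp(banded$age_low[b]:banded$age_high[b]))
  }, numeric(1))
  banded$exposure <- 1e5
  sm2 <- smooth_single_year_rates(banded)
  mid <- sm2$age >= 45 & sm2$age <= 80
  expect_true(all(abs(sm2$rate[mid] - gomp(sm2$age[mid])) /
                    gomp(sm2$age[mid]) < 0.05))
  # monotone-increasing band inputs give a monotone fitted curve at midpoints
  mids <- (banded$age_low + banded$age_high) / 2
  fit_at_mid <- sm2$rate[match(mids, sm2$age)]
  expect_true(all(diff(fit_at_mid) > 0))
  expect_error(smooth_single_year_rates(flat[1:3, ]), "bands")
})

test_that("rate to probability conversion is exponential with Taylor bound", {
  expect_equal(rate_to_probability(0, 1), 0)
  expect_equal(rate_to_probability(0.02, 1), 1 - exp(-0.02))
  expect_equal(rate_to_probability(0.02, 1), 0.019801, tolerance = 1e-4)
  rates <- c(1e-5, 1e-3, 0.05, 0.2)
  p <- rate_to_probability(rates, 1)
  expect_true(all(abs(p - rates) <= rates^2 / 2))
  expect_true(all(rate_to_probability(c(2, 5, 20), 1) < 1))
})
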