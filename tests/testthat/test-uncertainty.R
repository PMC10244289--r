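test_that("one-way DSA: degenerate ranges give zero width, effect bounds order ICERs", {
  p <- ref_params
  cfg <- base_config
  reg <- gdmcea:::model_parameters(p, cfg)

  # parameter fixed at its base value at both bounds: zero-width entry
  fixed <- reg[reg$name == "antenatal_gdm", ]
  fixed$lower <- fixed$mean
  fixed$upper <- fixed$mean
  t_fixed <- one_way_dsa(p, cfg, parameters = fixed)
  expect_equal(t_fixed$range_width, 0)
  expect_equal(t_fixed$delta_cost_low, t_fixed$delta_cost_high)

  # weaker intervention effect (RR 0.77 vs 0.58) averts fewer cases: the
  # signed ICER (negative = dominant) is at least as large at the high bound
  rr <- reg[reg$name == "rr_gdm_intervention", ]
  expect_equal(c(rr$lower, rr$upper), c(0.58, 0.77))
  t_rr <- one_way_dsa(p, cfg, parameters = rr)
  expect_gte(t_rr$icer_high, t_rr$icer_low)
  expect_gt(t_rr$delta_cost_high, t_rr$delta_cost_low)
  expect_lt(t_rr$delta_qaly_high, t_rr$delta_qaly_low)

  # utility ranges enter verbatim from the utilities table
  u45 <- reg[reg$name == "utility_45-54", ]
  expect_equal(c(u45$mean, u45$lower, u45$upper), c(0.87, 0.81, 0.93))

  # full registry runs and is sorted by induced cost range
  tor <- one_way_dsa(p, cfg)
  expect_s3_class(tor, "cea_tornado")
  expect_true(all(diff(tor$range_width) <= 0))
})

test_that("degenerate-distribution PSA collapses to the deterministic run", {
  p <- ref_params
  cfg <- base_config
  dists <- psa_distributions(p, cfg, cost_se_frac = 0)
  dists$lower <- dists$mean
  dists$upper <- dists$mean
  dists$dist <- purrr::pmap(
    dists[, c("family", "mean", "lower", "upper")],
    function(family, mean, lower, upper) {
      if (family == "gamma") fit_distribution("gamma", mean, se_frac = 0)
      else fit_distribution(family, mean, lower, upper)
    }
  )
  psa <- run_psa(p, cfg, n_iterations = 10, seed = 1, distributions = dists)
  det <- run_comparison(p, cfg)
  expect_equal(unique(psa$iterations$delta_cost), det$incremental$delta_cost)
  expect_equal(unique(psa$iterations$delta_qaly), det$incremental$delta_qaly)
  expect_equal(unique(psa$iterations$roi), det$roi)
})

test_that("PSA is seed-reproducible and internally consistent", {
  p <- ref_params
  cfg <- base_config
  psa1 <- run_psa(p, cfg, n_iterations = 200, seed = 42)
  psa2 <- run_psa(p, cfg, n_iterations = 200, seed = 42)
  expect_identical(psa1$iterations, psa2$iterations)
  expect_identical(psa1$ci, psa2$ci)
  psa3 <- run_psa(p, cfg, n_iterations = 200, seed = 43)
  expect_false(identical(psa1$iterations$delta_cost,
                         psa3$iterations$delta_cost))

  expect_equal(sum(psa1$quadrants$fraction), 1)
  ci <- psa1$ci
  expect_true(all(ci$lower <= ci$mean & ci$mean <= ci$upper))

  # Monte-Carlo consistency: PSA mean delta-QALY near the deterministic value
  det <- run_comparison(p, cfg)
  se <- sd(psa1$iterations$delta_qaly) / sqrt(nrow(psa1$iterations))
  expect_lt(abs(mean(psa1$iterations$delta_qaly) - det$incremental$delta_qaly),
            3 * se + 0.05 * abs(det$incremental$delta_qaly))
})

test_that("intervention cost threshold matches the linear closed form", {
  p <- ref_params
  cfg <- base_config
  # oracle: delta_cost is linear in the unit cost c with slope = total
  # included births, so the threshold solves N*c + K = wtp * delta_qaly
  cm <- gdmcea:::compile_model(p, cfg)
  th <- gdmcea:::base_theta(p, cfg)
  r0 <- gdmcea:::run_compiled(cm, gdmcea:::apply_theta_override(th, "c_intervention", NA, 0))
  r1 <- gdmcea:::run_compiled(cm, gdmcea:::apply_theta_override(th, "c_intervention", NA, 1000))
  slope <- (r1$delta_cost - r0$delta_cost) / 1000
  expected <- (cfg$wtp_threshold * r0$delta_qaly - r0$delta_cost) / slope
  got <- intervention_cost_threshold(p, cfg)
  expect_lt(abs(as.numeric(got) - expected), 1)
  expect_true(attr(got, "converged"))
  expect_gt(as.numeric(got), 228)

  # monotone in the willingness-to-pay threshold
  lo <- intervention_cost_threshold(p, cfg, wtp = 20000)
  hi <- intervention_cost_threshold(p, cfg, wtp = 80000)
  expect_gt(as.numeric(hi), as.numeric(lo))

  # infinite threshold: the upper bracket bound is returned, unconverged
  inf <- intervention_cost_threshold(p, cfg, wtp = Inf)
  expect_equal(as.numeric(inf), 20000)
  expect_false(attr(inf, "converged"))
})

test_that("scenario-2 sweep is monotone with a base-case left end", {
  p <- ref_params
  cfg <- base_config
  sw <- scenario2_sweep(p, cfg, rr_grid = seq(1, 9.5, by = 0.5))
  base <- run_comparison(p, cfg)
  expect_equal(sw$curve$delta_cost[1], base$incremental$delta_cost,
               tolerance = 1e-10)
  expect_equal(sw$curve$roi[1], base$roi, tolerance = 1e-10)
  # ROI non-increasing, net cost (hence ICER pressure) non-decreasing in rr
  expect_true(all(diff(sw$curve$roi) <= 1e-10))
  expect_true(all(diff(sw$curve$delta_cost) >= -1e-6))
  expect_true(all(diff(sw$curve$delta_cases_t2dm) >= -1e-9))

  # rr equal to the GDM progression RR removes all long-term benefit:
  # zero incremental lifetime T2DM cases, only perinatal effects remain
  cfg_eq <- model_config(scenario = "s2_rr_sweep", rr_avoided = 9.51)
  res_eq <- run_comparison(p, cfg_eq)
  expect_equal(res_eq$incremental$delta_cases_t2dm, 0, tolerance = 1e-6)
  arms <- tidy(res_eq)
  expect_equal(arms$incremental[arms$key == "c_t2dm"], 0, tolerance = 1e-4)
  expect_lt(arms$incremental[arms$key == "c_pregnancy"], 0)

  expect_error(scenario2_sweep(p, cfg, rr_grid = c(0.5, 2)), "within")
})
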