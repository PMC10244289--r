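test_that("intervention unit cost derives from staffing assumptions", {
  expect_equal(round(intervention_unit_cost()), 228)
  expect_equal(intervention_unit_cost(), 82600 * 1.15 * 1.20 / 500)
  # halving the caseload doubles the unit cost
  expect_equal(intervention_unit_cost(caseload = 250),
               2 * intervention_unit_cost())
})

test_that("perinatal costs weight branch events correctly", {
  costs <- ref_params$costs
  # toy: only the antenatal GDM cost is non-zero
  toy <- costs
  toy$value <- 0
  toy$value[toy$item == "antenatal_gdm"] <- 1000
  coh <- tibble::tibble(band_label = "x", n_births = 100,
                        gdm_prevalence = 0.1, preexisting_dm_prevalence = 0)
  w <- pregnancy_branching(coh, "usual_care")
  pc <- perinatal_costs(w, coh, toy, include_nicu = FALSE)
  expect_equal(pc$pregnancy, 100 * 0.1 * 1000)
  expect_equal(pc$nicu_scn, 0)

  # zero GDM prevalence: identical pregnancy costs in both arms
  coh0 <- coh
  coh0$gdm_prevalence <- 0
  w_uc <- pregnancy_branching(coh0, "usual_care")
  w_iv <- pregnancy_branching(coh0, "intervention", 0.67)
  expect_equal(perinatal_costs(w_uc, coh0, costs)$pregnancy,
               perinatal_costs(w_iv, coh0, costs)$pregnancy)

  # NICU costs appear only when enabled
  pc_on <- perinatal_costs(w, coh, costs, include_nicu = TRUE)
  expect_gt(pc_on$nicu_scn, 0)
})

test_that("chronic costs discount occupancy correctly across scenarios", {
  # one full case-year at cycle 1, annual cost 1000, r = 5%, half-cycle off
  trace <- tibble::tibble(cycle = 1, no_t2dm = 0, t2dm = 1, dead = 0,
                          new_t2dm_cases = 1, life_years = 1, t2dm_years = 1,
                          discount = 1 / 1.05)
  costs <- ref_params$costs
  costs$value[costs$item == "t2dm_annual_cost"] <- 1000
  cfg <- model_config(discount_rate = 0.05, half_cycle_correction = FALSE)
  cc <- chronic_costs(trace, costs, 32, cfg)
  expect_equal(cc$t2dm_management, 1000 / 1.05, tolerance = 1e-12)
  expect_equal(cc$societal_addons, 0)

  # empty occupancy costs nothing
  trace0 <- trace
  trace0$t2dm <- 0
  trace0$t2dm_years <- 0
  trace0$new_t2dm_cases <- 0
  expect_equal(chronic_costs(trace0, costs, 32, cfg)$t2dm_management, 0)

  # micro-costing with first-year == subsequent-year equals flat costing on
  # end-of-cycle occupancy
  sch <- build_transition_schedule("gdm", ref_params, base_config, 32)
  cfg_flat <- model_config(scenario = "s3_microcost_health",
                           half_cycle_correction = FALSE)
  tr <- run_markov_trace(sch, cfg_flat)
  costs2 <- ref_params$costs
  costs2$value[costs2$item %in% c("microcost_first_year",
                                  "microcost_subsequent_year")] <- 4000
  cc3 <- chronic_costs(tr, costs2, 32, cfg_flat)
  flat <- sum(tr$t2dm * 4000 * (1 + 0.05)^-(tr$cycle))
  expect_equal(cc3$t2dm_management, flat, tolerance = 1e-12)

  # societal add-ons only in scenario 4
  cfg4 <- model_config(scenario = "s4_microcost_societal")
  tr4 <- run_markov_trace(sch, cfg4)
  cc4 <- chronic_costs(tr4, ref_params$costs, 32, cfg4)
  expect_gt(cc4$societal_addons, 0)
})

test_that("QALY weighting follows the utility adjustment modes", {
  sch <- build_transition_schedule("never_gdm", ref_params, base_config, 32)
  tr <- run_markov_trace(sch, base_config)
  # all utilities 1: QALYs equal discounted life-years
  p1 <- unit_utilities(ref_params)
  q1 <- discounted_qalys(tr, p1$utilities, 32, base_config)
  expect_equal(q1, sum(tr$life_years * tr$discount), tolerance = 1e-12)

  # multiplicative mode: T2DM utility at age 30 is 0.95 * (0.785/0.95) = 0.785
  u_h <- gdmcea:::utility_by_age(ref_params$utilities, 30)
  u_t2 <- gdmcea:::t2dm_utility_by_age(u_h, 0.785, ref_params$utilities,
                                       "multiplicative")
  expect_equal(u_t2, 0.785, tolerance = 1e-12)
  # and never exceeds the healthy utility at any age
  ages <- 15:85
  uh <- gdmcea:::utility_by_age(ref_params$utilities, ages)
  for (mode in c("multiplicative", "absolute-decrement")) {
    ut2 <- gdmcea:::t2dm_utility_by_age(uh, 0.785, ref_params$utilities, mode)
    expect_true(all(ut2 <= uh), info = mode)
    expect_true(all(ut2 >= 0), info = mode)
  }

  # zero T2DM utility: QALYs reduce to healthy-years contribution
  p0 <- ref_params
  p0$utilities$mean[p0$utilities$band == "t2dm"] <- 0
  q0 <- discounted_qalys(tr, p0$utilities, 32, base_config)
  u_ages <- gdmcea:::utility_by_age(p0$utilities, 32 + tr$cycle)
  expect_equal(q0, sum((tr$life_years - tr$t2dm_years) * u_ages * tr$discount),
               tolerance = 1e-12)
})

test_that("ICER handles dominance quadrants and ROI reproduces published arithmetic", {
  expect_equal(compute_icer(100, 0.02)$icer, 5000)
  expect_equal(compute_icer(-50, 0.035)$label, "Dominant")
  expect_equal(compute_icer(100, -0.01)$label, "Dominated")
  expect_equal(compute_icer(100, 0)$label, "no QALY difference")
  expect_equal(compute_icer(-100, -0.01)$icer, 10000)

  # published base-case increments: ROI excluding and including NICU/SCN
  expect_equal(round(compute_roi(69904575, -25187141, -60108916), 2), 1.22)
  expect_equal(round(compute_roi(69904575, -25187141, -60108916,
                                 nicu_increment = -24264341,
                                 include_nicu = TRUE), 2), 1.57)
  expect_equal(round(compute_roi(69934187, -19081168, -45537057), 2), 0.92)
  expect_equal(compute_roi(1000, 0, 0), 0)
  expect_error(compute_roi(0, -10, -10), "zero")
  # ROI strictly decreasing in intervention cost
  rois <- vapply(c(5e7, 7e7, 9e7), compute_roi, numeric(1),
                 pregnancy_increment = -25187141, t2dm_increment = -60108916)
  expect_true(all(diff(rois) < 0))
})

test_that("efficiency frontier flags strict and extended dominance", {
  two <- tibble::tibble(strategy = c("a", "b"),
                        delta_cost = c(100, 50), delta_qaly = c(1, 2))
  f2 <- efficiency_frontier(two)
  expect_equal(f2$status[f2$strategy == "a"], "dominated")

  # collinear strategies all stay on the frontier
  col3 <- tibble::tibble(strategy = c("o", "m", "t"),
                         delta_cost = c(0, 50, 100), delta_qaly = c(0, 1, 2))
  f3 <- efficiency_frontier(col3)
  expect_equal(f3$status, rep("frontier", 3))

  # textbook triple: middle strategy extendedly dominated iff its incremental
  # ICER exceeds the next segment's
  tri <- tibble::tibble(strategy = c("o", "m", "t"),
                        delta_cost = c(0, 100, 150), delta_qaly = c(0, 1, 1.1))
  f <- efficiency_frontier(tri)
  # ICER o->m = 100; m->t = 50/0.1 = 500 > 100, so m stays on the frontier
  expect_equal(f$status[f$strategy == "m"], "frontier")
  tri2 <- tibble::tibble(strategy = c("o", "m", "t"),
                         delta_cost = c(0, 100, 150),
                         delta_qaly = c(0, 0.1, 1.1))
  f2b <- efficiency_frontier(tri2)
  # ICER o->m = 1000 > m->t = 50, so m is extendedly dominated
  expect_equal(f2b$status[f2b$strategy == "m"], "extendedly dominated")
})
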