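test_that("decision-tree branch weights follow the intervention RR", {
  coh <- tibble::tibble(gdm_prevalence = 0.15)
  w <- pregnancy_branching(coh, "intervention", 0.67)
  expect_equal(w$weight, c(0.1005, 0.0495, 0.85), tolerance = 1e-12)
  expect_equal(sum(w$weight), 1)

  w_uc <- pregnancy_branching(coh, "usual_care", 0.67)
  expect_equal(w_uc$weight, c(0.15, 0, 0.85))

  w_null <- pregnancy_branching(coh, "intervention", 1)
  expect_equal(w_null$weight[w_null$branch == "avoided_gdm"], 0)
  expect_equal(w_null$weight[w_null$branch == "gdm"],
               w_uc$weight[w_uc$branch == "gdm"])

  w0 <- pregnancy_branching(tibble::tibble(gdm_prevalence = 0), "intervention",
                            0.67)
  expect_equal(w0$weight, c(0, 0, 1))
  expect_error(pregnancy_branching(coh, "intervention", 1.7))
})

test_that("transition schedules encode branch risks and scenarios", {
  p <- ref_params
  cfg <- base_config
  s_gdm <- build_transition_schedule("gdm", p, cfg, 32)
  s_nog <- build_transition_schedule("never_gdm", p, cfg, 32)
  # base case: GDM vs never-GDM incidence rate ratio is the original RR 9.51
  r_gdm <- -log(1 - s_gdm$p_to_t2dm)
  r_nog <- -log(1 - s_nog$p_to_t2dm)
  expect_equal(r_gdm / r_nog, rep(9.51, length(r_gdm)), tolerance = 1e-10)
  expect_equal(s_gdm$p_death_no_t2dm, s_nog$p_death_no_t2dm)
  expect_equal(nrow(s_gdm), 85 - 32)
  expect_equal(s_gdm$age, 33:85)

  # avoided branch with rr_avoided = 1 is identical to never-GDM
  s_av <- build_transition_schedule("avoided_gdm", p, cfg, 32)
  expect_equal(s_av$p_to_t2dm, s_nog$p_to_t2dm)

  # scenario 1: GDM branch reverts to total-population incidence from cycle 11
  cfg1 <- model_config(scenario = "s1_10yr")
  s1 <- build_transition_schedule("gdm", p, cfg1, 32)
  i_total <- p$epi$t2dm_incidence_total[match(s1$age, p$epi$age)]
  expect_equal(-log(1 - s1$p_to_t2dm[12]), i_total[12], tolerance = 1e-12)
  expect_equal(s1$p_to_t2dm[1:10], s_gdm$p_to_t2dm[1:10])
})

test_that("Markov recursion matches hand computation and conserves occupancy", {
  sched <- tibble::tibble(p_to_t2dm = 0.1, p_death_no_t2dm = 0,
                          p_death_t2dm = 0)
  tr <- run_markov_trace(sched, model_config())
  expect_equal(c(tr$no_t2dm, tr$t2dm, tr$dead), c(0.9, 0.1, 0))
  expect_equal(tr$new_t2dm_cases, 0.1)

  # no transitions: occupancy constant, undiscounted life years = horizon
  sched0 <- tibble::tibble(p_to_t2dm = rep(0, 30), p_death_no_t2dm = 0,
                           p_death_t2dm = 0)
  tr0 <- run_markov_trace(sched0, model_config())
  expect_equal(sum(tr0$life_years), 30)
  expect_equal(tr0$no_t2dm, rep(1, 30))

  # conservation and absorbing death on random schedules
  withr::with_seed(21, {
    for (k in 1:50) {
      n <- sample(5:60, 1)
      sch <- tibble::tibble(
        p_to_t2dm = runif(n, 0, 0.5),
        p_death_no_t2dm = runif(n, 0, 0.5),
        p_death_t2dm = runif(n, 0, 0.6)
      )
      tr <- run_markov_trace(sch, model_config())
      expect_true(all(abs(tr$no_t2dm + tr$t2dm + tr$dead - 1) < 1e-12))
      expect_true(all(diff(c(0, tr$dead)) >= -1e-15))
      expect_true(all(tr$new_t2dm_cases >= 0))
    }
  })
  expect_error(run_markov_trace(tibble::tibble(p_to_t2dm = 1.2,
                                               p_death_no_t2dm = 0,
                                               p_death_t2dm = 0)))
})

test_that("cohort trace agrees with the individual-level microsimulation oracle", {
  p <- ref_params
  sch <- build_transition_schedule("gdm", p, base_config, 32)
  core <- run_markov_trace(sch, base_config)
  n <- 1e5
  ms <- microsim_trace(sch$p_to_t2dm, sch$p_death_no_t2dm, sch$p_death_t2dm,
                       n_women = n, seed = 99)
  expect_lt(abs(sum(core$new_t2dm_cases) - ms$cases), 3 * ms$cases_se)
  expect_lt(abs(sum(core$life_years) - ms$ly), 3 * ms$ly_se)
  expect_lt(abs(sum(core$t2dm_years) - ms$t2y), 3 * ms$t2y_se)
  # discounted QALYs from per-woman state-years vs deterministic trace
  u_h <- utility_by_age_oracle(p$utilities, 32 + core$cycle)
  u_t2 <- u_h * 0.785 / 0.95
  disc <- 1.05^-(core$cycle)
  det_qaly <- sum(((core$life_years - core$t2dm_years) * u_h +
                     core$t2dm_years * u_t2) * disc)
  expect_equal(det_qaly, discounted_qalys(core, p$utilities, 32, base_config),
               tolerance = 1e-10)
})

test_that("lifetime outcomes discount and scale correctly", {
  # two healthy cycles at utility 1, r = 5%, half-cycle off: geometric sum
  cfg <- model_config(discount_rate = 0.05, half_cycle_correction = FALSE)
  sched <- tibble::tibble(p_to_t2dm = c(0, 0), p_death_no_t2dm = 0,
                          p_death_t2dm = 0)
  tr <- run_markov_trace(sched, cfg)
  coh <- tibble::tibble(band_label = "30-34", representative_age = 32,
                        n_births = 1, gdm_prevalence = 0,
                        preexisting_dm_prevalence = 0)
  w <- pregnancy_branching(coh, "usual_care")
  p1 <- unit_utilities(ref_params)
  out <- lifetime_outcomes(list(gdm = tr, never_gdm = tr), w, coh, p1, cfg)
  expect_equal(out$years_of_life_disc, 1 / 1.05 + 1 / 1.05^2,
               tolerance = 1e-12)
  expect_equal(out$qalys_disc, out$years_of_life_disc, tolerance = 1e-12)

  # discounting never increases totals
  expect_lt(out$years_of_life_disc, out$years_of_life)
  cfg0 <- model_config(discount_rate = 0, half_cycle_correction = FALSE)
  tr0 <- run_markov_trace(sched, cfg0)
  out0 <- lifetime_outcomes(list(gdm = tr0, never_gdm = tr0), w, coh, p1, cfg0)
  expect_equal(out0$years_of_life_disc, out0$years_of_life)

  # doubling births doubles every population-level outcome
  coh2 <- coh
  coh2$n_births <- 2
  out2 <- lifetime_outcomes(list(gdm = tr, never_gdm = tr), w, coh2, p1, cfg)
  for (f in names(out)) expect_equal(out2[[f]], 2 * out[[f]], info = f)
})

test_that("null intervention produces exactly zero increments", {
  p <- ref_params
  p$relative_risks$mean[p$relative_risks$parameter == "rr_gdm_base"] <- 1
  p$relative_risks$lower[p$relative_risks$parameter == "rr_gdm_base"] <- 1
  p$relative_risks$upper[p$relative_risks$parameter == "rr_gdm_base"] <- 1
  p0 <- p
  p0$costs$value[p0$costs$item == "intervention_base"] <- 0
  res0 <- run_comparison(p0, base_config)
  expect_equal(res0$incremental$delta_cost, 0)
  expect_equal(res0$incremental$delta_qaly, 0)
  expect_equal(res0$incremental$delta_cases_t2dm, 0)
  expect_equal(res0$icer_label, "no QALY difference")

  # cost 228 with no effect: increment is exactly 228 per included birth
  res228 <- run_comparison(p, base_config)
  expect_equal(res228$incremental$delta_qaly, 0)
  expect_equal(res228$incremental$delta_cost, 228 * res228$total_births,
               tolerance = 1e-12)
})

test_that("intervention reduces T2DM cases and QALY gains are positive", {
  res <- run_comparison(ref_params, base_config)
  expect_lt(res$incremental$delta_cases_t2dm, 0)
  expect_lt(res$incremental$delta_cases_gdm, 0)
  expect_gt(res$incremental$delta_qaly, 0)
  arms <- tidy(res)
  expect_lt(arms$intervention[arms$key == "cases_t2dm"],
            arms$usual_care[arms$key == "cases_t2dm"])
})
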