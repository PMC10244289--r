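# Internal compiled representation of the model. All engines (deterministic
# run, DSA, PSA, threshold searches) funnel through `compile_model()` +
# `run_compiled()`: plain numeric vectors, no data-frame overhead, so a full
# two-arm lifetime comparison costs ~1 ms and 10,000 PSA iterations stay
# within minutes on one CPU.

# epi-level quantities shared by all cohorts
compile_epi <- function(params, config) {
  ep <- dplyr::arrange(params$epi, .data$age)
  prev_cnt <- ep$population * ep$t2dm_prevalence
  m_no <- derive_no_t2dm_mortality(
    ep$age,
    ep$all_cause_mortality * ep$population, ep$population,
    ep$t2dm_mortality * prev_cnt, prev_cnt
  )
  m_t2 <- ifelse(ep$age >= 40, ep$t2dm_mortality, m_no)
  list(
    age = ep$age,
    i_total = ep$t2dm_incidence_total,
    m_no = m_no,
    m_t2 = m_t2,
    p_gdm_pop = rr_value(params, "gdm_prevalence_population"),
    scenario = config$scenario,
    max_age = config$max_age,
    dt = config$cycle_length
  )
}

# cycle-indexed schedule (rates already converted to probabilities) for one
# branch of one cohort; scenario s1 reverts the GDM branch to the
# total-population incidence after 10 post-birth cycles
branch_schedule <- function(cm, representative_age, branch, rr_t2dm,
                            rr_avoided = 1) {
  idx <- which(cm$age > representative_age & cm$age <= cm$max_age)
  i_total <- cm$i_total[idx]
  split <- split_rates(i_total, cm$p_gdm_pop, rr_t2dm)
  i <- switch(branch,
    gdm = split$i_gdm,
    never_gdm = split$i_no_gdm,
    avoided_gdm = rr_avoided * split$i_no_gdm
  )
  if (branch == "gdm" && cm$scenario == "s1_10yr") {
    late <- seq_along(i) > 10
    i[late] <- i_total[late]
  }
  list(
    age = cm$age[idx],
    p_inc = 1 - exp(-i * cm$dt),
    p_die_no = 1 - exp(-cm$m_no[idx] * cm$dt),
    p_die_t2 = 1 - exp(-cm$m_t2[idx] * cm$dt)
  )
}

# bare-vector version of split_t2dm_incidence
split_rates <- function(i_total, p, rr) {
  rr_adj <- rr / (p * rr + (1 - p))
  i_gdm <- rr_adj * i_total
  list(i_gdm = i_gdm, i_no_gdm = i_gdm / rr)
}

# Vectorised three-state recursion. Competing risks within a cycle: death
# first, incidence on survivors. The T2DM occupancy recurrence
#   occ_t2(t) = occ_t2(t-1) (1 - p_die_t2(t)) + new(t)
# is solved in closed form through the survival product S2.
markov_core <- function(p_inc, p_die_no, p_die_t2, hcc = TRUE) {
  occ_no <- cumprod((1 - p_die_no) * (1 - p_inc))
  prev_no <- c(1, occ_no[-length(occ_no)])
  new_cases <- prev_no * (1 - p_die_no) * p_inc
  S2 <- cumprod(1 - p_die_t2)
  occ_t2 <- S2 * cumsum(new_cases / S2)
  prev_t2 <- c(0, occ_t2[-length(occ_t2)])
  ly_no <- if (hcc) (prev_no + occ_no) / 2 else occ_no
  ly_t2 <- if (hcc) (prev_t2 + occ_t2) / 2 else occ_t2
  list(
    occ_no = occ_no, occ_t2 = occ_t2, occ_dead = 1 - occ_no - occ_t2,
    new_cases = new_cases, ly_no = ly_no, ly_t2 = ly_t2
  )
}

UTILITY_BAND_ORDER <- c("18-24", "25-34", "35-44", "45-54", "55-64", "65-74",
                        "75+")

# T2DM-state utility by age. Multiplicative mode rescales the healthy curve
# by u_t2 / u_ref (u_ref = best healthy band utility, so a 0.785 state
# utility reproduces 0.785 at the reference band); absolute-decrement mode
# subtracts (u_ref - u_t2). Both are capped so the diseased state never
# exceeds the healthy state at any age.
t2dm_utility_by_age <- function(u_healthy, u_t2, utilities, mode) {
  u_ref <- max(utilities$mean[utilities$band != "t2dm"])
  out <- if (mode == "multiplicative") {
    u_healthy * (u_t2 / u_ref)
  } else {
    pmax(u_healthy - (u_ref - u_t2), 0)
  }
  pmin(out, u_healthy)
}

t2dm_utility_vec <- function(u_healthy, u_t2, u_ref, mode) {
  out <- if (mode == "multiplicative") {
    u_healthy * (u_t2 / u_ref)
  } else {
    pmax(u_healthy - (u_ref - u_t2), 0)
  }
  pmin(out, u_healthy)
}

# Full model compilation: everything that does not depend on sampled
# parameters is resolved to plain vectors here.
compile_model <- function(params, config) {
  cm <- compile_epi(params, config)
  ut <- params$utilities[params$utilities$band != "t2dm", ]
  band_order <- ut$band[order(ut$age_low)]
  cohorts <- dplyr::arrange(params$cohorts, .data$age_low)
  coh <- lapply(seq_len(nrow(cohorts)), function(k) {
    rep_age <- cohorts$representative_age[k]
    idx <- which(cm$age > rep_age & cm$age <= cm$max_age)
    ages <- cm$age[idx]
    # utility band index per cycle age (out-of-range ages clamp to ends)
    u_idx <- findInterval(ages, sort(ut$age_low))
    u_idx[u_idx < 1] <- 1
    list(
      births = cohorts$n_births[k] * (1 - cohorts$preexisting_dm_prevalence[k]),
      q = cohorts$gdm_prevalence[k],
      rep_age = rep_age,
      ages = ages,
      i_total = cm$i_total[idx],
      p_die_no = 1 - exp(-cm$m_no[idx] * cm$dt),
      p_die_t2 = 1 - exp(-cm$m_t2[idx] * cm$dt),
      disc = (1 + config$discount_rate)^-(seq_along(idx)),
      u_idx = u_idx,
      t2dm_cost_age = t2dm_cost_by_age(params$costs, ages)
    )
  })
  list(
    coh = coh,
    p_gdm_pop = cm$p_gdm_pop,
    dt = cm$dt,
    band_order = band_order,
    config = config,
    total_births = sum(vapply(coh, function(x) x$births, numeric(1)))
  )
}

# Base-case theta: every sampled quantity at its mean value.
base_theta <- function(params, config) {
  ut <- params$utilities[params$utilities$band != "t2dm", ]
  ut <- ut[order(ut$age_low), ]
  list(
    rr_t2dm = rr_value(params, "rr_t2dm_after_gdm"),
    rr_gdm = rr_value(params, subgroup_rr_name(config$subgroup)),
    rr_avoided = config$rr_avoided,
    u_bands = ut$mean,
    u_t2 = params$utilities$mean[params$utilities$band == "t2dm"],
    c_intervention = cost_value(params, subgroup_cost_item(config$subgroup)),
    c_antenatal = cost_value(params, "antenatal_gdm"),
    c_caesarean = cost_value(params, "caesarean_cost"),
    c_induction = cost_value(params, "induction_cost"),
    c_nicu = cost_value(params, "nicu_cost"),
    p_caes_gdm = cost_value(params, "p_caesarean_gdm"),
    p_caes_no = cost_value(params, "p_caesarean_no_gdm"),
    p_ind_gdm = cost_value(params, "p_induction_gdm"),
    p_ind_no = cost_value(params, "p_induction_no_gdm"),
    p_nicu_gdm = cost_value(params, "p_nicu_gdm"),
    p_nicu_no = cost_value(params, "p_nicu_no_gdm"),
    t2dm_cost_scale = 1,
    c_micro_first = cost_value(params, "microcost_first_year"),
    c_micro_subseq = cost_value(params, "microcost_subsequent_year"),
    c_nonhealth = cost_value(params, "microcost_direct_nonhealth"),
    c_subsidy = cost_value(params, "microcost_income_subsidy")
  )
}

# One branch's lifetime summary (per woman entering that branch).
branch_summary <- function(ck, p_inc, theta, config) {
  tr <- markov_core(p_inc, ck$p_die_no, ck$p_die_t2,
                    hcc = config$half_cycle_correction)
  u_ref <- max(theta$u_bands)
  u_h <- theta$u_bands[ck$u_idx]
  u_t2 <- t2dm_utility_vec(u_h, theta$u_t2, u_ref,
                           config$utility_adjustment_mode)
  q <- tr$ly_no * u_h + tr$ly_t2 * u_t2
  scen <- config$scenario
  chronic <- if (scen %in% c("s3_microcost_health", "s4_microcost_societal")) {
    carry <- tr$occ_t2 - tr$new_cases
    sum((tr$new_cases * theta$c_micro_first + carry * theta$c_micro_subseq) *
          ck$disc)
  } else {
    sum(tr$ly_t2 * ck$t2dm_cost_age * theta$t2dm_cost_scale * ck$disc)
  }
  societal <- if (scen == "s4_microcost_societal") {
    sum(tr$ly_t2 * (theta$c_nonhealth + theta$c_subsidy) * ck$disc)
  } else {
    0
  }
  c(
    cases = sum(tr$new_cases),
    ly = sum(tr$ly_no + tr$ly_t2),
    ly_disc = sum((tr$ly_no + tr$ly_t2) * ck$disc),
    t2y = sum(tr$ly_t2),
    t2y_disc = sum(tr$ly_t2 * ck$disc),
    qaly = sum(q),
    qaly_disc = sum(q * ck$disc),
    chronic_disc = chronic,
    societal_disc = societal
  )
}

# Run both arms over every cohort. `theta` carries every sampled/varied
# parameter; everything else lives in the compiled model `cm`.
run_compiled <- function(cm, theta) {
  config <- cm$config
  arms <- list()
  for (arm in c("usual_care", "intervention")) {
    tot <- c(cases_gdm = 0, cases_t2dm = 0, ly = 0, ly_disc = 0, t2y = 0,
             t2y_disc = 0, qaly = 0, qaly_disc = 0, nicu = 0,
             c_intervention = 0, c_pregnancy = 0, c_nicu = 0, c_t2dm = 0,
             c_societal = 0)
    for (ck in cm$coh) {
      q <- ck$q
      rr <- theta$rr_gdm
      w <- if (arm == "usual_care") {
        c(gdm = q, avoided_gdm = 0, never_gdm = 1 - q)
      } else {
        c(gdm = q * rr, avoided_gdm = q * (1 - rr), never_gdm = 1 - q)
      }
      sp <- split_rates(ck$i_total, cm$p_gdm_pop, theta$rr_t2dm)
      i_gdm <- sp$i_gdm
      if (config$scenario == "s1_10yr") {
        late <- seq_along(i_gdm) > 10
        i_gdm[late] <- ck$i_total[late]
      }
      summaries <- list(
        gdm = branch_summary(ck, 1 - exp(-i_gdm * cm$dt), theta, config),
        never_gdm = branch_summary(ck, 1 - exp(-sp$i_no_gdm * cm$dt), theta,
                                   config)
      )
      # the avoided branch equals the never-GDM branch when rr_avoided = 1
      # (base-case assumption); weight may be negative for sampled GDM RRs
      # above 1 (intervention harmful in that draw), where the identity keeps
      # the mixture arithmetic exact
      summaries$avoided_gdm <- if (w[["avoided_gdm"]] == 0 ||
                                   theta$rr_avoided == 1) {
        summaries$never_gdm
      } else {
        branch_summary(ck, 1 - exp(-theta$rr_avoided * sp$i_no_gdm * cm$dt),
                       theta, config)
      }
      mix <- w[["gdm"]] * summaries$gdm +
        w[["avoided_gdm"]] * summaries$avoided_gdm +
        w[["never_gdm"]] * summaries$never_gdm

      births <- ck$births
      w_gdm <- w[["gdm"]]
      # perinatal event expectations (cycle 0, undiscounted); the avoided and
      # never-GDM branches share non-GDM perinatal probabilities
      preg <- w_gdm * (theta$c_antenatal +
                         theta$p_caes_gdm * theta$c_caesarean +
                         theta$p_ind_gdm * theta$c_induction) +
        (1 - w_gdm) * (theta$p_caes_no * theta$c_caesarean +
                         theta$p_ind_no * theta$c_induction)
      nicu_adm <- w_gdm * theta$p_nicu_gdm + (1 - w_gdm) * theta$p_nicu_no

      tot <- tot + c(
        cases_gdm = births * w_gdm,
        cases_t2dm = births * mix[["cases"]],
        ly = births * mix[["ly"]],
        ly_disc = births * mix[["ly_disc"]],
        t2y = births * mix[["t2y"]],
        t2y_disc = births * mix[["t2y_disc"]],
        qaly = births * mix[["qaly"]],
        qaly_disc = births * mix[["qaly_disc"]],
        nicu = births * nicu_adm,
        c_intervention = if (arm == "intervention") births * theta$c_intervention else 0,
        c_pregnancy = births * preg,
        c_nicu = births * nicu_adm * theta$c_nicu,
        c_t2dm = births * mix[["chronic_disc"]],
        c_societal = births * mix[["societal_disc"]]
      )
    }
    arms[[arm]] <- tot
  }
  uc <- arms$usual_care
  iv <- arms$intervention
  inc <- iv - uc
  hc_total <- function(x) {
    x[["c_intervention"]] + x[["c_pregnancy"]] + x[["c_t2dm"]] +
      if (config$include_nicu_scn) x[["c_nicu"]] else 0
  }
  persp_total <- function(x) {
    hc_total(x) + if (config$scenario == "s4_microcost_societal") x[["c_societal"]] else 0
  }
  list(
    usual_care = uc, intervention = iv, incremental = inc,
    total_births = cm$total_births,
    delta_cost = persp_total(iv) - persp_total(uc),
    delta_cost_healthcare = hc_total(iv) - hc_total(uc),
    delta_qaly = inc[["qaly_disc"]]
  )
}
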