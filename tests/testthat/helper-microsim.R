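# Independent individual-level microsimulation oracle for the cohort Markov
# engine: simulates each woman's path through {no T2DM, T2DM, dead} with the
# same per-cycle transition probabilities (death first, incidence on
# survivors) and accumulates per-woman totals, so Monte Carlo standard
# errors are available for the comparison with the deterministic trace.
microsim_trace <- function(p_inc, p_die_no, p_die_t2, n_women, seed,
                           hcc = TRUE) {
  withr::with_seed(seed, {
    n_cycles <- length(p_inc)
    state <- integer(n_women) # 0 = no T2DM, 1 = T2DM, 2 = dead
    ly_no <- ly_t2 <- numeric(n_women)
    case <- logical(n_women)
    for (t in seq_len(n_cycles)) {
      prev <- state
      healthy <- which(prev == 0L)
      if (length(healthy) > 0) {
        dies <- runif(length(healthy)) < p_die_no[t]
        state[healthy[dies]] <- 2L
        surv <- healthy[!dies]
        inc <- runif(length(surv)) < p_inc[t]
        state[surv[inc]] <- 1L
        case[surv[inc]] <- TRUE
      }
      sick <- which(prev == 1L)
      if (length(sick) > 0) {
        dies <- runif(length(sick)) < p_die_t2[t]
        state[sick[dies]] <- 2L
      }
      if (hcc) {
        ly_no <- ly_no + ((prev == 0L) + (state == 0L)) / 2
        ly_t2 <- ly_t2 + ((prev == 1L) + (state == 1L)) / 2
      } else {
        ly_no <- ly_no + (state == 0L)
        ly_t2 <- ly_t2 + (state == 1L)
      }
    }
    ly <- ly_no + ly_t2
    list(
      cases = mean(case), cases_se = sd(case) / sqrt(n_women),
      ly = mean(ly), ly_se = sd(ly) / sqrt(n_women),
      t2y = mean(ly_t2), t2y_se = sd(ly_t2) / sqrt(n_women),
      ly_no_i = ly_no, ly_t2_i = ly_t2
    )
  })
}
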