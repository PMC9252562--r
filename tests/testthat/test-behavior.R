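dp <- disease_params()
bp <- behavior_params()

test_that("utility is zero at the boundaries, peaks at b/2, errors outside", {
  expect_equal(utility(0, 48, 0.1), 0)
  expect_equal(utility(48, 48, 0.1), 0)
  expect_equal(utility(24, 48, 0.1), 1.8881750225898, tolerance = 1e-12)
  # argmax at b/2 for several shapes
  grid <- seq(0, 48, by = 0.05)
  for (nu in c(0.05, 0.1, 0.5, 1)) {
    expect_equal(grid[which.max(utility(grid, 48, nu))], 24)
  }
  expect_error(utility(49, 48, 0.1), "outside")
  expect_error(utility(-1, 48, 0.1), "outside")
})

test_that("perceived infection probability follows the frozen environment", {
  st <- epidemic_state(S1 = 0.9, I = 0.1)
  env1 <- perceived_environment(st, flat_contacts(24), 1, dp)
  # direct arithmetic: 1 - exp(-beta * C * mix), mix = 0.1
  expect_equal(perceived_infection_probability(24, env1, dp, phi = 1),
               0.0312764481467092, tolerance = 1e-12)
  # phi = 0 nulls perception regardless of prevalence
  expect_equal(perceived_infection_probability(24, env1, dp, phi = 0), 0)
  # no infectious individuals -> 0
  env0 <- perceived_environment(epidemic_state(S1 = 1), flat_contacts(24),
                                1, dp)
  expect_equal(perceived_infection_probability(24, env0, dp, phi = 1), 0)
  # risk-evaders perceive epsilon-scaled risk
  env2 <- perceived_environment(st, flat_contacts(24), 2, dp)
  p1 <- perceived_infection_probability(24, env1, dp, phi = 1)
  p2 <- perceived_infection_probability(24, env2, dp, phi = 1)
  expect_lt(p2, p1)
  expect_equal(log(1 - p2) / log(1 - p1), dp$epsilon, tolerance = 1e-10)
})

test_that("progression probabilities are the daily exponential forms", {
  pr <- progression_probabilities(dp)
  expect_equal(pr[["P_E"]], 0.181269246922018, tolerance = 1e-12)
  expect_equal(pr[["P_AR"]], 0.10516068318563, tolerance = 1e-12)
  expect_equal(pr[["P_AR"]], pr[["P_IR"]])
  expect_equal(progression_probabilities(disease_params(kappa = 1e-12))[["P_E"]],
               0, tolerance = 1e-10)
})

test_that("static symptomatic/recovered values match forward enumeration", {
  # recovered: geometric sum of discounted u(C*)
  sv <- terminal_static_values(14, bp, dp, group = 1)
  ustar <- utility(24, 48, bp$nu1)
  expect_equal(sv$V_R[1], sum(bp$delta^(0:14)) * ustar, tolerance = 1e-10)
  expect_equal(sv$V_R[15], ustar, tolerance = 1e-12)  # k = tau: one day left
  expect_equal(sv$V_R[16], 0)                          # terminal
  # undiscounted, full symptomatic utility: V_0(I) = V_0(R) = (tau+1) u(C*)
  bp_full <- behavior_params(delta = 1, symptomatic_utility = "full")
  sv_full <- terminal_static_values(10, bp_full, dp)
  expect_equal(sv_full$V_I[1], 11 * utility(24, 48, bp_full$nu1))
  # zero symptomatic utility: forward enumeration of the I -> R chain,
  # V_0(I) = sum_j delta^j P(recovered by day j) u(C*)
  p_ir <- 1 - exp(-dp$gamma)
  oracle <- sum(bp$delta^(0:14) * (1 - (1 - p_ir)^(0:14)) * ustar)
  expect_equal(sv$V_I[1], oracle, tolerance = 1e-10)
  expect_equal(sv$V_I[1], 13.7412550405844, tolerance = 1e-10)
})

test_that("discount conversion matches the annual convention", {
  expect_equal(annual_to_daily_discount(0), 1)
  expect_equal(round(annual_to_daily_discount(0.05), 5), 0.99986)
  rate <- 0.07
  expect_equal(annual_to_daily_discount(rate)^365, 1 - rate, tolerance = 1e-12)
  expect_error(annual_to_daily_discount(1), "\\[0, 1\\)")
})

test_that("policy is the disease-free optimum when no risk is perceived", {
  st <- epidemic_state(S1 = 0.8, E1 = 0.05, A1 = 0.05, I = 0.05, R = 0.05)
  env <- perceived_environment(st, flat_contacts(24), 1, dp)
  # phi = 0: perceived risk nulled
  sol0 <- solve_group_policy(env, dp, behavior_params(phi = 0))
  expect_identical(sol0$C_opt, 24)
  # tau = 0 with zero terminal value: no future to protect
  sol_t0 <- solve_group_policy(env, dp, behavior_params(tau1 = 0))
  expect_identical(sol_t0$C_opt, 24)
  # disease-free environment
  env_free <- perceived_environment(epidemic_state(S1 = 0.5, S2 = 0.5),
                                    flat_contacts(24), 1, dp)
  expect_identical(solve_group_policy(env_free, dp, bp)$C_opt, 24)
})

test_that("optimizer agrees with dense-grid backward induction on 100 random environments", {
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    envr <- random_environment(dp)
    g <- if (i %% 2 == 0) 1L else 2L
    env <- perceived_environment(envr$state, envr$contacts, g, dp)
    mine <- solve_group_policy(env, dp, bp)$C_opt
    oracle <- brute_force_policy(envr$state, envr$contacts, g, dp, bp)
    worst <- max(worst, abs(mine - oracle))
  }
  expect_lt(worst, 24 / 2000 + 1e-6)  # within the oracle's grid spacing
})

test_that("contact choice responds monotonically to prevalence, phi and epsilon", {
  mk_env <- function(prev, group) {
    st <- epidemic_state(S1 = 1 - 2.5 * prev, E1 = prev, E2 = prev / 2,
                         A1 = prev / 2, I = prev / 2)
    perceived_environment(st, flat_contacts(24), group, dp)
  }
  # non-increasing in prevalence
  for (g in 1:2) {
    c_prev <- vapply(c(0.004, 0.02, 0.06, 0.12, 0.2),
                     function(q) solve_group_policy(mk_env(q, g), dp, bp)$C_opt,
                     numeric(1))
    expect_true(all(diff(c_prev) <= 1e-9))
  }
  # non-increasing in phi; phi = 0 gives exactly C*
  c_phi <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(ph) {
    solve_group_policy(mk_env(0.08, 1), dp, behavior_params(phi = ph))$C_opt
  }, numeric(1))
  expect_identical(c_phi[1], 24)
  expect_true(all(diff(c_phi) <= 1e-9))
  # epsilon ordering: at identical nu and tau, risk-evaders perceive less
  # risk, hence sacrifice fewer contacts
  bp_eq <- behavior_params(nu1 = 0.1, nu2 = 0.1, tau1 = 14, tau2 = 14)
  expect_gte(solve_group_policy(mk_env(0.08, 2), dp, bp_eq)$C_opt,
             solve_group_policy(mk_env(0.08, 1), dp, bp_eq)$C_opt)
})

test_that("value ordering holds: susceptible >= exposed >= symptomatic", {
  st <- epidemic_state(S1 = 0.7, E1 = 0.1, A1 = 0.1, I = 0.1)
  for (g in 1:2) {
    env <- perceived_environment(st, flat_contacts(20), g, dp)
    vt <- solve_group_policy(env, dp, bp)$value_table
    expect_true(all(vt$V_S >= vt$V_E - 1e-12))
    expect_true(all(vt$V_E >= vt$V_I - 1e-12))
  }
})

test_that("value table has the documented layout and bounds", {
  st <- epidemic_state(S1 = 0.85, E1 = 0.05, A1 = 0.05, I = 0.05)
  vt <- solve_group_policy(perceived_environment(st, flat_contacts(24), 1, dp),
                           dp, bp)$value_table
  expect_identical(names(vt), c("k", "V_S", "V_E", "V_A", "V_I", "V_R",
                                "C_hat"))
  expect_equal(nrow(vt), bp$tau1 + 1L)
  expect_true(all(vt$C_hat > 0 & vt$C_hat <= 24))
  # last backward step has no future: its optimizer is C*
  expect_equal(vt$C_hat[nrow(vt)], 24)
})
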