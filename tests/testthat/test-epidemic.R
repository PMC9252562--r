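dp <- disease_params()

test_that("mixing fraction matches direct arithmetic and degenerates safely", {
  # no infectious compartments -> 0
  s <- epidemic_state(S1 = 0.6, S2 = 0.3, R = 0.1)
  expect_equal(mixing_fraction(s, flat_contacts(24), dp), 0)

  # equal contact rates cancel: result is rho*E + alpha*A + I
  s2 <- epidemic_state(S1 = 0.5, E1 = 0.1, E2 = 0.1, A1 = 0.05, A2 = 0.05,
                       I = 0.1, R = 0.1)
  expected <- dp$rho * 0.2 + dp$alpha * 0.1 + 0.1
  expect_equal(mixing_fraction(s2, flat_contacts(24), dp), expected)
  expect_equal(mixing_fraction(s2, flat_contacts(7), dp), expected)

  # direct arithmetic: S1=0.9, I=0.1, all contacts 24
  s3 <- epidemic_state(S1 = 0.9, I = 0.1)
  expect_equal(mixing_fraction(s3, flat_contacts(24), dp), 0.1)

  # zero total activity is an explicit error
  expect_error(mixing_fraction(s3, flat_contacts(0), dp), "degenerate mixing")
})

test_that("one-day step reproduces hand-evaluated flows and conserves mass", {
  # no infectious individuals: nothing moves
  s <- epidemic_state(S1 = 0.7, S2 = 0.3)
  out <- step_epidemic(s, flat_contacts(24), dp)
  expect_equal(unclass(out$state), unclass(s))
  expect_equal(out$lambda1, 0)

  # hand-evaluated flows for S1=0.999, E1=0.001, all contacts 24:
  # mix = 0.25*24*0.001/24 = 2.5e-4, lambda1 = 0.01324*24*2.5e-4
  s2 <- epidemic_state(S1 = 0.999, E1 = 0.001)
  out2 <- step_epidemic(s2, flat_contacts(24), dp)
  expect_equal(out2$lambda1, 7.944e-05)
  expect_equal(out2$state[["S1"]], 0.998920642592118, tolerance = 1e-12)
  expect_equal(out2$state[["E1"]], 0.000898088160960032, tolerance = 1e-12)
  expect_equal(out2$state[["A1"]], 9.06346234610091e-05, tolerance = 1e-12)
  expect_equal(out2$state[["I"]], 9.06346234610091e-05, tolerance = 1e-12)
  expect_equal(sum(out2$state), 1, tolerance = 1e-12)
})

test_that("compartment sum stays at 1 over 1000 steps (no drift beyond 1e-9)", {
  state <- initial_state(scenario_config(p = 0.6, i0 = 1e-3))
  contacts <- flat_contacts(24)
  worst <- 0
  for (i in 1:1000) {
    state <- step_epidemic(state, contacts, dp)$state
    worst <- max(worst, abs(sum(state) - 1))
  }
  expect_lt(worst, 1e-9)
})

test_that("continuous-kernel R0 has the SIR closed form and is linear in beta", {
  # sigma = 0, rho = 0: only the symptomatic path remains
  dsir <- disease_params(sigma = 0, rho = 0)
  expect_equal(r0(dsir, b = 48), dsir$beta * 24 / dsir$gamma)
  expect_equal(r0(disease_params(beta = 2 * 0.01324), b = 48),
               2 * r0(disease_params(), b = 48))
  # discrete kernel uses geometric residence times, hence is larger
  expect_gt(r0(dp, b = 48, kernel = "discrete"), r0(dp, b = 48))
})

test_that("constant-contacts final size matches the implicit equation", {
  # homogeneous run vs the root of z = 1 - exp(-R0 z) at the
  # kernel-consistent (discrete) R0, across R0 in [1.5, 3] via beta
  for (target_r0 in c(1.5, 2.0, 2.55, 3.0)) {
    beta <- target_r0 / r0(disease_params(beta = 1), 48, "discrete")
    cfg <- scenario_config(beta = beta, p = 1, epsilon = 1, i0 = 1e-6,
                           t_max = 3000)
    sim <- simulate_constant(cfg)
    expect_true(sim$converged)
    z <- final_size_oracle(r0(cfg$disease, 48, "discrete"))
    expect_equal(attack_rate(sim), z, tolerance = 0.01)
  }
})

test_that("final size is insensitive to small seeds and beta-monotone", {
  ar <- vapply(c(1e-6, 2e-6), function(i0) {
    attack_rate(simulate_constant(scenario_config(p = 1, i0 = i0,
                                                  t_max = 3000)))
  }, numeric(1))
  expect_lt(abs(ar[2] - ar[1]), 1e-3)

  # beta = 0: attack rate equals the seed fraction
  cfg0 <- scenario_config(beta = 0, i0 = 1e-4)
  expect_equal(attack_rate(simulate_constant(cfg0)), 1e-4, tolerance = 1e-12)

  # attack rate non-decreasing in beta
  ars <- vapply(c(0.006, 0.009, 0.01324, 0.02), function(b) {
    attack_rate(simulate_constant(scenario_config(beta = b, p = 1)))
  }, numeric(1))
  expect_true(all(diff(ars) >= 0))
})

test_that("constant-contacts attack rate is monotone in epsilon and p", {
  ar_eps <- vapply(c(0.2, 0.5, 0.8, 1), function(e) {
    attack_rate(simulate_constant(scenario_config(p = 0.5, epsilon = e)))
  }, numeric(1))
  expect_true(all(diff(ar_eps) >= 0))

  ar_p <- vapply(c(0, 0.3, 0.7, 1), function(p) {
    attack_rate(simulate_constant(scenario_config(p = p, epsilon = 0.6)))
  }, numeric(1))
  expect_true(all(diff(ar_p) >= 0))
})

test_that("attack rate agrees with the non-susceptible mass at termination", {
  cfg <- scenario_config(p = 0.4)
  sim <- simulate_constant(cfg)
  tr <- sim$trajectory
  n <- nrow(tr)
  expect_equal(attack_rate(sim),
               tr$E1[n] + tr$E2[n] + tr$A1[n] + tr$A2[n] + tr$I[n] + tr$R[n],
               tolerance = cfg$stop_tol * 10)
})

test_that("trajectory CSV has the mandated columns", {
  sim <- simulate_constant(scenario_config(p = 0.5, t_max = 50))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(sim, path)
  got <- utils::read.csv(path)
  expect_identical(names(got),
                   c("day", "S1", "S2", "E1", "E2", "A1", "A2", "I", "R",
                     "C_S1", "C_S2", "C_I", "lambda1", "lambda2"))
  expect_equal(nrow(got), nrow(sim$trajectory))
})
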