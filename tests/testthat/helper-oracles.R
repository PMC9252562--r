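# Independent oracles used across the suite. These re-derive quantities by
# routes separate from the package implementation: dense-grid backward
# induction for the contact-choice problem, the implicit final-size root,
# and forward enumeration of the symptomatic/recovered Markov chain.

# Brute-force backward induction: argmax over a dense contact grid at every
# step, written independently of solve_group_policy().
brute_force_policy <- function(state, contacts, group, dp, bp, npts = 2000) {
  nu <- if (group == 1L) bp$nu1 else bp$nu2
  tau <- if (group == 1L) bp$tau1 else bp$tau2
  beta_i <- if (group == 1L) dp$beta else dp$epsilon * dp$beta
  s <- unclass(state)
  cc <- unclass(contacts)
  theta <- sum(cc * s)
  phi_num <- dp$rho * (cc[["C_E1"]] * s[["E1"]] + cc[["C_E2"]] * s[["E2"]]) +
    dp$alpha * (cc[["C_A1"]] * s[["A1"]] + cc[["C_A2"]] * s[["A2"]]) +
    cc[["C_I"]] * s[["I"]]
  a <- beta_i * bp$phi * phi_num / theta

  cstar <- bp$b / 2
  Cg <- seq(cstar / npts, cstar, length.out = npts)
  u <- (bp$b * Cg - Cg^2)^nu
  P <- 1 - exp(-a * Cg)
  pe <- 1 - exp(-dp$kappa)
  par <- 1 - exp(-dp$gamma)
  ustar <- (bp$b * cstar - cstar^2)^nu
  ui <- if (bp$symptomatic_utility == "full") ustar else 0

  VS <- VE <- VA <- VI <- VR <- bp$terminal_value
  copt <- cstar
  for (k in seq(tau, 0)) {
    val <- u + bp$delta * ((1 - P) * VS + P * VE)
    i <- which.max(val)
    copt <- Cg[i]
    VS_new <- val[i]
    VE_new <- u[i] + bp$delta * ((1 - pe) * VE +
                                   pe * (dp$sigma * VA + (1 - dp$sigma) * VI))
    VA_new <- u[i] + bp$delta * ((1 - par) * VA + par * VR)
    VI <- ui + bp$delta * ((1 - par) * VI + par * VR)
    VR <- ustar + bp$delta * VR
    VS <- VS_new; VE <- VE_new; VA <- VA_new
  }
  copt
}

# Root of the implicit final-size equation z = 1 - exp(-R0 z).
final_size_oracle <- function(R0) {
  if (R0 <= 1) return(0)
  uniroot(function(z) z - (1 - exp(-R0 * z)), c(1e-12, 1), tol = 1e-12)$root
}

# Random valid decision environment under a fixed RNG state.
random_environment <- function(dp, b = 48) {
  w <- stats::rgamma(8, shape = 1)
  s <- w / sum(w)
  state <- epidemic_state(S1 = s[1], S2 = s[2], E1 = s[3], E2 = s[4],
                          A1 = s[5], A2 = s[6], I = s[7], R = s[8])
  cc <- stats::runif(8, min = 0.5, max = b)
  contacts <- contact_profile(cc[1], cc[2], cc[3], cc[4], cc[5], cc[6],
                              cc[7], cc[8], b = b)
  list(state = state, contacts = contacts)
}

baseline_scenario <- function(...) scenario_config(...)
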