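#' Infectious mixing fraction
#'
#' The probability-weighted share of total population activity contributed
#' by infectious classes: with per-class contact rates `C^h` and population
#' fractions `h`,
#' \deqn{\Phi/\Theta = \frac{\rho(C^{E_1}E_1 + C^{E_2}E_2) +
#'   \alpha(C^{A_1}A_1 + C^{A_2}A_2) + C^I I}{\sum_h C^h h}}
#' where the denominator \eqn{\Theta} is the total population activity. The
#' force of infection on a susceptible making `C` contacts per day is
#' `beta * C * Phi/Theta` (times `epsilon` for risk-evaders).
#'
#' @param state An [epidemic_state()].
#' @param contacts A [contact_profile()].
#' @param dparams A [disease_params()].
#' @return Dimensionless ratio in `[0, max(rho, alpha, 1)]`.
#' @export
mixing_fraction <- function(state, contacts, dparams) {
  s <- unclass(state); cc <- unclass(contacts)
  theta <- sum(cc * s[c("S1", "S2", "E1", "E2", "A1", "A2", "I", "R")])
  if (theta <= 0) {
    stop("degenerate mixing: total population activity is zero", call. = FALSE)
  }
  phi <- dparams$rho * (cc[["C_E1"]] * s[["E1"]] + cc[["C_E2"]] * s[["E2"]]) +
    dparams$alpha * (cc[["C_A1"]] * s[["A1"]] + cc[["C_A2"]] * s[["A2"]]) +
    cc[["C_I"]] * s[["I"]]
  phi / theta
}

#' One-day epidemic update
#'
#' Advances the two-group SEIAR state one day under the given contact
#' profile. All flows are computed simultaneously from the current state
#' with daily transition probabilities `1 - exp(-rate)`:
#' new infections leave `S_i` with probability `1 - exp(-lambda_i)` where
#' `lambda_1 = beta * C_S1 * Phi/Theta` and
#' `lambda_2 = epsilon * beta * C_S2 * Phi/Theta`; exposed individuals
#' progress with probability `1 - exp(-kappa)`, a fraction `sigma` of them
#' to their group's asymptomatic class and `1 - sigma` to the shared
#' symptomatic class; asymptomatic and symptomatic individuals recover with
#' probability `1 - exp(-gamma)`.
#'
#' @inheritParams mixing_fraction
#' @return A list with the updated `state` and the realized forces of
#'   infection `lambda1`, `lambda2`.
#' @export
step_epidemic <- function(state, contacts, dparams) {
  s <- unclass(state); cc <- unclass(contacts)
  mix <- mixing_fraction(state, contacts, dparams)
  lambda1 <- dparams$beta * cc[["C_S1"]] * mix
  lambda2 <- dparams$epsilon * dparams$beta * cc[["C_S2"]] * mix

  p_inf1 <- -expm1(-lambda1)
  p_inf2 <- -expm1(-lambda2)
  p_prog <- -expm1(-dparams$kappa)
  p_rec  <- -expm1(-dparams$gamma)
  sigma <- dparams$sigma

  new_inf1 <- s[["S1"]] * p_inf1
  new_inf2 <- s[["S2"]] * p_inf2
  out_E1 <- s[["E1"]] * p_prog
  out_E2 <- s[["E2"]] * p_prog
  out_A1 <- s[["A1"]] * p_rec
  out_A2 <- s[["A2"]] * p_rec
  out_I  <- s[["I"]] * p_rec

  nxt <- c(
    S1 = s[["S1"]] - new_inf1,
    S2 = s[["S2"]] - new_inf2,
    E1 = s[["E1"]] - out_E1 + new_inf1,
    E2 = s[["E2"]] - out_E2 + new_inf2,
    A1 = s[["A1"]] - out_A1 + sigma * out_E1,
    A2 = s[["A2"]] - out_A2 + sigma * out_E2,
    I  = s[["I"]] - out_I + (1 - sigma) * (out_E1 + out_E2),
    R  = s[["R"]] + out_A1 + out_A2 + out_I
  )
  validate_state(nxt)
  list(state = structure(nxt, class = "epi_state"),
       lambda1 = lambda1, lambda2 = lambda2)
}

#' Constant-contacts baseline simulation
#'
#' Iterates the daily SEIAR kernel with every class fixed at the
#' disease-free optimal contact rate `C* = b/2` until total infectious
#' prevalence (E + A + I) drops below `stop_tol` or `t_max` days elapse.
#' This is the no-behavioral-response baseline against which the adaptive
#' model is compared.
#'
#' @param config A `scenario` from [scenario_config()]; `phi`, `nu` and
#'   `tau` are ignored (no decisions are made).
#' @param state0 Optional initial state; defaults to [initial_state()].
#' @return An `epi_sim` object: list with `trajectory` (data frame with one
#'   row per day), `attack_rate`, `min_contacts`, `converged`, `adaptive`
#'   and a `config` echo.
#' @examples
#' sim <- simulate_constant(scenario_config(p = 1))
#' attack_rate(sim)
#' @export
simulate_constant <- function(config, state0 = initial_state(config)) {
  stopifnot(inherits(config, "scenario"))
  cstar <- config$behavior$b / 2
  contacts <- flat_contacts(cstar, b = config$behavior$b)
  run_simulation(config, state0,
                 decide = function(state, contacts_prev, day) {
                   c(C1 = cstar, C2 = cstar)
                 },
                 contacts0 = contacts, adaptive = FALSE)
}

# Shared day loop for constant and adaptive simulations. `decide` maps
# (state, previous day's realized contacts, day index) to the susceptible
# contact rates of the two risk groups.
run_simulation <- function(config, state0, decide, contacts0, adaptive) {
  dp <- config$disease
  bp <- config$behavior
  cstar <- bp$b / 2
  t_max <- config$t_max
  n <- t_max + 1L

  traj <- matrix(NA_real_, nrow = n, ncol = 13L)
  colnames(traj) <- c(COMPARTMENTS, "C_S1", "C_S2", "C_I",
                      "lambda1", "lambda2")
  state <- state0
  contacts <- contacts0
  traj[1L, 1:8] <- unclass(state)
  traj[1L, 9:11] <- unclass(contacts)[c("C_S1", "C_S2", "C_I")]
  traj[1L, 12:13] <- 0

  converged <- FALSE
  last <- 1L
  for (t in seq_len(t_max)) {
    prevalence <- sum(state[c("E1", "E2", "A1", "A2", "I")])
    if (prevalence < config$stop_tol) {
      converged <- TRUE
      break
    }
    ch <- decide(state, contacts, t)
    contacts <- contact_profile(
      C_S1 = ch[["C1"]], C_S2 = ch[["C2"]],
      C_E1 = ch[["C1"]], C_E2 = ch[["C2"]],
      C_A1 = ch[["C1"]], C_A2 = ch[["C2"]],
      C_I = cstar, C_R = cstar, b = bp$b
    )
    stepped <- step_epidemic(state, contacts, dp)
    state <- stepped$state
    last <- t + 1L
    traj[last, 1:8] <- unclass(state)
    traj[last, 9:11] <- unclass(contacts)[c("C_S1", "C_S2", "C_I")]
    traj[last, 12:13] <- c(stepped$lambda1, stepped$lambda2)
  }
  if (!converged) {
    converged <- sum(state[c("E1", "E2", "A1", "A2", "I")]) < config$stop_tol
  }

  traj <- as.data.frame(traj[seq_len(last), , drop = FALSE])
  traj <- cbind(day = 0:(last - 1L), traj)

  p <- bp$p
  ar <- 1 - traj$S1[last] - traj$S2[last]
  min1 <- min(traj$C_S1); min2 <- min(traj$C_S2)
  structure(
    list(
      trajectory = traj,
      attack_rate = ar,
      min_contacts = c(rt = min1, re = min2),
      min_contact_day = c(rt = traj$day[which.min(traj$C_S1)],
                          re = traj$day[which.min(traj$C_S2)]),
      peak_day = traj$day[which.max(traj$E1 + traj$E2 + traj$A1 +
                                      traj$A2 + traj$I)],
      converged = converged,
      adaptive = adaptive,
      config = config
    ),
    class = "epi_sim"
  )
}

#' Basic reproduction number of the constant-contacts model
#'
#' Next-generation-matrix reproduction number for the homogeneous model
#' (all risk-takers, `p = 1`) at the disease-free optimal contact rate
#' `C* = b/2`. A single infection spends, on average, its incubation period
#' at relative infectiousness `rho`, then either the asymptomatic infectious
#' period at relative infectiousness `alpha` (probability `sigma`) or the
#' symptomatic period at full infectiousness (probability `1 - sigma`);
#' each day in a stage it transmits at rate `beta * C*` times the stage's
#' relative infectiousness (at the disease-free equilibrium the mixing
#' fraction reduces to the infectious weights themselves). Hence
#' \deqn{R_0 = \beta C^* \left(\frac{\rho}{\kappa} +
#'   \frac{\sigma\alpha}{\gamma} + \frac{1-\sigma}{\gamma}\right)}
#' for the continuous-time kernel. The daily discrete-time kernel replaces
#' the exponential residence times `1/kappa`, `1/gamma` by the geometric
#' means `1/(1 - exp(-kappa))`, `1/(1 - exp(-gamma))`; see the package
#' vignette for the full derivation.
#'
#' @param dparams A [disease_params()].
#' @param b Maximum contacts/day (so `C* = b/2`).
#' @param kernel `"continuous"` (exponential residence times; the conventional
#'   calibration convention) or `"discrete"` (geometric residence times
#'   consistent with the daily simulation kernel; use this one in final-size
#'   calculations).
#' @return The reproduction number (dimensionless).
#' @examples
#' r0(disease_params(), b = 48)                      # ~ 2.4
#' r0(disease_params(), b = 48, kernel = "discrete") # ~ 2.55
#' @export
r0 <- function(dparams, b, kernel = c("continuous", "discrete")) {
  kernel <- match.arg(kernel)
  cstar <- b / 2
  if (kernel == "continuous") {
    t_e <- 1 / dparams$kappa
    t_i <- 1 / dparams$gamma
  } else {
    t_e <- 1 / (-expm1(-dparams$kappa))
    t_i <- 1 / (-expm1(-dparams$gamma))
  }
  dparams$beta * cstar *
    (dparams$rho * t_e + dparams$sigma * dparams$alpha * t_i +
       (1 - dparams$sigma) * t_i)
}

#' Final epidemic size
#'
#' `attack_rate()` reads the cumulative fraction ever infected,
#' `1 - S1(T) - S2(T)`, off a completed simulation.
#' `final_size_implicit()` solves the classical implicit final-size
#' equation `z = 1 - exp(-R0 * z)` for a homogeneous epidemic with
#' reproduction number `R0`.
#'
#' @param result An `epi_sim`.
#' @return A fraction in `[0, 1]`.
#' @export
attack_rate <- function(result) {
  stopifnot(inherits(result, "epi_sim"))
  result$attack_rate
}

#' @rdname attack_rate
#' @param R0 Reproduction number (> 1 for a non-trivial root).
#' @export
final_size_implicit <- function(R0) {
  stopifnot(is.numeric(R0), R0 >= 0)
  if (R0 <= 1) return(0)
  stats::uniroot(function(z) z - (-expm1(-R0 * z)),
                 interval = c(1e-12, 1), tol = 1e-12)$root
}

#' Per-group attack rates
#'
#' Decomposes the overall attack rate by risk group: group i's attack rate
#' is the fraction of that group's initial size that left its susceptible
#' compartment by the end of the run.
#'
#' @param result An `epi_sim`.
#' @param p Proportion of risk-takers (defaults to the run's configuration).
#' @return Named numeric vector `overall`, `rt`, `re`; a degenerate group
#'   (size 0) reports `NA`.
#' @export
group_attack_rates <- function(result, p = result$config$behavior$p) {
  stopifnot(inherits(result, "epi_sim"))
  traj <- result$trajectory
  n <- nrow(traj)
  overall <- 1 - traj$S1[n] - traj$S2[n]
  rt <- if (p > 0) (traj$S1[1] - traj$S1[n]) / p else NA_real_
  re <- if (p < 1) (traj$S2[1] - traj$S2[n]) / (1 - p) else NA_real_
  c(overall = overall, rt = rt, re = re)
}

#' @export
print.epi_sim <- function(x, ...) {
  n <- nrow(x$trajectory)
  cat(sprintf("%s simulation: %d days%s\n",
              if (x$adaptive) "Adaptive-behavior" else "Constant-contacts",
              n - 1L,
              if (x$converged) " (epidemic extinguished)" else " (horizon hit)"))
  cat(sprintf("  attack rate: %.4f\n", x$attack_rate))
  cstar <- x$config$behavior$b / 2
  cat(sprintf("  min contacts: RT %.2f (day %d), RE %.2f (day %d); C* = %g\n",
              x$min_contacts[["rt"]], as.integer(x$min_contact_day[["rt"]]),
              x$min_contacts[["re"]], as.integer(x$min_contact_day[["re"]]),
              cstar))
  invisible(x)
}
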