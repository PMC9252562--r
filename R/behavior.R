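#' Contact utility
#'
#' Daily utility of making `C` contacts, `u(C) = (b*C - C^2)^nu`: a
#' single-peaked function, zero at `C = 0` and `C = b`, maximized at the
#' disease-free optimum `C* = b/2` for every shape `nu > 0`. Smaller `nu`
#' flattens the peak so that shedding contacts costs less utility.
#'
#' @param C Contact rate(s), each in `[0, b]`.
#' @param b Maximum contacts/day.
#' @param nu Shape parameter in (0, 1\].
#' @return Utility value(s).
#' @examples
#' utility(24, b = 48, nu = 0.1)    # 576^0.1
#' @export
utility <- function(C, b, nu) {
  if (any(C < 0 | C > b)) {
    stop("contact rate outside [0, b]: utility base would be negative",
         call. = FALSE)
  }
  (b * C - C^2)^nu
}

#' Perceived daily infection probability
#'
#' Probability of infection perceived by a susceptible decision-maker of a
#' risk group who plans to make `C` contacts today:
#' `1 - exp(-beta_i * C * phi * Phi/Theta)`, with `beta_1 = beta` for
#' risk-takers and `beta_2 = epsilon * beta` for risk-evaders. The mixing
#' fraction `Phi/Theta` is evaluated on the *frozen* environment (yesterday's
#' realized contacts for every class, today's state): the decision variable
#' `C` scales the individual's own exposure but does not perturb the
#' population activity `Theta` (atomistic decision-maker). The reporting
#' level `phi` scales only the perceived infectious activity `Phi` — others'
#' total activity is observable, their infection status is not.
#'
#' @param C Planned contact rate (contacts/day).
#' @param env A [perceived_environment()].
#' @param dparams A [disease_params()].
#' @param phi Reporting level in \[0, 1\].
#' @return Probability in \[0, 1).
#' @export
perceived_infection_probability <- function(C, env, dparams, phi) {
  beta_i <- if (env$group == 1L) dparams$beta else dparams$epsilon * dparams$beta
  -expm1(-beta_i * C * phi * env$mix)
}

#' Frozen decision environment
#'
#' Snapshot of the epidemic state and the previous day's realized contact
#' profile against which one risk group solves its contact-choice problem.
#' The mixing fraction is computed once at construction and reused by every
#' backward-induction step (constant-prevalence projection).
#'
#' @param state An [epidemic_state()].
#' @param contacts A [contact_profile()] of yesterday's realized rates.
#' @param group 1 (risk-taker) or 2 (risk-evader).
#' @param dparams A [disease_params()] used to fold the infectiousness
#'   weights into the frozen mixing fraction.
#' @return A `perceived_environment` object.
#' @export
perceived_environment <- function(state, contacts, group, dparams) {
  group <- as.integer(group)
  stopifnot(group %in% c(1L, 2L))
  structure(
    list(state = state, contacts = contacts, group = group,
         mix = mixing_fraction(state, contacts, dparams)),
    class = "perceived_environment"
  )
}

#' Daily health-state transition probabilities
#'
#' The probabilities used by both the epidemic kernel and the decision
#' model: progression out of the exposed class, `1 - exp(-kappa)`, and
#' recovery of asymptomatic and symptomatic individuals, `1 - exp(-gamma)`.
#'
#' @param dparams A [disease_params()].
#' @return Named vector `(P_E, P_AR, P_IR)`.
#' @export
progression_probabilities <- function(dparams) {
  c(P_E = -expm1(-dparams$kappa),
    P_AR = -expm1(-dparams$gamma),
    P_IR = -expm1(-dparams$gamma))
}

#' Expected utilities of symptomatic and recovered individuals
#'
#' Symptomatic and recovered individuals have no incentive to adapt (no
#' reinfection), so their value functions are epidemic-state-independent
#' recursions that can be computed once per horizon: recovered individuals
#' collect `u(C*)` every day, `V_k(R) = sum_{j=0}^{tau-k} delta^j u(C*)`;
#' symptomatic individuals collect either nothing (`symptomatic_utility =
#' "zero"`, the default behavioral assumption — illness suspends utility,
#' which is what makes infection costly) or `u(C*)` (`"full"`), and recover
#' with daily probability `1 - exp(-gamma)`.
#'
#' @param horizon Planning horizon `tau` (days, >= 0).
#' @param bparams A [behavior_params()].
#' @param dparams A [disease_params()].
#' @param group Risk group (1 or 2) whose utility shape `nu` applies.
#' @return List with numeric vectors `V_I` and `V_R`, indexed `k = 0..tau+1`
#'   (element `k + 1`), the last entry holding the terminal value.
#' @export
terminal_static_values <- function(horizon, bparams, dparams, group = 1L) {
  stopifnot(horizon >= 0, group %in% c(1L, 2L))
  nu <- if (group == 1L) bparams$nu1 else bparams$nu2
  static_values(horizon, nu, bparams, dparams)
}

# Group-specific static value recursions for I and R.
static_values <- function(horizon, nu, bparams, dparams) {
  cstar <- bparams$b / 2
  u_star <- utility(cstar, bparams$b, nu)
  u_i <- if (bparams$symptomatic_utility == "full") u_star else 0
  delta <- bparams$delta
  p_ir <- -expm1(-dparams$gamma)
  n <- horizon + 2L  # k = 0..tau+1
  V_I <- numeric(n); V_R <- numeric(n)
  V_I[n] <- bparams$terminal_value
  V_R[n] <- bparams$terminal_value
  for (k in seq(horizon, 0)) {
    V_R[k + 1L] <- u_star + delta * V_R[k + 2L]
    V_I[k + 1L] <- u_i + delta * ((1 - p_ir) * V_I[k + 2L] +
                                    p_ir * V_R[k + 2L])
  }
  list(V_I = V_I, V_R = V_R)
}

#' Convert an annual discount rate to a daily discount factor
#'
#' The daily factor `delta` satisfies `delta^365 = 1 - annual_rate`, i.e.
#' `delta = (1 - annual_rate)^(1/365)`. A 5% annual rate gives the baseline
#' `delta = 0.99986` (5 decimals).
#'
#' @param annual_rate Annual discount rate in \[0, 1).
#' @return Daily discount factor.
#' @examples
#' annual_to_daily_discount(0.05)
#' @export
annual_to_daily_discount <- function(annual_rate) {
  if (!is.numeric(annual_rate) || any(annual_rate < 0) ||
      any(annual_rate >= 1)) {
    stop("annual rate must lie in [0, 1)", call. = FALSE)
  }
  (1 - annual_rate)^(1 / 365)
}

# Maximize g(C) = u(C) - d_gap * (1 - exp(-a * C)) over (0, cstar].
# A bracketing grid locates the basin, stats::optimize refines it; ties
# within 1e-12 are broken toward larger C (the disease-free optimum).
maximize_contact_choice <- function(a, d_gap, b, nu, delta = NULL) {
  cstar <- b / 2
  if (a <= 0 || d_gap <= 0) return(cstar)  # no perceived risk: u is maximized
  grid <- seq(cstar / 256, cstar, length.out = 256)
  refine_contact_choice(grid, utility(grid, b, nu) - d_gap * (-expm1(-a * grid)),
                        a, d_gap, b, nu)
}

# Refine a grid argmax of g(C) = u(C) - d_gap * (1 - exp(-a C)) with a
# bounded 1-D optimization in the bracketing interval (absolute tolerance
# 1e-6 contacts); ties go to larger C.
refine_contact_choice <- function(grid, vals, a, d_gap, b, nu) {
  cstar <- b / 2
  n <- length(grid)
  i <- n + 1L - which.max(rev(vals))   # last argmax: larger C wins ties
  obj <- function(C) utility(C, b, nu) - d_gap * (-expm1(-a * C))
  lo <- if (i == 1L) grid[1L] / 2 else grid[i - 1L]
  hi <- if (i == n) cstar else grid[i + 1L]
  opt <- stats::optimize(obj, interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-6)
  cand_c <- c(grid[i], opt$maximum, cstar)
  cand_v <- c(vals[i], opt$objective, obj(cstar))
  best <- which(cand_v >= max(cand_v) - 1e-12)
  cand_c[best[length(best)]]
}

#' Solve one risk group's contact-choice problem
#'
#' Backward induction over the group's planning horizon `tau` with terminal
#' value `V_{tau+1}(.) = terminal_value` (default 0). The environment is
#' frozen: the current prevalence and yesterday's realized contacts are
#' assumed to persist over the whole horizon, so the perceived infection
#' probability depends only on the chosen `C`. At each backward step `k`:
#' the optimal contact rate maximizes
#' `u(C) + delta * [(1 - P(C)) V_{k+1}(S) + P(C) V_{k+1}(E)]` over
#' `(0, b/2]` (rates above `b/2` lower utility *and* raise risk, so they
#' are dominated); the exposed and asymptomatic values use the same contact
#' rate — lacking symptoms, those individuals believe themselves
#' susceptible; symptomatic and recovered values come from the static
#' recursions. `C_hat[1]` (the step-0 optimizer) is the contact rate the
#' group's S, E and A classes realize today.
#'
#' @param env A [perceived_environment()].
#' @param dparams A [disease_params()].
#' @param bparams A [behavior_params()].
#' @return List with `C_opt` (today's optimal contact rate) and
#'   `value_table`, a data frame with columns `k, V_S, V_E, V_A, V_I, V_R,
#'   C_hat` for `k = 0..tau`.
#' @export
solve_group_policy <- function(env, dparams, bparams) {
  g <- env$group
  nu <- if (g == 1L) bparams$nu1 else bparams$nu2
  tau <- if (g == 1L) bparams$tau1 else bparams$tau2
  b <- bparams$b
  delta <- bparams$delta
  beta_i <- if (g == 1L) dparams$beta else dparams$epsilon * dparams$beta
  a <- beta_i * bparams$phi * env$mix   # P(C) = 1 - exp(-a C), frozen

  pr <- progression_probabilities(dparams)
  p_e <- pr[["P_E"]]; p_ar <- pr[["P_AR"]]
  sv <- static_values(tau, nu, bparams, dparams)
  V_I <- sv$V_I; V_R <- sv$V_R

  n <- tau + 2L
  V_S <- numeric(n); V_E <- numeric(n); V_A <- numeric(n)
  V_S[n] <- bparams$terminal_value
  V_E[n] <- bparams$terminal_value
  V_A[n] <- bparams$terminal_value
  C_hat <- numeric(tau + 1L)

  # The search grid and its utility / infection-probability values are
  # shared by every backward step (frozen environment); only the
  # continuation gap changes with k. The step-0 choice, the one that is
  # realized, gets a continuous refinement.
  cstar <- b / 2
  grid <- seq(cstar / 256, cstar, length.out = 256)
  u_grid <- utility(grid, b, nu)
  p_grid <- -expm1(-a * grid)

  for (k in seq(tau, 0)) {
    vs1 <- V_S[k + 2L]; ve1 <- V_E[k + 2L]
    d_gap <- delta * (vs1 - ve1)
    if (a <= 0 || d_gap <= 0) {
      ck <- cstar
    } else {
      vals <- u_grid - d_gap * p_grid
      ck <- if (k == 0L) {
        refine_contact_choice(grid, vals, a, d_gap, b, nu)
      } else {
        grid[length(grid) + 1L - which.max(rev(vals))]
      }
    }
    u_ck <- utility(ck, b, nu)
    p_se <- -expm1(-a * ck)
    V_S[k + 1L] <- u_ck + delta * ((1 - p_se) * vs1 + p_se * ve1)
    V_E[k + 1L] <- u_ck + delta * ((1 - p_e) * ve1 +
                                     p_e * (dparams$sigma * V_A[k + 2L] +
                                              (1 - dparams$sigma) * V_I[k + 2L]))
    V_A[k + 1L] <- u_ck + delta * ((1 - p_ar) * V_A[k + 2L] +
                                     p_ar * V_R[k + 2L])
    C_hat[k + 1L] <- ck
  }

  list(
    C_opt = C_hat[1L],
    value_table = data.frame(
      k = 0:tau,
      V_S = V_S[seq_len(tau + 1L)],
      V_E = V_E[seq_len(tau + 1L)],
      V_A = V_A[seq_len(tau + 1L)],
      V_I = V_I[seq_len(tau + 1L)],
      V_R = V_R[seq_len(tau + 1L)],
      C_hat = C_hat
    )
  )
}
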