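#' Disease progression and transmission parameters
#'
#' Container for the constants of the two-risk-group SEIAR transmission
#' kernel. Rates are per day; scalar factors are dimensionless.
#'
#' @param beta Per-contact likelihood of transmission from a symptomatic
#'   contact (per contact, >= 0).
#' @param kappa Incubation rate (1/day): exposed individuals progress with
#'   daily probability `1 - exp(-kappa)`.
#' @param gamma Recovery rate (1/day) shared by symptomatic and asymptomatic
#'   individuals.
#' @param rho Relative infectiousness of exposed individuals, in \[0, 1\].
#' @param alpha Relative infectiousness of asymptomatic individuals, in
#'   \[0, 1\].
#' @param sigma Fraction of infections that remain asymptomatic, in \[0, 1\].
#' @param epsilon Risk-evader per-contact infection-risk scalar, in \[0, 1\]
#'   (1 = no reduction relative to risk-takers).
#'
#' @return An object of class `disease_params` (a validated named list).
#' @examples
#' dp <- disease_params()          # baseline parameterization (R0 ~ 2.4)
#' r0(dp, b = 48, kernel = "continuous")
#' @export
disease_params <- function(beta = 0.01324, kappa = 1 / 5, gamma = 1 / 9,
                           rho = 0.25, alpha = 0.4, sigma = 0.5,
                           epsilon = 0.7) {
  stopifnot(
    is.numeric(beta), length(beta) == 1L, is.finite(beta), beta >= 0,
    is.numeric(kappa), length(kappa) == 1L, kappa > 0,
    is.numeric(gamma), length(gamma) == 1L, gamma > 0
  )
  for (nm in c("rho", "alpha", "sigma", "epsilon")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1) {
      stop(sprintf("`%s` must be a single value in [0, 1]", nm), call. = FALSE)
    }
  }
  structure(
    list(beta = beta, kappa = kappa, gamma = gamma, rho = rho, alpha = alpha,
         sigma = sigma, epsilon = epsilon),
    class = "disease_params"
  )
}

#' Behavioral decision parameters
#'
#' Constants of the per-group finite-horizon Markov decision problems.
#'
#' @param b Maximum possible contacts per day (> 0). The disease-free optimal
#'   contact rate is `C* = b/2`.
#' @param nu1,nu2 Utility shape parameters for risk-takers / risk-evaders,
#'   each in (0, 1\]. Smaller values flatten the utility curve, lowering the
#'   cost of shedding contacts.
#' @param tau1,tau2 Planning horizons in days (non-negative integers) for
#'   risk-takers / risk-evaders.
#' @param delta Daily discount factor in (0, 1\].
#' @param phi Reporting (surveillance) level in \[0, 1\]: fraction of the
#'   infectious population visible to decision-makers. Distorts perceived,
#'   never actual, infection risk.
#' @param p Proportion of risk-takers in the population, in \[0, 1\].
#' @param symptomatic_utility Either `"zero"` (symptomatic individuals accrue
#'   no utility while infectious; the default behavioral assumption) or
#'   `"full"` (they accrue `u(C*)` like recovered individuals).
#' @param terminal_value Value assigned to every health state beyond the
#'   planning horizon (default 0; a state-independent constant leaves all
#'   contact decisions unchanged).
#'
#' @return An object of class `behavior_params`.
#' @examples
#' bp <- behavior_params(p = 0.66)
#' @export
behavior_params <- function(b = 48, nu1 = 0.1, nu2 = 0.05,
                            tau1 = 14L, tau2 = 14L,
                            delta = 0.99986, phi = 1, p = 0.5,
                            symptomatic_utility = c("zero", "full"),
                            terminal_value = 0) {
  symptomatic_utility <- match.arg(symptomatic_utility)
  stopifnot(
    is.numeric(b), length(b) == 1L, b > 0,
    is.numeric(nu1), nu1 > 0, nu1 <= 1,
    is.numeric(nu2), nu2 > 0, nu2 <= 1,
    is.numeric(delta), delta > 0, delta <= 1,
    is.numeric(phi), phi >= 0, phi <= 1,
    is.numeric(p), p >= 0, p <= 1,
    is.numeric(terminal_value), length(terminal_value) == 1L
  )
  tau1 <- as.integer(tau1); tau2 <- as.integer(tau2)
  if (is.na(tau1) || tau1 < 0L || is.na(tau2) || tau2 < 0L) {
    stop("planning horizons `tau1`, `tau2` must be non-negative integers",
         call. = FALSE)
  }
  structure(
    list(b = b, nu1 = nu1, nu2 = nu2, tau1 = tau1, tau2 = tau2,
         delta = delta, phi = phi, p = p,
         symptomatic_utility = symptomatic_utility,
         terminal_value = terminal_value),
    class = "behavior_params"
  )
}

#' Full scenario configuration
#'
#' Bundles disease and behavior parameters with initial conditions and run
#' control into a single flat-keyed scenario, mirroring the baseline
#' parameter table of the model. All arguments default to the baseline
#' calibration (reproduction number 2.4 for the homogeneous
#' constant-contacts model).
#'
#' @param beta,kappa,gamma,rho,alpha,sigma,epsilon See [disease_params()].
#' @param b,nu1,nu2,tau1,tau2,delta,phi,p See [behavior_params()].
#' @param i0 Initial seed: total fraction of the population initially in the
#'   exposed compartments.
#' @param t_max Maximum simulated days.
#' @param stop_tol Simulation stops once total infectious prevalence
#'   (E + A + I) falls below this value.
#' @param seed_split Either `"proportional"` (seed split across risk groups
#'   in proportion to group sizes, the default) or a numeric fraction of the
#'   seed assigned to the risk-taker group.
#' @param symptomatic_utility,terminal_value See [behavior_params()].
#' @param seed Unused by the deterministic pipeline; retained in the config
#'   echo for forward compatibility.
#'
#' @return An object of class `scenario` with elements `disease`
#'   ([disease_params()]), `behavior` ([behavior_params()]), `i0`, `t_max`,
#'   `stop_tol`, `seed_split`, `seed`.
#' @examples
#' sc <- scenario_config(p = 0.33, epsilon = 0.7)
#' @export
scenario_config <- function(beta = 0.01324, kappa = 1 / 5, gamma = 1 / 9,
                            rho = 0.25, alpha = 0.4, sigma = 0.5,
                            epsilon = 0.7,
                            b = 48, nu1 = 0.1, nu2 = 0.05,
                            tau1 = 14L, tau2 = 14L, delta = 0.99986,
                            phi = 1, p = 0.5,
                            i0 = 1e-4, t_max = 1000L, stop_tol = 1e-7,
                            seed_split = "proportional",
                            symptomatic_utility = "zero",
                            terminal_value = 0,
                            seed = NULL) {
  stopifnot(is.numeric(i0), i0 >= 0, i0 < 1,
            is.numeric(t_max), t_max >= 1,
            is.numeric(stop_tol), stop_tol >= 0)
  if (is.character(seed_split)) {
    seed_split <- match.arg(seed_split, "proportional")
  } else {
    stopifnot(is.numeric(seed_split), seed_split >= 0, seed_split <= 1)
  }
  structure(
    list(
      disease = disease_params(beta = beta, kappa = kappa, gamma = gamma,
                               rho = rho, alpha = alpha, sigma = sigma,
                               epsilon = epsilon),
      behavior = behavior_params(b = b, nu1 = nu1, nu2 = nu2, tau1 = tau1,
                                 tau2 = tau2, delta = delta, phi = phi, p = p,
                                 symptomatic_utility = symptomatic_utility,
                                 terminal_value = terminal_value),
      i0 = i0, t_max = as.integer(t_max), stop_tol = stop_tol,
      seed_split = seed_split, seed = seed
    ),
    class = "scenario"
  )
}

#' Modify a scenario
#'
#' Returns a copy of `config` with the named flat keys replaced. Keys are the
#' same flat names accepted by [scenario_config()].
#'
#' @param config A `scenario`.
#' @param ... Named flat keys to replace (e.g. `p = 0.66`, `phi = 0.5`).
#' @return A new `scenario`.
#' @export
update_scenario <- function(config, ...) {
  stopifnot(inherits(config, "scenario"))
  args <- utils::modifyList(scenario_flat(config), list(...))
  do.call(scenario_config, args)
}

# Flatten a scenario back to scenario_config() arguments.
scenario_flat <- function(config) {
  c(unclass(config$disease),
    unclass(config$behavior),
    list(i0 = config$i0, t_max = config$t_max, stop_tol = config$stop_tol,
         seed_split = config$seed_split, seed = config$seed))
}

#' Read / write a scenario configuration file
#'
#' Scenario files are flat YAML key-value mappings whose keys match the
#' baseline parameter symbols: `beta, kappa, gamma, rho, alpha, sigma,
#' epsilon, p, b, nu1, nu2, tau1, tau2, delta, phi, i0, t_max, stop_tol,
#' seed_split` (plus the optional `symptomatic_utility`, `terminal_value`,
#' `seed`). Missing keys take the baseline defaults.
#'
#' @param path Path to a YAML file.
#' @return `read_scenario()` returns a `scenario`; `write_scenario()`
#'   (invisibly) the path written.
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("scenario file must be a YAML mapping", call. = FALSE)
  known <- names(formals(scenario_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown scenario keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(scenario_config, raw)
}

#' @rdname read_scenario
#' @param config A `scenario` to serialize.
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "scenario"))
  flat <- scenario_flat(config)
  flat <- flat[!vapply(flat, is.null, logical(1))]
  yaml::write_yaml(flat, path, precision = 15)
  invisible(path)
}

#' @export
print.disease_params <- function(x, ...) {
  cat("Disease parameters (two-group SEIAR kernel)\n")
  cat(sprintf("  beta=%.5g  kappa=%.4g  gamma=%.4g\n", x$beta, x$kappa, x$gamma))
  cat(sprintf("  rho=%.3g  alpha=%.3g  sigma=%.3g  epsilon=%.3g\n",
              x$rho, x$alpha, x$sigma, x$epsilon))
  invisible(x)
}

#' @export
print.behavior_params <- function(x, ...) {
  cat("Behavioral decision parameters\n")
  cat(sprintf("  b=%g (C*=%g)  nu1=%.3g  nu2=%.3g  tau1=%d  tau2=%d\n",
              x$b, x$b / 2, x$nu1, x$nu2, x$tau1, x$tau2))
  cat(sprintf("  delta=%.6g  phi=%.3g  p=%.3g  symptomatic utility: %s\n",
              x$delta, x$phi, x$p, x$symptomatic_utility))
  invisible(x)
}

#' @export
print.scenario <- function(x, ...) {
  cat("Scenario configuration\n")
  print(x$disease)
  print(x$behavior)
  cat(sprintf("  i0=%.3g  t_max=%d  stop_tol=%.3g  seed_split=%s\n",
              x$i0, x$t_max, x$stop_tol,
              if (is.character(x$seed_split)) x$seed_split
              else format(x$seed_split)))
  invisible(x)
}
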