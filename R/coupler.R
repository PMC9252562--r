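#' Coupled epidemic-behavior simulation
#'
#' Runs the daily feedback loop between the SEIAR kernel and the two
#' risk groups' contact-choice problems. Each day `t`:
#' \enumerate{
#'   \item each group builds a frozen decision environment from the current
#'     state and the previous day's realized contact profile (the other
#'     group's rates are taken as observed — one-step Jacobi decoupling);
#'   \item both groups solve their finite-horizon Bellman problems
#'     independently ([solve_group_policy()]);
#'   \item the group's susceptible, exposed and asymptomatic classes all
#'     adopt the group optimum (non-symptomatic individuals believe
#'     themselves susceptible); symptomatic and recovered classes stay at
#'     the disease-free optimum `C*`;
#'   \item the epidemic advances one day with the *true* transmission
#'     process: `epsilon` applies, the reporting level `phi` does not —
#'     `phi` distorts perception only.
#' }
#' Day-0 contacts are `C*` for every class (the early epidemic runs ahead
#' of any behavioral response). Terminates when total infectious prevalence
#' drops below `stop_tol` or after `t_max` days.
#'
#' @param config A `scenario` from [scenario_config()].
#' @param state0 Optional initial state; defaults to [initial_state()].
#' @return An `epi_sim` (see [simulate_constant()]), with `adaptive = TRUE`.
#' @examples
#' \donttest{
#' sim <- simulate_adaptive(scenario_config(p = 0.66, epsilon = 0.7))
#' contact_reduction_at_peak(sim, group = 2)
#' }
#' @export
simulate_adaptive <- function(config, state0 = initial_state(config)) {
  stopifnot(inherits(config, "scenario"))
  dp <- config$disease
  bp <- config$behavior
  cstar <- bp$b / 2
  contacts0 <- flat_contacts(cstar, b = bp$b)

  decide <- function(state, contacts_prev, day) {
    sol <- withCallingHandlers(
      list(
        c1 = solve_group_policy(
          perceived_environment(state, contacts_prev, 1L, dp), dp, bp),
        c2 = solve_group_policy(
          perceived_environment(state, contacts_prev, 2L, dp), dp, bp)
      ),
      error = function(e) {
        stop(sprintf("day %d: %s", day, conditionMessage(e)), call. = FALSE)
      }
    )
    c(C1 = sol$c1$C_opt, C2 = sol$c2$C_opt)
  }
  run_simulation(config, state0, decide, contacts0, adaptive = TRUE)
}

#' Peak contact-rate reduction of a risk group
#'
#' The strongest relative reduction of a group's susceptible contact rate
#' over the whole trajectory, `100 * (1 - min_t C_S(t) / C*)`, in percent.
#' The trajectory minimum operationalizes the reduction "at the peak": the
#' contact rate bottoms out when perceived prevalence peaks.
#'
#' @param result An `epi_sim`.
#' @param group 1 (risk-takers) or 2 (risk-evaders).
#' @return Percent reduction in `[0, 100)`.
#' @export
contact_reduction_at_peak <- function(result, group) {
  stopifnot(inherits(result, "epi_sim"), group %in% c(1L, 2L))
  cstar <- result$config$behavior$b / 2
  key <- if (group == 1L) "rt" else "re"
  100 * (1 - result$min_contacts[[key]] / cstar)
}

#' Write a simulation trajectory to CSV
#'
#' One row per day with columns `day, S1, S2, E1, E2, A1, A2, I, R, C_S1,
#' C_S2, C_I, lambda1, lambda2`, floats at 10 significant digits.
#'
#' @param result An `epi_sim`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(result, path) {
  stopifnot(inherits(result, "epi_sim"))
  traj <- result$trajectory
  out <- traj
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v) signif(v, 10))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulation summary to JSON
#'
#' Records attack rates (overall and per group), minimum contact rates and
#' the days they occur, the prevalence peak day and the convergence flag.
#'
#' @param result An `epi_sim`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_summary <- function(result, path) {
  stopifnot(inherits(result, "epi_sim"))
  gar <- group_attack_rates(result)
  out <- list(
    adaptive = result$adaptive,
    attack_rate = gar[["overall"]],
    attack_rate_rt = gar[["rt"]],
    attack_rate_re = gar[["re"]],
    min_C_S1 = result$min_contacts[["rt"]],
    min_C_S2 = result$min_contacts[["re"]],
    min_day_rt = result$min_contact_day[["rt"]],
    min_day_re = result$min_contact_day[["re"]],
    peak_day = result$peak_day,
    days = nrow(result$trajectory) - 1L,
    converged = result$converged
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
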