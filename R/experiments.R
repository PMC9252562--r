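#' Parameter sweep specification
#'
#' Describes a rectangular grid of scenario variations: each axis is a
#' scenario key (any flat key of [scenario_config()]) with a vector of
#' values. Rows of the resulting sweep are ordered lexicographically over
#' the axes in the order given (first axis slowest).
#'
#' @param axes Named list of non-empty grids, e.g.
#'   `list(p = seq(0, 1, 0.25), epsilon = seq(0, 1, 0.25))`.
#' @param base Base `scenario` the axes perturb.
#' @param include_constant Also run the constant-contacts baseline at every
#'   grid point and report its attack rate.
#' @return A `sweep_spec` object.
#' @export
sweep_spec <- function(axes, base = scenario_config(),
                       include_constant = FALSE) {
  stopifnot(is.list(axes), length(axes) >= 1L, !is.null(names(axes)),
            all(nzchar(names(axes))), inherits(base, "scenario"))
  known <- names(formals(scenario_config))
  bad <- setdiff(names(axes), known)
  if (length(bad)) {
    stop("unknown scenario keys in axes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(vapply(axes, length, integer(1)) == 0L)) {
    stop("every axis grid must be non-empty", call. = FALSE)
  }
  structure(list(axes = axes, base = base,
                 include_constant = include_constant),
            class = "sweep_spec")
}

#' Run a parameter sweep
#'
#' Evaluates [simulate_adaptive()] (and, if requested, the
#' constant-contacts baseline) at every grid point of a [sweep_spec()].
#' The pipeline is fully deterministic, so repeated runs produce identical
#' tables. A failing grid point is flagged in its row rather than aborting
#' the sweep.
#'
#' @param spec A [sweep_spec()].
#' @return A data frame of class `sweep_result`: one row per grid point
#'   with the axis values followed by `attack_rate`, `attack_rate_rt`,
#'   `attack_rate_re`, `attack_rate_constant`, `min_C_S1`, `min_C_S2`,
#'   `peak_day`, `converged`.
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  axes <- spec$axes
  # expand.grid varies the first factor fastest; reverse for lexicographic
  # order with the first axis slowest.
  grid <- expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(axes)), drop = FALSE]
  names(grid) <- names(axes)

  n <- nrow(grid)
  out <- data.frame(
    grid,
    attack_rate = NA_real_, attack_rate_rt = NA_real_,
    attack_rate_re = NA_real_, attack_rate_constant = NA_real_,
    min_C_S1 = NA_real_, min_C_S2 = NA_real_,
    peak_day = NA_integer_, converged = NA,
    check.names = FALSE
  )
  for (i in seq_len(n)) {
    cfg <- do.call(update_scenario,
                   c(list(spec$base), as.list(grid[i, , drop = FALSE])))
    row <- tryCatch({
      sim <- simulate_adaptive(cfg)
      gar <- group_attack_rates(sim)
      const_ar <- if (spec$include_constant) {
        attack_rate(simulate_constant(cfg))
      } else NA_real_
      list(gar[["overall"]], gar[["rt"]], gar[["re"]], const_ar,
           sim$min_contacts[["rt"]], sim$min_contacts[["re"]],
           as.integer(sim$peak_day), sim$converged)
    }, error = function(e) {
      warning(sprintf("grid point %d failed: %s", i, conditionMessage(e)),
              call. = FALSE)
      list(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
           NA_integer_, FALSE)
    })
    out[i, length(axes) + 1:8] <- row
  }
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Scenario presets for the benchmark experiments
#'
#' Returns the scenario or sweep encoding of the named experiment, all at
#' the baseline parameterization unless an axis varies it:
#' \describe{
#'   \item{"3A"}{single adaptive-vs-constant scenario, `p = 0.33`,
#'     `epsilon = 0.7`.}
#'   \item{"3B"}{same with `p = 0.66`.}
#'   \item{"4"}{attack-rate surface over `p` x `epsilon` (step 0.05), both
#'     models.}
#'   \item{"5"}{the same surface for asymptomatic fractions
#'     `sigma = 0.25, 0.5, 0.75`.}
#'   \item{"6"}{contact trajectories at reporting levels
#'     `phi = 0.25, 0.5, 1`.}
#'   \item{"7"}{attack-rate surface over reporting level `phi` x `p`.}
#'   \item{"8"}{attack rate over planning-horizon grids `tau1 x tau2`
#'     (1..30) at `p = 0.33, 0.5, 0.75`.}
#' }
#'
#' @param figure One of `"3A", "3B", "4", "5", "6", "7", "8"`.
#' @param base Base scenario (baseline parameters by default).
#' @param step Grid step for continuous axes (default 0.05).
#' @param tau_max Upper bound of the planning-horizon grids (default 30).
#' @return A `scenario` (3A, 3B), a `sweep_spec` (4, 6, 7), or a named list
#'   of `sweep_spec`s (5, 8).
#' @export
preset_fig <- function(figure, base = scenario_config(), step = 0.05,
                       tau_max = 30L) {
  figure <- as.character(figure)
  pg <- seq(0, 1, by = step)
  eg <- seq(0, 1, by = step)
  switch(
    figure,
    "3A" = update_scenario(base, p = 0.33, epsilon = 0.7),
    "3B" = update_scenario(base, p = 0.66, epsilon = 0.7),
    "4" = sweep_spec(list(p = pg, epsilon = eg), base,
                     include_constant = TRUE),
    "5" = {
      out <- lapply(c(0.25, 0.5, 0.75), function(s) {
        sweep_spec(list(p = pg, epsilon = eg),
                   update_scenario(base, sigma = s),
                   include_constant = TRUE)
      })
      names(out) <- paste0("sigma=", c(0.25, 0.5, 0.75))
      out
    },
    "6" = sweep_spec(list(phi = c(0.25, 0.5, 1.0)), base),
    "7" = sweep_spec(list(phi = seq(0, 1, by = step), p = pg), base),
    "8" = {
      taus <- seq_len(tau_max)
      out <- lapply(c(0.33, 0.5, 0.75), function(pp) {
        sweep_spec(list(tau1 = taus, tau2 = taus),
                   update_scenario(base, p = pp))
      })
      names(out) <- paste0("p=", c(0.33, 0.5, 0.75))
      out
    },
    stop("unknown figure preset: ", figure, call. = FALSE)
  )
}

#' Iso-attack-rate trade-off curve between risk composition and reporting
#'
#' For each proportion of risk-takers `p` on the grid, finds the reporting
#' level `phi*` at which the adaptive attack rate equals the attack rate of
#' the reference scenario `(p0, phi0)`, by bisection on `phi` (attack rate
#' is non-increasing in `phi`). Points where no `phi` in `[0, 1]` attains
#' the reference value are returned with `phi_star = NA` and a boundary
#' marker.
#'
#' @param base Base `scenario`.
#' @param p0,phi0 Reference point (defaults: no risk-takers, no reporting).
#' @param p_grid Grid of `p` values to trace.
#' @param tol Absolute attack-rate tolerance for the bisection.
#' @return Data frame with columns `p`, `phi_star`, `attack_rate`,
#'   `boundary` (`""`, `"below"` or `"above"`).
#' @export
iso_attack_curve <- function(base = scenario_config(), p0 = 0, phi0 = 0,
                             p_grid = seq(0, 1, by = 0.1), tol = 1e-3) {
  ar_at <- function(p, phi) {
    attack_rate(simulate_adaptive(update_scenario(base, p = p, phi = phi)))
  }
  ref <- ar_at(p0, phi0)
  rows <- lapply(p_grid, function(p) {
    ar_lo <- ar_at(p, 1)   # strongest response -> lowest attack rate
    ar_hi <- ar_at(p, 0)   # no perception -> highest attack rate
    if (ref < ar_lo - tol) {
      return(data.frame(p = p, phi_star = NA_real_, attack_rate = ar_lo,
                        boundary = "above"))
    }
    if (ref > ar_hi + tol) {
      return(data.frame(p = p, phi_star = NA_real_, attack_rate = ar_hi,
                        boundary = "below"))
    }
    lo <- 0; hi <- 1
    ar_mid <- ar_hi; mid <- 0
    for (it in seq_len(20)) {
      mid <- (lo + hi) / 2
      ar_mid <- ar_at(p, mid)
      if (abs(ar_mid - ref) < tol) break
      if (ar_mid > ref) lo <- mid else hi <- mid
    }
    data.frame(p = p, phi_star = mid, attack_rate = ar_mid, boundary = "")
  })
  do.call(rbind, rows)
}

#' Planning horizons minimizing the attack rate
#'
#' Evaluates the adaptive attack rate over a grid of risk-taker and
#' risk-evader planning horizons and returns the minimizing pair. Ties are
#' broken toward smaller `tau1 + tau2`, then smaller `tau1`.
#'
#' @param base Base `scenario`.
#' @param tau1_grid,tau2_grid Integer grids of planning horizons.
#' @return List with `tau1_opt`, `tau2_opt`, `attack_rate_opt` and `grid`,
#'   a data frame with columns `tau1`, `tau2`, `attack_rate`.
#' @export
optimal_horizons <- function(base = scenario_config(),
                             tau1_grid = 1:30, tau2_grid = 1:30) {
  tau1_grid <- as.integer(tau1_grid); tau2_grid <- as.integer(tau2_grid)
  res <- run_sweep(sweep_spec(list(tau1 = tau1_grid, tau2 = tau2_grid),
                              base))
  grid <- data.frame(tau1 = res$tau1, tau2 = res$tau2,
                     attack_rate = res$attack_rate)
  ord <- order(grid$attack_rate, grid$tau1 + grid$tau2, grid$tau1)
  best <- grid[ord[1L], ]
  list(tau1_opt = best$tau1, tau2_opt = best$tau2,
       attack_rate_opt = best$attack_rate, grid = grid)
}

#' Write a sweep result to CSV
#'
#' Fixed column order: axis columns, then `attack_rate`, `attack_rate_rt`,
#' `attack_rate_re`, `attack_rate_constant`, `min_C_S1`, `min_C_S2`,
#' `peak_day`, `converged`.
#'
#' @param result A `sweep_result`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sweep <- function(result, path) {
  stopifnot(inherits(result, "sweep_result"))
  out <- result
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v) signif(v, 10))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
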