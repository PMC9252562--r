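COMPARTMENTS <- c("S1", "S2", "E1", "E2", "A1", "A2", "I", "R")
CONTACT_CLASSES <- c("C_S1", "C_S2", "C_E1", "C_E2", "C_A1", "C_A2",
                     "C_I", "C_R")

#' Epidemic state
#'
#' Population fractions in the eight health/risk compartments of the
#' two-risk-group SEIAR model: susceptible, exposed and asymptomatic classes
#' split by risk group (risk-takers carry subscript 1, risk-evaders 2), a
#' single shared symptomatic class `I` (symptomatic individuals behave
#' homogeneously) and a shared recovered class `R`.
#'
#' @param S1,S2,E1,E2,A1,A2,I,R Non-negative population fractions summing to
#'   1 (closed population).
#' @return A named numeric vector of class `epi_state`.
#' @examples
#' epidemic_state(S1 = 0.9, I = 0.1)
#' @export
epidemic_state <- function(S1 = 0, S2 = 0, E1 = 0, E2 = 0,
                           A1 = 0, A2 = 0, I = 0, R = 0) {
  x <- c(S1 = S1, S2 = S2, E1 = E1, E2 = E2, A1 = A1, A2 = A2, I = I, R = R)
  validate_state(x)
  structure(x, class = "epi_state")
}

validate_state <- function(x) {
  if (any(!is.finite(x)) || any(x < -1e-15)) {
    stop("compartment fractions must be finite and non-negative",
         call. = FALSE)
  }
  if (abs(sum(x) - 1) > 1e-12) {
    stop(sprintf("compartments must sum to 1 (got %.15g)", sum(x)),
         call. = FALSE)
  }
  invisible(x)
}

#' Initial epidemic state for a scenario
#'
#' Places a seed fraction `i0` in the exposed compartments and the remainder
#' in the susceptible compartments, split across risk groups. With
#' `seed_split = "proportional"` (the default) `E1(0) = p * i0` and
#' `E2(0) = (1 - p) * i0`, so the per-capita seed is identical in both
#' groups; a numeric `seed_split` gives the fraction of the seed assigned to
#' risk-takers.
#'
#' @param config A `scenario` from [scenario_config()].
#' @return An `epi_state`.
#' @export
initial_state <- function(config) {
  stopifnot(inherits(config, "scenario"))
  p <- config$behavior$p
  i0 <- config$i0
  share1 <- if (identical(config$seed_split, "proportional")) p
            else config$seed_split
  E1 <- i0 * share1
  E2 <- i0 * (1 - share1)
  if (E1 > p || E2 > 1 - p) {
    stop("seed_split places more seed in a group than its size", call. = FALSE)
  }
  epidemic_state(S1 = p - E1, S2 = (1 - p) - E2, E1 = E1, E2 = E2)
}

#' Daily contact-rate profile
#'
#' Realized contact rates (contacts/day) for the eight health/risk classes.
#'
#' @param C_S1,C_S2,C_E1,C_E2,C_A1,C_A2,C_I,C_R Contact rates, each in
#'   `[0, b]`.
#' @param b Maximum contacts/day used for range validation.
#' @return A named numeric vector of class `contact_profile`.
#' @examples
#' flat_contacts(24)        # everybody at the disease-free optimum for b = 48
#' @export
contact_profile <- function(C_S1, C_S2, C_E1, C_E2, C_A1, C_A2, C_I, C_R,
                            b = 48) {
  x <- c(C_S1 = C_S1, C_S2 = C_S2, C_E1 = C_E1, C_E2 = C_E2,
         C_A1 = C_A1, C_A2 = C_A2, C_I = C_I, C_R = C_R)
  if (any(!is.finite(x)) || any(x < 0) || any(x > b + 1e-9)) {
    stop("contact rates must lie in [0, b]", call. = FALSE)
  }
  structure(x, class = "contact_profile")
}

#' @rdname contact_profile
#' @param c Single contact rate applied to every class.
#' @export
flat_contacts <- function(c, b = max(48, 2 * c)) {
  contact_profile(c, c, c, c, c, c, c, c, b = b)
}

#' @export
print.epi_state <- function(x, ...) {
  cat("Epidemic state (population fractions)\n")
  print(round(unclass(x), 6))
  invisible(x)
}

#' @export
print.contact_profile <- function(x, ...) {
  cat("Contact profile (contacts/day)\n")
  print(round(unclass(x), 4))
  invisible(x)
}
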