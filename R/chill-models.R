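## Hourly dormancy/growth model kernels: Utah chill units, Dynamic-model chill
## portions, and growing degree hours after Richardson and after Anderson
## (ASYMCUR).  These are the per-hour primitives summed over seasonal windows
## by accumulate_season().

#' Utah model hourly chill units
#'
#' Piecewise-constant hourly weighting of temperature into chill units
#' (Richardson et al. 1974).  Band edges are resolved as closed on the right:
#' \itemize{
#'   \item T <= 1.4 C: 0
#'   \item 1.4 < T <= 2.4: +0.5
#'   \item 2.4 < T <= 9.1: +1.0
#'   \item 9.1 < T <= 12.4: +0.5
#'   \item 12.4 < T <= 15.9: 0
#'   \item 15.9 < T <= 18.0: -0.5
#'   \item T > 18.0: -1.0
#' }
#' Warm hours carry negative weight (chill negation).
#'
#' @param temp_c numeric vector of hourly temperatures in degrees Celsius.
#' @return numeric vector of chill units per hour.
#' @examples
#' utah_hour(c(-5, 2, 6, 10, 14, 17, 20))
#' @export
utah_hour <- function(temp_c) {
  stopifnot(is.numeric(temp_c))
  w <- numeric(length(temp_c))
  w[temp_c > 1.4 & temp_c <= 2.4] <- 0.5
  w[temp_c > 2.4 & temp_c <= 9.1] <- 1.0
  w[temp_c > 9.1 & temp_c <= 12.4] <- 0.5
  w[temp_c > 15.9 & temp_c <= 18.0] <- -0.5
  w[temp_c > 18.0] <- -1.0
  w[is.na(temp_c)] <- NA_real_
  w
}

#' Dynamic-model constants
#'
#' The canonical published parameter set of the two-step chill-portion
#' kinetics (Fishman et al. 1987; Erez et al. 1990), kept as a single
#' versioned table.  Temperatures enter the recursion in Kelvin
#' (K = C + 273.15 exactly).
#'
#' @return named list with elements `e0`, `e1` (activation energies),
#'   `a0`, `a1` (pre-exponential factors), `slp`, `tetmlt` (transfer
#'   sigmoid slope and transition temperature, K).
#' @export
dynamic_model_constants <- function() {
  list(e0 = 4153.5, e1 = 12888.8, a0 = 1.395e5, a1 = 2.567e18,
       slp = 1.6, tetmlt = 277)
}

#' Accumulate Dynamic-model chill portions over an hourly temperature series
#'
#' Runs the hourly two-step precursor recursion: a thermally labile
#' intermediate forms toward a temperature-dependent equilibrium and, once it
#' completes (level >= 1), a fraction `xi(T)` is banked irreversibly as chill
#' portions and the intermediate pool resets toward zero.  Banking is
#' deterministic (the convention of the standard dormancy toolkits); portions
#' never decrease.
#'
#' @param temp_c numeric vector of consecutive hourly temperatures (Celsius).
#' @param state optional starting state, a list with `intermediate` and
#'   `portions` (defaults to a fresh season: both 0).
#' @param cumulative if `TRUE`, also return the running portion total per hour.
#' @return list with `portions` (total), `intermediate` (final precursor
#'   level) and, if requested, `cumulative` (numeric vector).
#' @examples
#' dynamic_portions(rep(6, 1440))$portions   # ~ 1 portion per ~28 h near 6 C
#' @export
dynamic_portions <- function(temp_c, state = NULL, cumulative = FALSE) {
  stopifnot(is.numeric(temp_c))
  if (is.null(state)) state <- list(intermediate = 0, portions = 0)
  stop_if_not(state$intermediate >= 0 && state$portions >= 0,
              "invalid Dynamic-model state")
  if (length(temp_c) == 0L) {
    return(list(portions = state$portions,
                intermediate = state$intermediate,
                cumulative = numeric(0)))
  }
  if (anyNA(temp_c)) stop("missing temperatures in Dynamic-model input")
  k <- dynamic_model_constants()
  res <- dynamic_portions_cpp(temp_c + 273.15, k$e0, k$e1, k$a0, k$a1,
                              k$slp, k$tetmlt,
                              state$intermediate, state$portions, cumulative)
  if (!cumulative) res$cumulative <- NULL
  res
}

#' Single hourly update of the Dynamic-model state
#'
#' @param state list with `intermediate` (precursor level >= 0) and
#'   `portions` (accumulated chill portions >= 0).
#' @param temp_kelvin temperature of the hour in Kelvin; must lie in
#'   [233, 328] K (about -40 to 55 C).
#' @return updated state list.
#' @export
dynamic_step <- function(state, temp_kelvin) {
  stop_if_not(is.finite(temp_kelvin), "non-finite temperature")
  stop_if_not(temp_kelvin >= 233 && temp_kelvin <= 328,
              "temperature %.1f K outside the supported range [233, 328] K",
              temp_kelvin)
  res <- dynamic_portions(temp_kelvin - 273.15,
                          state = state, cumulative = FALSE)
  list(intermediate = res$intermediate, portions = res$portions)
}

#' Richardson growing degree hours for one hour
#'
#' Linear heat response above a base of 4.5 C with the response capped at
#' 25 C: `max(0, min(T, 25) - 4.5)`.
#'
#' @param temp_c numeric vector of hourly temperatures (Celsius).
#' @param base,cap base and cap temperatures (C).
#' @return GDH per hour.
#' @export
gdh_richardson_hour <- function(temp_c, base = 4.5, cap = 25) {
  pmax(0, pmin(temp_c, cap) - base)
}

#' Anderson (ASYMCUR) growing degree hours for one hour
#'
#' Asymmetric cosine response with cardinal temperatures: base 4 C, optimum
#' 25 C, critical 36 C; zero outside [base, critical]; maximum
#' `optimum - base` = 21 GDH at the optimum.  The stress factor is fixed at 1.
#'
#' @param temp_c numeric vector of hourly temperatures (Celsius).
#' @param base,optimum,critical cardinal temperatures (C).
#' @return GDH per hour.
#' @export
gdh_anderson_hour <- function(temp_c, base = 4, optimum = 25, critical = 36) {
  stopifnot(base < optimum, optimum < critical)
  g <- numeric(length(temp_c))
  rising <- !is.na(temp_c) & temp_c > base & temp_c <= optimum
  falling <- !is.na(temp_c) & temp_c > optimum & temp_c < critical
  half <- (optimum - base) / 2
  g[rising] <- half *
    (1 + cos(pi + pi * (temp_c[rising] - base) / (optimum - base)))
  g[falling] <- (optimum - base) *
    (1 + cos(pi / 2 + pi / 2 * (temp_c[falling] - optimum) /
               (critical - optimum)))
  g[is.na(temp_c)] <- NA_real_
  g
}
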