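#' Validity parameters of a breeding goal
#'
#' @param c_b expected share of the niche held by the breed (0-1).
#' @param N_min minimum population size for long-term survival (a breeding
#'   program should sustain an effective population size of at least 100,
#'   which informs this census figure).
#' @param a_ref reference adaptedness of competing breeds (merit units).
#' @param kappa sensitivity of the population growth rate to the
#'   adaptedness surplus (per merit unit, >= 0).
#' @return An object of class `validity_params`.
#' @export
validity_params <- function(c_b, N_min, a_ref = 0, kappa = 0) {
  if (c_b < 0 || c_b > 1) stop_ng("c_b must be in [0, 1]")
  if (N_min < 0) stop_ng("N_min must be >= 0")
  if (kappa < 0) stop_ng("kappa must be >= 0")
  structure(list(c_b = as.numeric(c_b), N_min = as.numeric(N_min),
                 a_ref = as.numeric(a_ref), kappa = as.numeric(kappa)),
            class = "validity_params")
}

#' Check the long-term validity condition of an envisaged niche
#'
#' The breed's expected share of the projected niche must stay at or above
#' the minimum viable population size: `c_b * m_t >= N_min`.
#'
#' @param validity a [validity_params].
#' @param niche a [breed_niche].
#' @param t horizon in years.
#' @return list with `valid` (logical) and `margin`
#'   (`c_b * m_t - N_min`, signed).
#' @export
check_validity <- function(validity, niche, t) {
  margin <- validity$c_b * project_niche_size(niche, t) - validity$N_min
  list(valid = margin >= 0, margin = margin)
}

#' Simulate the breeding program under a selection index
#'
#' Deterministic expectation-level recursion of the trait means,
#' `mu_{t+1} = mu_t + i G b / sqrt(b' P b)` (constant G, P), with the
#' adaptedness, the genetic variance of the index, and a population-size
#' dynamic recomputed each generation. The population grows or shrinks with
#' the adaptedness surplus over competitors,
#' `n_{t+1} = n_t exp(kappa (a_t - a_ref))`, capped by the breed's share of
#' the projected niche `c_b * m_t`. The per-generation validity flag
#' requires both the niche share and the current population to reach N_min.
#'
#' @param state a [breed_state].
#' @param b named K-vector of index weights.
#' @param intensity selection intensity i per generation.
#' @param T number of generations (>= 1).
#' @param niche a [breed_niche].
#' @param params a [merit_params] or named list per subniche (passed to
#'   [adaptedness_niche()]).
#' @param validity a [validity_params].
#' @param n0 starting population size (> 0).
#' @param seed integer seed (used only by the Monte-Carlo adaptedness path).
#' @param gen_interval years per generation (for projecting the niche size).
#' @param method adaptedness method, `"closed_form"` (default) or
#'   `"monte_carlo"`.
#' @param n_env,n_pheno Monte-Carlo sizes for [adaptedness_niche()].
#' @return A `breeding_trajectory`: data.frame with one row per generation
#'   (0..T): trait means, adaptedness value and SE, population size, index
#'   genetic variance, validity flag.
#' @export
simulate_breeding_program <- function(state, b, intensity, T, niche, params,
                                      validity, n0, seed = 1L,
                                      gen_interval = 1,
                                      method = "closed_form",
                                      n_env = 100L, n_pheno = 5000L) {
  if (T < 1) stop_ng("T must be >= 1")
  if (n0 <= 0) stop_ng("n0 must be > 0")
  gain <- expected_response(state$genetics, b, intensity)
  ivar <- index_variance_check(state$genetics, b)$variance
  K <- length(state$mu_c)
  mu <- state$mu_c
  n_pop <- as.numeric(n0)
  rows <- vector("list", T + 1L)
  for (g in 0:T) {
    years <- g * gen_interval
    est <- adaptedness_niche(state, niche, params, method = method,
                             n_env = n_env, n_pheno = n_pheno,
                             seed = derive_seed(seed, paste0("gen", g)),
                             mu = mu)
    cap <- validity$c_b * project_niche_size(niche, years)
    n_pop <- min(n_pop, cap)
    valid <- (cap >= validity$N_min) && (n_pop >= validity$N_min)
    rows[[g + 1L]] <- c(generation = g, mu,
                        adaptedness = est$value, se = est$se,
                        pop_size = n_pop, index_var = ivar,
                        valid = as.numeric(valid))
    if (g < T) {
      mu <- mu + gain
      n_pop <- n_pop * exp(validity$kappa * (est$value - validity$a_ref))
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("generation", names(state$mu_c), "adaptedness", "se",
                  "pop_size", "index_var", "valid")
  out$valid <- out$valid > 0
  class(out) <- c("breeding_trajectory", "data.frame")
  out
}
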