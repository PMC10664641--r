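#' Scenario container
#'
#' A fully specified toy study: trait space and breed state, niche, the true
#' merit parameters per subniche, validity parameters and optimization
#' settings. Scenarios make every pipeline stage testable end-to-end without
#' external data.
#'
#' @param name scenario name.
#' @param state a [breed_state].
#' @param niche a [breed_niche].
#' @param merit named list of [merit_params], one entry per subniche label.
#' @param validity a [validity_params].
#' @param optimization list with `intensity`, `generations`, `gen_interval`,
#'   `horizon_years`, `search_k`, `exclusions`.
#' @param seed integer seed propagated to downstream runs.
#' @return An object of class `scenario` (validated).
#' @export
scenario <- function(name, state, niche, merit, validity, optimization, seed = 1L) {
  stopifnot(inherits(state, "breed_state"), inherits(niche, "breed_niche"),
            inherits(validity, "validity_params"))
  missing_m <- setdiff(names(niche$subniches), names(merit))
  if (length(missing_m)) {
    stop_ng("merit parameters missing for subniche(s): ",
            paste(missing_m, collapse = ", "))
  }
  for (m in merit) {
    if (!inherits(m, "merit_params")) stop_ng("merit entries must be merit_params")
    validate_merit_traits(m, state$trait_space)
  }
  opt_defaults <- list(intensity = 1, generations = 5L, gen_interval = 1,
                       horizon_years = 20, search_k = 2, exclusions = list())
  optimization <- utils::modifyList(opt_defaults, optimization)
  structure(list(name = name, state = state, niche = niche, merit = merit,
                 validity = validity, optimization = optimization,
                 seed = as.integer(seed)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario>", x$name, "- K =", length(x$state$mu_c), "traits,",
      length(x$niche$subniches), "subniche(s), seed", x$seed, "\n")
  invisible(x)
}

# default tau_max: sum of omega * 2 phenotypic SD, so the reward merit stays
# positive over the default two-SD search box
default_tau_max <- function(omega, P) {
  if (length(omega) == 0L) return(0)
  sum(omega * 2 * sqrt(diag(P)[names(omega)]))
}

#' Companion-dog scenario
#'
#' A toy breed kept purely for companionship: six traits (cuteness score,
#' barking frequency, trainability, longevity, health score, body size) and
#' two atom subniches -- apartment owners with noise-sensitive neighbours
#' (low optimal barking, strong perceived barking cost) and house-with-garden
#' owners (tolerant of barking). The owners are themselves the "consumers":
#' there is no product, profit coefficients are zero, lambda = 1, the weight
#' on the producer's merit is small and the bulk of the adaptedness weight
#' sits on the merit of the animal for its owner. A health-score floor
#' excludes welfare-incompatible goals.
#'
#' @param seed integer seed stored in the scenario.
#' @return A [scenario].
#' @export
make_companion_dog_scenario <- function(seed = 1L) {
  ts <- trait_space(data.frame(
    label = c("cuteness", "barking_frequency", "trainability",
              "longevity", "health_score", "body_size"),
    category = c("supplemental", "behaviour", "performance",
                 "functional", "functional", "conformation_movement"),
    unit = c("score", "bouts/day", "score", "years", "score", "kg")))
  labs <- ts$label
  sds <- c(1.5, 2.0, 1.5, 1.5, 1.2, 4.0)
  h2 <- c(0.35, 0.30, 0.25, 0.15, 0.20, 0.50)
  Pcor <- diag(6)
  Pcor[4, 5] <- Pcor[5, 4] <- 0.30   # longevity ~ health
  Pcor[1, 6] <- Pcor[6, 1] <- -0.15  # cuteness ~ body size
  P <- diag(sds) %*% Pcor %*% diag(sds)
  Gcor <- diag(6)
  Gcor[4, 5] <- Gcor[5, 4] <- 0.50
  Gcor[1, 6] <- Gcor[6, 1] <- -0.20
  gsd <- sds * sqrt(h2)
  G <- diag(gsd) %*% Gcor %*% diag(gsd)
  dimnames(G) <- dimnames(P) <- list(labs, labs)
  gen <- genetic_parameters(G, P)
  mu_c <- stats::setNames(c(5, 5, 5, 11, 5, 20), labs)
  st <- breed_state(ts, mu_c, gen)

  mk_env <- function(noise_sensitive) {
    owner_environment(
      desire_profile(emotional = c(companionship = 1),
                     easygoing = c(low_disturbance = if (noise_sensitive) 1 else 0.2)),
      influencing_variables(
        owner = c(noise_sensitive_neighbours = as.numeric(noise_sensitive)),
        physical = c(garden = as.numeric(!noise_sensitive))))
  }
  e_apartment <- mk_env(TRUE)
  e_garden <- mk_env(FALSE)

  mk_params <- function(opt_bark, omega_bark, cost_bark) {
    perf_omega <- c(trainability = 0.6, barking_frequency = omega_bark)
    emo_omega <- c(cuteness = 0.8)
    alt_omega <- c(body_size = 0.2)
    merit_params(
      performance = list(omega = perf_omega,
                         opt = c(trainability = 7, barking_frequency = opt_bark),
                         tau_max = default_tau_max(perf_omega, P)),
      emotional = list(omega = emo_omega, opt = c(cuteness = 8),
                       tau_max = default_tau_max(emo_omega, P)),
      altruistic = list(breed_id = "toy_spaniel", omega = alt_omega,
                        opt = c(body_size = 20),
                        tau_max = default_tau_max(alt_omega, P)),
      easygoing = list(omega = c(barking_frequency = cost_bark),
                       omega_mon = c(barking_frequency = 0)),
      weights = list(lambda = 1, w = c(1, 1, 0.5), alpha = c(0.1, 0.9, 0)),
      traits = ts)
  }
  niche <- breed_niche(
    list(subniche("apartment", size = 60000, growth_rate = 0.01,
                  atoms = list(list(environment = e_apartment, prob = 1))),
         subniche("garden", size = 40000, growth_rate = -0.005,
                  atoms = list(list(environment = e_garden, prob = 1)))),
    producer_env = e_garden)
  merit <- list(apartment = mk_params(opt_bark = 2, omega_bark = 1.0, cost_bark = 0.4),
                garden = mk_params(opt_bark = 5, omega_bark = 0.3, cost_bark = 0.1))
  scenario(
    name = "companion_dog", state = st, niche = niche, merit = merit,
    validity = validity_params(c_b = 0.05, N_min = 1000, a_ref = 2, kappa = 0.02),
    optimization = list(intensity = 1, generations = 5L, gen_interval = 4,
                        horizon_years = 20, search_k = 2,
                        exclusions = list(exclusion_halfspace(
                          "health_floor", c(health_score = 1), 4.5))),
    seed = seed)
}

#' Dairy-cattle scenario
#'
#' A commercial dairy breed kept mainly for profit: five traits (milk yield,
#' longevity, udder score, temperament, stature), one Gaussian subniche over
#' the milk price and the feed quality, a linear profit equation whose milk
#' coefficient is the milk price, a reaction norm of milk yield on feed
#' quality, and a small lambda (producers weight perceived rewards close to,
#' but not exactly, zero).
#'
#' @param seed integer seed stored in the scenario.
#' @return A [scenario].
#' @export
make_dairy_scenario <- function(seed = 1L) {
  ts <- trait_space(data.frame(
    label = c("milk_yield", "longevity", "udder_score", "temperament", "stature"),
    category = c("production", "functional", "conformation_movement",
                 "behaviour", "conformation_movement"),
    unit = c("kg/yr", "years", "score", "score", "cm")))
  labs <- ts$label
  sds <- c(900, 1.2, 1.5, 1.8, 5)
  h2 <- c(0.30, 0.10, 0.25, 0.15, 0.45)
  Pcor <- diag(5)
  Pcor[1, 2] <- Pcor[2, 1] <- -0.10  # yield ~ longevity
  Pcor[1, 5] <- Pcor[5, 1] <- 0.20   # yield ~ stature
  P <- diag(sds) %*% Pcor %*% diag(sds)
  Gcor <- diag(5)
  Gcor[1, 2] <- Gcor[2, 1] <- -0.30
  Gcor[1, 5] <- Gcor[5, 1] <- 0.25
  gsd <- sds * sqrt(h2)
  G <- diag(gsd) %*% Gcor %*% diag(gsd)
  dimnames(G) <- dimnames(P) <- list(labs, labs)
  gen <- genetic_parameters(G, P)
  mu_c <- stats::setNames(c(8000, 5, 5, 5, 145), labs)
  rn <- matrix(0, 5, 1, dimnames = list(labs, "feed_quality"))
  rn["milk_yield", "feed_quality"] <- 250  # kg per feed-quality unit
  st <- breed_state(ts, mu_c, gen, reaction_norm = rn)

  base_env <- owner_environment(
    desire_profile(profit = c(income = 1), easygoing = c(low_workload = 0.5)),
    influencing_variables(market = c(milk_price = 0.35),
                          physical = c(feed_quality = 0)))
  producer_env <- owner_environment(
    base_env$desire,
    influencing_variables(market = c(milk_price = 0.35),
                          physical = c(feed_quality = 0.5)))

  perf_omega <- c(temperament = 20)
  params <- merit_params(
    profit = list(fixed = -1500,
                  base = c(longevity = 120, temperament = 8),
                  mult = list(milk_yield = c(milk_price = 1))),
    quality = list(q0 = 0, q = c(udder_score = 2, milk_yield = 0.001)),
    performance = list(omega = perf_omega, opt = c(temperament = 6),
                       tau_max = default_tau_max(perf_omega, P)),
    easygoing = list(omega = c(stature = 5), omega_mon = c(stature = 0)),
    weights = list(lambda = 0.05, w = c(1, 0, 0), alpha = c(0, 0.9, 0.1)),
    traits = ts)

  niche <- breed_niche(
    list(subniche("commercial_farms", size = 200000, growth_rate = -0.01,
                  gaussian = list(
                    base = base_env,
                    mean = c(milk_price = 0.35, feed_quality = 0),
                    cov = diag(c(0.05^2, 1))))),
    producer_env = producer_env)
  scenario(
    name = "dairy", state = st, niche = niche,
    merit = list(commercial_farms = params),
    validity = validity_params(c_b = 0.3, N_min = 5000, a_ref = 1200,
                               kappa = 1e-4),
    optimization = list(intensity = 1, generations = 4L, gen_interval = 5,
                        horizon_years = 20, search_k = 2, exclusions = list()),
    seed = seed)
}

#' Two-environment body-weight scenario
#'
#' A one-trait illustration of environment-dependent optima: two atom
#' environments prefer opposite body weights (a small animal where feed is
#' scarce, a large one where feed is rich), a reaction norm shifts the
#' realized weight with feed quality, and the niche-averaged optimum is a
#' compromise between the two preferred weights.
#'
#' @param seed integer seed stored in the scenario.
#' @param size1,size2 subniche sizes (owner places) for the two environments.
#' @return A [scenario].
#' @export
make_two_env_bodyweight_scenario <- function(seed = 1L, size1 = 500, size2 = 500) {
  ts <- trait_space(data.frame(label = "body_weight",
                               category = "conformation_movement", unit = "kg"))
  P <- matrix(16, 1, 1, dimnames = list("body_weight", "body_weight"))
  G <- matrix(6.4, 1, 1, dimnames = list("body_weight", "body_weight"))
  gen <- genetic_parameters(G, P)
  rn <- matrix(2, 1, 1, dimnames = list("body_weight", "feed_quality"))
  st <- breed_state(ts, c(body_weight = 27), gen, reaction_norm = rn)

  mk_env <- function(feed) owner_environment(
    desire_profile(performance = c(working_use = 1)),
    influencing_variables(physical = c(feed_quality = feed)))
  e1 <- mk_env(-1)
  e2 <- mk_env(1)
  mk_params <- function(opt) merit_params(
    performance = list(omega = c(body_weight = 1), opt = c(body_weight = opt),
                       tau_max = default_tau_max(c(body_weight = 1), P)),
    weights = list(lambda = 1, w = c(1, 0, 0), alpha = c(0, 1, 0)),
    traits = ts)
  niche <- breed_niche(
    list(subniche("lean_environment", size = size1, growth_rate = 0,
                  atoms = list(list(environment = e1, prob = 1))),
         subniche("rich_environment", size = size2, growth_rate = 0,
                  atoms = list(list(environment = e2, prob = 1)))),
    producer_env = e1)
  scenario(
    name = "two_env_bodyweight", state = st, niche = niche,
    merit = list(lean_environment = mk_params(24),
                 rich_environment = mk_params(36)),
    validity = validity_params(c_b = 0.5, N_min = 100, a_ref = 5, kappa = 0.01),
    optimization = list(intensity = 1, generations = 4L, gen_interval = 1,
                        horizon_years = 8, search_k = 2, exclusions = list()),
    seed = seed)
}

#' Build the permissible set of a scenario
#'
#' Convenience: search area (scenario box half-width and exclusions) and
#' response area (scenario intensity and generations) with the genetic
#' parameters attached.
#'
#' @param scn a [scenario].
#' @return A [permissible_set].
#' @export
scenario_permissible_set <- function(scn) {
  sa <- search_area(scn$state, k = scn$optimization$search_k,
                    exclusions = scn$optimization$exclusions)
  ra <- build_response_area(scn$state$genetics, scn$state$mu_c,
                            scn$optimization$intensity,
                            scn$optimization$generations)
  permissible_set_with_genetics(permissible_set(sa, ra), scn$state$genetics)
}

#' Closed-form adaptedness objective of a scenario
#'
#' Returns a deterministic function of a putative goal mu: the size-weighted
#' average of the closed-form environment adaptedness over the niche. Atom
#' subniches contribute their exact atom average; for Gaussian subniches a
#' fixed environment sample of size `n_env` is drawn once (seeded), so the
#' objective is smooth in mu and identical across optimizer calls.
#'
#' @param scn a [scenario].
#' @param n_env environments per Gaussian subniche.
#' @param seed integer seed for the environment sample.
#' @return function(mu) -> scalar adaptedness estimate.
#' @export
scenario_objective <- function(scn, n_env = 100L, seed = NULL) {
  seed <- seed %||% scn$seed
  w <- niche_weights(scn$niche)
  evals <- list()
  weights <- numeric(0)
  for (u in seq_along(scn$niche$subniches)) {
    sub <- scn$niche$subniches[[u]]
    params <- scn$merit[[sub$label]]
    if (sub$distribution$type == "atoms") {
      envs <- lapply(sub$distribution$atoms, `[[`, "environment")
      probs <- vapply(sub$distribution$atoms, `[[`, numeric(1), "prob")
    } else {
      sn <- breed_niche(list(sub), scn$niche$producer_env)
      # same substream label as adaptedness_niche, so the fixed environment
      # sample agrees with the reporting path at equal n_env
      envs <- sample_environments(sn, n_env, derive_seed(seed, paste0("envs", u)))
      probs <- rep(1 / length(envs), length(envs))
    }
    for (i in seq_along(envs)) {
      evals[[length(evals) + 1L]] <-
        compile_adaptedness_env(scn$state, envs[[i]], scn$niche, params)
      weights <- c(weights, w[u] * probs[i])
    }
  }
  function(mu) {
    tot <- 0
    for (i in seq_along(evals)) tot <- tot + weights[i] * evals[[i]](mu)
    tot
  }
}

#' Run the full optimization pipeline of a scenario
#'
#' Maximizes the closed-form niche adaptedness over the scenario's
#' permissible set and derives the desired-gain index.
#'
#' @param scn a [scenario].
#' @param n_starts,seed,tol passed to [optimize_goal()] (seed defaults to
#'   the scenario seed).
#' @param n_env environments per Gaussian subniche in the objective.
#' @return A `goal_result`.
#' @export
optimize_scenario_goal <- function(scn, n_starts = 4L, seed = NULL, tol = 1e-6,
                                   n_env = 100L) {
  seed <- seed %||% scn$seed
  uset <- scenario_permissible_set(scn)
  obj <- scenario_objective(scn, n_env = n_env, seed = seed)
  optimize_goal(obj, uset, n_starts = n_starts, seed = seed, tol = tol)
}
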