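# Shared fixture builders; everything is generated in code at test time.

fx_traits <- function(K, category = "performance") {
  trait_space(data.frame(label = paste0("t", seq_len(K)),
                         category = category, unit = "u"))
}

# random genetic parameters with heritabilities in (0.2, 0.6) so that
# diag(G) < diag(P) always holds and both matrices are positive definite
fx_genetics <- function(K, seed = 1) {
  set.seed(seed)
  labs <- paste0("t", seq_len(K))
  A <- matrix(rnorm(K * K), K)
  P <- crossprod(A) + diag(K) * K * 0.5
  W <- crossprod(matrix(rnorm(K * K), K)) + diag(K) * 0.1
  C <- stats::cov2cor(W)
  h2 <- runif(K, 0.2, 0.6)
  gsd <- sqrt(h2 * diag(P))
  G <- diag(gsd, nrow = K) %*% C %*% diag(gsd, nrow = K)
  dimnames(G) <- dimnames(P) <- list(labs, labs)
  genetic_parameters(G, P)
}

fx_env <- function(feed = 0, price = 1) {
  owner_environment(
    desire_profile(performance = c(use = 1)),
    influencing_variables(physical = c(feed_quality = feed),
                          market = c(price = price)))
}

fx_state <- function(K = 2, seed = 1, reaction_norm = NULL) {
  gen <- fx_genetics(K, seed)
  set.seed(seed + 1000)
  mu <- stats::setNames(rnorm(K), rownames(gen$G))
  breed_state(fx_traits(K), mu, gen, reaction_norm = reaction_norm)
}

fx_atom_niche <- function(envs = list(fx_env()), sizes = 100,
                          probs = NULL, producer = NULL) {
  if (length(sizes) == 1L && length(envs) > 1L) {
    subs <- list(subniche("s1", sizes, 0, atoms = lapply(seq_along(envs), function(i)
      list(environment = envs[[i]],
           prob = (probs %||% rep(1 / length(envs), length(envs)))[i]))))
  } else {
    subs <- lapply(seq_along(envs), function(i)
      subniche(paste0("s", i), sizes[i], 0,
               atoms = list(list(environment = envs[[i]], prob = 1))))
  }
  breed_niche(subs, producer %||% envs[[1]])
}

# merit params over the fixture traits: reward merit on t1 (and optionally
# more), linear profit on the last trait
fx_params <- function(K = 2, omega = c(t1 = 1.5), opt = c(t1 = 0.7),
                      tau_max = 10, lambda = 1, alpha = c(0, 1, 0),
                      profit_base = NULL, quality = list()) {
  merit_params(
    profit = if (is.null(profit_base)) list() else list(base = profit_base),
    quality = quality,
    performance = list(omega = omega, opt = opt, tau_max = tau_max),
    weights = list(lambda = lambda, w = c(1, 0, 0), alpha = alpha),
    traits = fx_traits(K))
}

# a complete single-atom-niche problem for optimizer/adaptedness tests
fx_problem <- function(K = 2, seed = 1, lambda = 1, alpha = c(0, 1, 0),
                       omega = NULL, opt = NULL, profit_base = NULL,
                       intensity = 1, generations = 3, search_k = 50) {
  st <- fx_state(K, seed)
  labs <- names(st$mu_c)
  if (is.null(omega)) {
    omega <- stats::setNames(runif(K, 0.5, 2), labs)
    opt <- st$mu_c + stats::setNames(rnorm(K), labs)
  }
  params <- merit_params(
    profit = if (is.null(profit_base)) list() else list(base = profit_base),
    performance = list(omega = omega, opt = opt,
                       tau_max = sum(omega) * 10),
    weights = list(lambda = lambda, w = c(1, 0, 0), alpha = alpha),
    traits = st$trait_space)
  e <- fx_env()
  niche <- fx_atom_niche(list(e), sizes = 100)
  sa <- search_area(st, k = search_k)
  ra <- build_response_area(st$genetics, st$mu_c, intensity, generations)
  uset <- permissible_set_with_genetics(permissible_set(sa, ra), st$genetics)
  list(state = st, e = e, niche = niche, params = params, set = uset,
       response = ra)
}
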