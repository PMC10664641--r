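#' Expected absolute deviation of a Gaussian variable
#'
#' For Y ~ Normal(m, s^2), computes E|Y - c| in closed form (folded-normal
#' mean of Y - c): with delta = m - c,
#' `s * sqrt(2/pi) * exp(-delta^2 / (2 s^2)) + delta * (2 pnorm(delta/s) - 1)`.
#' This is the kernel from which the expected reward merits are assembled
#' under Gaussian phenotypes. For s = 0 it degenerates to |m - c|.
#'
#' @param m mean (vectorized).
#' @param s standard deviation, >= 0 (vectorized).
#' @param c reference point (vectorized).
#' @return E|Y - c| (>= |m - c|, with equality iff s = 0).
#' @examples
#' expected_abs_dev(0, 1, 0)  # sqrt(2/pi)
#' @export
expected_abs_dev <- function(m, s, c) {
  if (any(s < 0)) stop_ng("s must be >= 0")
  delta <- m - c
  out <- abs(delta)
  pos <- s > 0
  if (any(pos)) {
    d <- delta[pos]
    sp <- s[pos]
    out[pos] <- sp * sqrt(2 / pi) * exp(-d^2 / (2 * sp^2)) +
      d * (2 * stats::pnorm(d / sp) - 1)
  }
  out
}

# Precompiled closed-form adaptedness in one environment, as a function of a
# putative goal mu: all linear coefficients and folded-normal terms are
# assembled once, so repeated evaluation inside the optimizer is cheap.
# Mirrors adaptedness_env(method = "closed_form") exactly.
compile_adaptedness_env <- function(state, e, niche, params) {
  labs <- names(state$mu_c)
  K <- length(labs)
  sd_all <- sqrt(diag(state$genetics$P))
  shift_for <- function(env) {
    rn <- state$reaction_norm
    if (is.null(rn)) stats::setNames(numeric(K), labs)
    else drop(rn %*% iv_get(env$influencing, colnames(rn), "reaction-norm variable"))
  }
  piece <- function(env, weight_tm, weight_pq) {
    # contribution weight_tm * E TM_env(y) + weight_pq * E PQ(y),
    # y ~ N(mu + shift, P)
    sh <- shift_for(env)
    cc <- profit_coefficients(params, env$influencing, labs)
    lin <- weight_tm * cc
    const <- weight_tm * profit_fixed_term(params, env$influencing) +
      weight_tm * sum(cc * sh)
    lam <- params$weights$lambda
    fold_w <- numeric(0); fold_opt <- numeric(0); fold_sd <- numeric(0)
    fold_idx <- integer(0); fold_sh <- numeric(0)
    if (lam > 0) {
      w <- params$weights$w
      comps <- list(params$performance, params$emotional, params$altruistic)
      for (i in 1:3) {
        comp <- comps[[i]]
        if (w[i] == 0) next
        const <- const + weight_tm * lam * w[i] * comp$tau_max
        if (length(comp$omega)) {
          fold_w <- c(fold_w, weight_tm * lam * w[i] * comp$omega)
          fold_opt <- c(fold_opt, comp$opt)
          fold_sd <- c(fold_sd, sd_all[names(comp$omega)])
          fold_idx <- c(fold_idx, match(names(comp$omega), labs))
          fold_sh <- c(fold_sh, sh[names(comp$omega)])
        }
      }
      eg <- params$easygoing
      if (length(eg$omega)) {
        d <- eg$omega - eg$omega_mon
        keep <- d > 0
        if (any(keep)) {
          dk <- stats::setNames(numeric(K), labs)
          dk[names(d)[keep]] <- d[keep]
          lin <- lin - weight_tm * lam * dk
          const <- const - weight_tm * lam * sum(dk * sh)
        }
      }
    }
    if (weight_pq != 0) {
      q <- params$quality
      const <- const + weight_pq * q$q0
      if (length(q$q)) {
        qk <- stats::setNames(numeric(K), labs)
        qk[names(q$q)] <- q$q
        lin <- lin + weight_pq * qk
        const <- const + weight_pq * sum(qk * sh)
      }
    }
    list(const = const, lin = unname(lin), fold_w = fold_w,
         fold_opt = unname(fold_opt), fold_sd = unname(fold_sd),
         fold_idx = fold_idx, fold_sh = unname(fold_sh))
  }
  a <- params$weights$alpha
  pieces <- list(piece(e, a[["n"]], a[["c"]]))
  if (a[["p"]] > 0) {
    pieces[[2]] <- piece(niche$producer_env, a[["p"]], 0)
  }
  function(mu) {
    mu <- unname(mu[labs])
    val <- 0
    for (pc in pieces) {
      val <- val + pc$const + sum(pc$lin * mu)
      if (length(pc$fold_w)) {
        val <- val - sum(pc$fold_w *
                           expected_abs_dev(mu[pc$fold_idx] + pc$fold_sh,
                                            pc$fold_sd, pc$fold_opt))
      }
    }
    unname(val)
  }
}

adaptedness_estimate <- function(value, se, method, n) {
  structure(list(value = value, se = se, method = method, n = n),
            class = "adaptedness_estimate")
}

#' @export
print.adaptedness_estimate <- function(x, ...) {
  cat(sprintf("<adaptedness> %.6g (SE %.3g, %s, n = %d)\n",
              x$value, x$se, x$method, as.integer(x$n)))
  invisible(x)
}

# closed-form E TM_e(y) for y ~ N(mu, P): linear parts pass through the
# expectation, |y - Opt| terms become folded-normal expectations on the
# trait marginals.
expected_total_merit <- function(mu, e, params, P) {
  sd_all <- sqrt(diag(P))
  prof <- profit_merit(mu, e$influencing, params)
  lam <- params$weights$lambda
  if (lam == 0) return(prof)
  w <- params$weights$w
  rew <- 0
  comps <- list(params$performance, params$emotional, params$altruistic)
  for (i in 1:3) {
    comp <- comps[[i]]
    if (w[i] == 0) next
    if (length(comp$omega) == 0L) {
      rew <- rew + w[i] * comp$tau_max
    } else {
      ead <- expected_abs_dev(mu[names(comp$omega)], sd_all[names(comp$omega)], comp$opt)
      rew <- rew + w[i] * (comp$tau_max - sum(comp$omega * ead))
    }
  }
  prof + lam * (rew - easygoing_cost(mu, params))
}

#' Adaptedness of a breed to one environment
#'
#' The expected satisfaction generated by a randomly chosen animal:
#' `alpha_p E TM_ep(y') + alpha_n E TM_e(y) + alpha_c E PQ(y)`, where y is
#' the phenotype of an animal kept in environment e and y' that of an animal
#' kept in the producer's environment. Under Gaussian phenotypes with linear
#' profit/quality the expectation is available in closed form (the absolute
#' deviations around the merit optima become folded-normal expectations);
#' alternatively it is estimated by Monte Carlo with a standard error.
#'
#' @param state a [breed_state].
#' @param e the owner [owner_environment].
#' @param niche a [breed_niche] (supplies the producer environment).
#' @param params a [merit_params].
#' @param method `"closed_form"` or `"monte_carlo"`.
#' @param n Monte-Carlo sample size (ignored for closed form).
#' @param seed integer seed for the Monte-Carlo path.
#' @param mu optional named K-vector: evaluate a putative breeding goal
#'   instead of the stored current means.
#' @return An `adaptedness_estimate` (value, SE, method, n).
#' @export
adaptedness_env <- function(state, e, niche, params,
                            method = c("closed_form", "monte_carlo"),
                            n = 10000L, seed = 1L, mu = NULL) {
  method <- match.arg(method)
  a <- params$weights$alpha
  e_p <- niche$producer_env
  if (method == "closed_form") {
    mu_e <- mean_in_environment(state, e, mu = mu)
    val <- a[["n"]] * expected_total_merit(mu_e, e, params, state$genetics$P) +
      a[["c"]] * product_quality(mu_e, params)
    if (a[["p"]] > 0) {
      mu_p <- mean_in_environment(state, e_p, mu = mu)
      val <- val + a[["p"]] * expected_total_merit(mu_p, e_p, params, state$genetics$P)
    }
    return(adaptedness_estimate(unname(val), 0, "closed_form", 0L))
  }
  if (n < 2) stop_ng("monte_carlo requires n >= 2")
  Y <- sample_phenotypes(state, e, n, derive_seed(seed, "mc_owner"), mu = mu)
  per <- a[["n"]] * total_merit_rows(Y, e, params) +
    a[["c"]] * product_quality_rows(Y, params)
  if (a[["p"]] > 0) {
    Yp <- sample_phenotypes(state, e_p, n, derive_seed(seed, "mc_producer"), mu = mu)
    per <- per + a[["p"]] * total_merit_rows(Yp, e_p, params)
  }
  adaptedness_estimate(mean(per), stats::sd(per) / sqrt(n), "monte_carlo", as.integer(n))
}

#' Adaptedness of a breed to its envisaged niche
#'
#' Averages [adaptedness_env()] over the niche's environment distribution:
#' subniches are weighted by their sizes; within an atom subniche the
#' average over atoms is exact, within a Gaussian subniche it is a Monte
#' Carlo average over sampled environments (with a standard error).
#'
#' @param state a [breed_state].
#' @param niche a [breed_niche].
#' @param params_by_subniche either a single [merit_params] used for every
#'   subniche, or a named list mapping each subniche label to its own
#'   [merit_params].
#' @param method phenotype expectation: `"closed_form"` or `"monte_carlo"`.
#' @param n_env environments sampled per Gaussian subniche.
#' @param n_pheno Monte-Carlo phenotype sample size per environment.
#' @param seed integer seed.
#' @param mu optional putative breeding goal (named K-vector).
#' @return An `adaptedness_estimate`.
#' @export
adaptedness_niche <- function(state, niche, params_by_subniche,
                              method = c("closed_form", "monte_carlo"),
                              n_env = 200L, n_pheno = 10000L, seed = 1L,
                              mu = NULL) {
  method <- match.arg(method)
  if (inherits(params_by_subniche, "merit_params")) {
    params_by_subniche <- stats::setNames(
      rep(list(params_by_subniche), length(niche$subniches)),
      names(niche$subniches))
  }
  unbound <- setdiff(names(niche$subniches), names(params_by_subniche))
  if (length(unbound)) {
    stop_ng("no merit parameters bound for subniche(s): ",
            paste(unbound, collapse = ", "))
  }
  w <- niche_weights(niche)
  vals <- numeric(length(w))
  vars <- numeric(length(w))
  n_tot <- 0L
  for (u in seq_along(niche$subniches)) {
    sub <- niche$subniches[[u]]
    pu <- params_by_subniche[[sub$label]]
    if (sub$distribution$type == "atoms") {
      atoms <- sub$distribution$atoms
      av <- 0
      avar <- 0
      for (i in seq_along(atoms)) {
        est <- adaptedness_env(state, atoms[[i]]$environment, niche, pu,
                               method = method, n = n_pheno,
                               seed = derive_seed(seed, paste0("sub", u, "atom", i)),
                               mu = mu)
        av <- av + atoms[[i]]$prob * est$value
        avar <- avar + (atoms[[i]]$prob * est$se)^2
        n_tot <- n_tot + est$n
      }
      vals[u] <- av
      vars[u] <- avar
    } else {
      sub_niche <- breed_niche(list(sub), niche$producer_env)
      envs <- sample_environments(sub_niche, n_env,
                                  derive_seed(seed, paste0("envs", u)))
      per <- vapply(seq_along(envs), function(i) {
        adaptedness_env(state, envs[[i]], niche, pu, method = method,
                        n = n_pheno,
                        seed = derive_seed(seed, paste0("sub", u, "env", i)),
                        mu = mu)$value
      }, numeric(1))
      vals[u] <- mean(per)
      vars[u] <- stats::var(per) / length(per)
      n_tot <- n_tot + length(per)
    }
  }
  adaptedness_estimate(sum(w * vals), sqrt(sum(w^2 * vars)),
                       if (method == "closed_form" && all(vars == 0)) "closed_form" else "monte_carlo",
                       as.integer(n_tot))
}

#' Export adaptedness evaluations per subniche as a data frame
#'
#' @inheritParams adaptedness_niche
#' @return data.frame with columns subniche, method, value, se, n.
#' @export
adaptedness_by_subniche <- function(state, niche, params_by_subniche,
                                    method = "closed_form", n_env = 200L,
                                    n_pheno = 10000L, seed = 1L) {
  if (inherits(params_by_subniche, "merit_params")) {
    params_by_subniche <- stats::setNames(
      rep(list(params_by_subniche), length(niche$subniches)),
      names(niche$subniches))
  }
  rows <- lapply(names(niche$subniches), function(lab) {
    sub_niche <- breed_niche(list(niche$subniches[[lab]]), niche$producer_env)
    est <- adaptedness_niche(state, sub_niche, params_by_subniche[lab],
                             method = method, n_env = n_env,
                             n_pheno = n_pheno, seed = seed)
    data.frame(subniche = lab, method = est$method, value = est$value,
               se = est$se, n = est$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
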