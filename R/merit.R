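#' Merit-function parameters
#'
#' Bundles the parameters of all merit functions for one environment (or one
#' subniche of like-minded owners):
#'
#' * `profit`: linear profit equation. `fixed` plus per-trait coefficients
#'   `base`; both can depend on influencing variables through per-variable
#'   multipliers (`fixed_mult`, and `mult`, a per-trait list of named
#'   multipliers), giving coefficients c_k(v) = base_k + sum_j mult_kj * v_j.
#' * `quality`: linear product-quality score `q0 + sum_k q_k y_k` rated by
#'   consumers.
#' * `performance`, `emotional`, `altruistic`: reward merits of the form
#'   `tau_max - sum_k omega_k |y_k - opt_k|`, each over its own trait subset
#'   (performance/behaviour traits, emotional pattern scores, traditional
#'   breed-type traits). The altruistic merit also carries the breed id.
#' * `easygoing`: perceived per-trait costs `omega` and their monetary
#'   counterparts `omega_mon`; the perceived extra cost is
#'   `sum_k (omega_k - omega_mon_k) y_k` over traits with omega > omega_mon.
#' * `weights`: `lambda` (weight of non-monetary rewards/costs relative to
#'   profit, >= 0), `w` (three nonnegative weights for the performance,
#'   emotional and altruistic rewards), and `alpha` (weights alpha_p,
#'   alpha_n, alpha_c of producer merit, owner merit and product quality in
#'   the adaptedness; nonnegative, summing to 1).
#'
#' @param profit list(fixed=, fixed_mult=, base=, mult=).
#' @param quality list(q0=, q=).
#' @param performance,emotional list(omega=, opt=, tau_max=).
#' @param altruistic list(breed_id=, omega=, opt=, tau_max=).
#' @param easygoing list(omega=, omega_mon=).
#' @param weights list(lambda=, w=c(perf, emot, altr), alpha=c(p, n, c)).
#' @param traits optional [trait_space]; when given, every referenced trait
#'   label is checked against it.
#' @return An object of class `merit_params`.
#' @export
merit_params <- function(profit = list(), quality = list(),
                         performance = list(), emotional = list(),
                         altruistic = list(), easygoing = list(),
                         weights = list(), traits = NULL) {
  reward_component <- function(x, what, need_breed = FALSE) {
    omega <- assert_named_numeric(x[["omega"]] %||% numeric(0),
                                  paste0(what, " omega"), nonneg = TRUE)
    opt <- assert_named_numeric(x[["opt"]] %||% numeric(0), paste0(what, " opt"))
    if (!identical(sort(names(omega)), sort(names(opt)))) {
      stop_ng(what, ": omega and opt must cover the same traits")
    }
    opt <- if (length(omega)) opt[names(omega)] else opt
    tau_max <- x[["tau_max"]] %||% 0
    if (!is.numeric(tau_max) || length(tau_max) != 1L) {
      stop_ng(what, ": tau_max must be a number")
    }
    out <- list(omega = omega, opt = opt, tau_max = as.numeric(tau_max))
    if (need_breed) out$breed_id <- x[["breed_id"]] %||% ""
    out
  }
  p <- list(
    fixed = as.numeric(profit[["fixed"]] %||% 0),
    fixed_mult = assert_named_numeric(profit[["fixed_mult"]] %||% numeric(0), "profit fixed_mult"),
    base = assert_named_numeric(profit[["base"]] %||% numeric(0), "profit base"),
    mult = lapply(profit[["mult"]] %||% list(), function(m) assert_named_numeric(m, "profit mult"))
  )
  if (length(p$mult) && (is.null(names(p$mult)) || anyDuplicated(names(p$mult)))) {
    stop_ng("profit$mult must be a named list keyed by trait label")
  }
  q <- list(q0 = as.numeric(quality[["q0"]] %||% 0),
            q = assert_named_numeric(quality[["q"]] %||% numeric(0), "quality q"))
  eg <- list(omega = assert_named_numeric(easygoing[["omega"]] %||% numeric(0),
                                          "easygoing omega", nonneg = TRUE),
             omega_mon = assert_named_numeric(easygoing[["omega_mon"]] %||% numeric(0),
                                              "easygoing omega_mon"))
  if (!identical(sort(names(eg$omega)), sort(names(eg$omega_mon)))) {
    stop_ng("easygoing: omega and omega_mon must cover the same traits")
  }
  if (length(eg$omega)) eg$omega_mon <- eg$omega_mon[names(eg$omega)]
  wt <- list(lambda = as.numeric(weights[["lambda"]] %||% 0),
             w = as.numeric(weights[["w"]] %||% c(1, 1, 1)),
             alpha = as.numeric(weights[["alpha"]] %||% c(0, 1, 0)))
  if (wt$lambda < 0) stop_ng("lambda must be >= 0")
  if (length(wt$w) != 3L || any(wt$w < 0)) stop_ng("weights$w must be 3 nonnegative numbers")
  if (length(wt$alpha) != 3L || any(wt$alpha < 0)) {
    stop_ng("weights$alpha must be 3 nonnegative numbers")
  }
  if (abs(sum(wt$alpha) - 1) > 1e-12) stop_ng("alpha weights must sum to 1")
  names(wt$w) <- c("performance", "emotional", "altruistic")
  names(wt$alpha) <- c("p", "n", "c")
  obj <- structure(list(profit = p, quality = q,
                        performance = reward_component(performance, "performance"),
                        emotional = reward_component(emotional, "emotional"),
                        altruistic = reward_component(altruistic, "altruistic", need_breed = TRUE),
                        easygoing = eg, weights = wt),
                   class = "merit_params")
  if (!is.null(traits)) validate_merit_traits(obj, traits)
  obj
}

validate_merit_traits <- function(params, traits) {
  labs <- trait_labels(traits)
  referenced <- unique(c(names(params$profit$base), names(params$profit$mult),
                         names(params$quality$q),
                         names(params$performance$omega),
                         names(params$emotional$omega),
                         names(params$altruistic$omega),
                         names(params$easygoing$omega)))
  bad <- setdiff(referenced, labs)
  if (length(bad)) {
    stop_ng("merit parameters reference unknown traits: ",
            paste(bad, collapse = ", "))
  }
  invisible(params)
}

# per-trait profit coefficients c_k(v) for all traits referenced in params;
# traits not referenced get coefficient 0
profit_coefficients <- function(params, v, trait_names = NULL) {
  p <- params$profit
  trait_names <- trait_names %||% unique(c(names(p$base), names(p$mult)))
  cc <- stats::setNames(numeric(length(trait_names)), trait_names)
  if (length(p$base)) cc[names(p$base)] <- p$base
  for (tr in names(p$mult)) {
    m <- p$mult[[tr]]
    vals <- iv_get(v, names(m), "profit-equation variable")
    cc[tr] <- cc[tr] + sum(m * vals)
  }
  cc
}

profit_fixed_term <- function(params, v) {
  p <- params$profit
  fx <- p$fixed
  if (length(p$fixed_mult)) {
    fx <- fx + sum(p$fixed_mult * iv_get(v, names(p$fixed_mult), "profit-equation variable"))
  }
  fx
}

#' Monetary profit of an animal
#'
#' Linear profit equation: fixed term plus per-trait coefficients, both
#' possibly depending on influencing variables (e.g. a milk-price multiplier
#' on milk yield).
#'
#' @param y named K-vector of trait values.
#' @param v an [influencing_variables].
#' @param params a [merit_params].
#' @return Profit in money units.
#' @export
profit_merit <- function(y, v, params) {
  cc <- profit_coefficients(params, v)
  profit_fixed_term(params, v) + sum(cc * y[names(cc)])
}

reward_merit <- function(y, comp) {
  if (length(comp$omega) == 0L) return(comp$tau_max)
  comp$tau_max - sum(comp$omega * abs(y[names(comp$omega)] - comp$opt))
}

#' Merit for physical and mental performance
#'
#' `tau_max - sum_k omega_k |y_k - opt_k|` over the performance and
#' behaviour traits: each trait has an owner-specific optimum (highly
#' performing animals can overwhelm their owners), and deviations in either
#' direction reduce the perceived reward.
#'
#' @inheritParams profit_merit
#' @return Merit in reward units; maximal (= tau_max) exactly at the optima.
#' @export
performance_merit <- function(y, params) reward_merit(y, params$performance)

#' Merit for satisfying emotional needs
#'
#' Same functional form as [performance_merit()], taken over emotional
#' pattern scores (e.g. a cuteness score), with owner-specific optimum
#' scores and importance weights.
#'
#' @inheritParams profit_merit
#' @export
emotional_merit <- function(y, params) reward_merit(y, params$emotional)

#' Merit for altruistic desires (traditional breed type)
#'
#' Reward for adhering to the historic breed type: deviations from the
#' historic optima of the configured traits reduce the merit. Depends on the
#' breed, not on the environment. With an empty trait set and tau_max = 0 it
#' is constantly zero.
#'
#' @inheritParams profit_merit
#' @export
altruistic_merit <- function(y, params) reward_merit(y, params$altruistic)

#' Perceived easygoingness cost
#'
#' `sum_k (omega_k - omega_mon_k) y_k` over traits whose perceived cost
#' omega exceeds the true monetary cost omega_mon; traits where the
#' perceived cost does not exceed the monetary cost carry no extra perceived
#' cost and are excluded from the sum.
#'
#' @inheritParams profit_merit
#' @export
easygoing_cost <- function(y, params) {
  eg <- params$easygoing
  if (length(eg$omega) == 0L) return(0)
  d <- eg$omega - eg$omega_mon
  dropped <- names(d)[d < 0]
  if (length(dropped)) {
    ng_message("easygoing_cost: perceived cost below monetary cost, excluding: ",
               paste(dropped, collapse = ", "))
  }
  keep <- d > 0
  if (!any(keep)) return(0)
  sum(d[keep] * y[names(d)[keep]])
}

#' Non-monetary reward of an owner
#'
#' Weighted sum of the performance, emotional and altruistic rewards with
#' the owner's weights w.
#'
#' @inheritParams profit_merit
#' @export
nonmonetary_reward <- function(y, params) {
  w <- params$weights$w
  w[[1]] * performance_merit(y, params) +
    w[[2]] * emotional_merit(y, params) +
    w[[3]] * altruistic_merit(y, params)
}

#' Total merit of an animal for its owner
#'
#' `TM_e(y) = profit + lambda * (reward - perceived cost)`: the monetary
#' profit plus the lambda-weighted non-monetary net reward. With lambda = 0
#' (pure producer) only the profit remains; lambda = 1 suits owners who keep
#' animals for their own sake.
#'
#' @param y named K-vector of trait values.
#' @param e an [owner_environment].
#' @param params a [merit_params].
#' @export
total_merit <- function(y, e, params) {
  profit_merit(y, e$influencing, params) +
    params$weights$lambda * (nonmonetary_reward(y, params) - easygoing_cost(y, params))
}

#' Product quality as rated by consumers
#'
#' Linear quality score `q0 + sum_k q_k y_k`.
#'
#' @inheritParams profit_merit
#' @export
product_quality <- function(y, params) {
  q <- params$quality
  if (length(q$q) == 0L) return(q$q0)
  q$q0 + sum(q$q * y[names(q$q)])
}

#' Monetary costs of traits from the profit equation
#'
#' First-order Taylor approximation of the profit function around the trait
#' means: for the linear profit equation this is exactly the vector of
#' profit coefficients c_k(v), independent of the expansion point. Used to
#' populate the monetary costs omega_mon of the easygoingness component.
#'
#' @param params a [merit_params].
#' @param mu named K-vector of trait means (expansion point).
#' @param v an [influencing_variables].
#' @return Named vector of per-trait monetary values (money per trait unit)
#'   over all traits in `mu`.
#' @export
monetary_trait_costs <- function(params, mu, v) {
  cc <- profit_coefficients(params, v, trait_names = names(mu))
  cc[names(mu)]
}

# vectorized total merit over rows of a phenotype matrix (same formulas as
# total_merit; kept in sync for the Monte-Carlo path)
total_merit_rows <- function(Y, e, params) {
  cc <- profit_coefficients(params, e$influencing)
  prof <- profit_fixed_term(params, e$influencing) +
    if (length(cc)) drop(Y[, names(cc), drop = FALSE] %*% cc) else 0
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
      dev <- abs(sweep(Y[, names(comp$omega), drop = FALSE], 2, comp$opt))
      rew <- rew + w[i] * (comp$tau_max - drop(dev %*% comp$omega))
    }
  }
  cost <- 0
  eg <- params$easygoing
  if (length(eg$omega)) {
    d <- eg$omega - eg$omega_mon
    keep <- d > 0
    if (any(keep)) {
      cost <- drop(Y[, names(d)[keep], drop = FALSE] %*% d[keep])
    }
  }
  prof + lam * (rew - cost)
}

product_quality_rows <- function(Y, params) {
  q <- params$quality
  if (length(q$q) == 0L) return(rep(q$q0, nrow(Y)))
  q$q0 + drop(Y[, names(q$q), drop = FALSE] %*% q$q)
}
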