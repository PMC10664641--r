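#' Search area for the breeding-goal optimization
#'
#' A per-trait box around the current trait means (default half-width two
#' phenotypic standard deviations) minus labelled ethical exclusion regions.
#' Exclusions describe trait combinations incompatible with animal health or
#' welfare, expressed as half-spaces (e.g. a health-score floor) or boxes.
#'
#' @param state a [breed_state].
#' @param k box half-width in phenotypic standard deviations (default 2).
#' @param exclusions list of exclusions from [exclusion_halfspace()] /
#'   [exclusion_box()].
#' @param lower,upper optional named vectors overriding the default box.
#' @return An object of class `search_area`.
#' @export
search_area <- function(state, k = 2, exclusions = list(), lower = NULL,
                        upper = NULL) {
  stopifnot(inherits(state, "breed_state"))
  sds <- sqrt(diag(state$genetics$P))
  lo <- lower %||% (state$mu_c - k * sds)
  hi <- upper %||% (state$mu_c + k * sds)
  lo <- lo[names(state$mu_c)]
  hi <- hi[names(state$mu_c)]
  if (any(hi < lo)) stop_ng("search-area box is empty for some trait")
  for (ex in exclusions) {
    if (!inherits(ex, "goal_exclusion")) stop_ng("exclusions must be goal_exclusion objects")
  }
  structure(list(lower = lo, upper = hi, exclusions = exclusions),
            class = "search_area")
}

#' Ethical exclusion: half-space
#'
#' Excludes breeding goals mu with `sum(coef * mu) < rhs`; i.e. the
#' requirement `coef' mu >= rhs` must hold (for example a floor on a health
#' score, or `coef = -1` for a cap on barking frequency).
#'
#' @param label constraint name (reported when violated).
#' @param coef named coefficient vector over traits.
#' @param rhs threshold.
#' @export
exclusion_halfspace <- function(label, coef, rhs) {
  structure(list(label = label, type = "halfspace",
                 coef = assert_named_numeric(coef, "exclusion coef"),
                 rhs = as.numeric(rhs)),
            class = "goal_exclusion")
}

#' Ethical exclusion: box
#'
#' Excludes breeding goals lying inside the given trait box (all listed
#' traits simultaneously within their excluded intervals).
#'
#' @param label constraint name.
#' @param lower,upper named vectors over the same traits.
#' @export
exclusion_box <- function(label, lower, upper) {
  lower <- assert_named_numeric(lower, "exclusion lower")
  upper <- assert_named_numeric(upper, "exclusion upper")[names(lower)]
  structure(list(label = label, type = "box", lower = lower, upper = upper),
            class = "goal_exclusion")
}

excluded_by <- function(ex, mu) {
  if (ex$type == "halfspace") {
    sum(ex$coef * mu[names(ex$coef)]) < ex$rhs
  } else {
    all(mu[names(ex$lower)] >= ex$lower & mu[names(ex$lower)] <= ex$upper)
  }
}

#' Response area: the ellipsoid of reachable trait means
#'
#' Trait-mean states reachable from the current means within T generations
#' of index selection at intensity i per generation, with constant G and P:
#' the set `{mu : (mu - mu_c)' (G P^-1 G)^-1 (mu - mu_c) <= (T i)^2}`. Every
#' per-generation index response `i G b / sqrt(b' P b)` lies on the
#' unit-radius version of this boundary, so T generations reach radius T i.
#'
#' @param gen a [genetic_parameters] (G must be nonsingular).
#' @param mu_c named K-vector of current means (ellipsoid center).
#' @param intensity selection intensity i per generation (> 0).
#' @param generations number of generations T (>= 1).
#' @return An object of class `response_area` with the shape matrix `M`
#'   (= (G P^-1 G)^-1), its inverse `Minv`, center and radius `r = T i`.
#' @export
build_response_area <- function(gen, mu_c, intensity, generations) {
  stopifnot(inherits(gen, "genetic_parameters"))
  if (intensity <= 0) stop_ng("intensity must be > 0")
  if (generations < 1) stop_ng("generations must be >= 1")
  G <- gen$G
  P <- gen$P
  evG <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(evG) <= 1e-10 * max(evG)) {
    stop_ng("G is singular: some trait has no usable genetic variance; ",
            "reduce the trait set before building the response area")
  }
  Minv <- G %*% solve(P, G)          # G P^-1 G
  Minv <- (Minv + t(Minv)) / 2
  M <- solve(Minv)
  M <- (M + t(M)) / 2
  mu_c <- mu_c[rownames(G)]
  structure(list(center = mu_c, M = M, Minv = Minv,
                 r = as.numeric(generations * intensity),
                 intensity = as.numeric(intensity),
                 generations = as.integer(generations)),
            class = "response_area")
}

ellipsoid_qf <- function(response, mu) {
  d <- mu[names(response$center)] - response$center
  drop(t(d) %*% response$M %*% d)
}

#' Permissible set of breeding goals
#'
#' The intersection of the search area and the response area, minus
#' the ethical exclusions: membership = in-box AND in-ellipsoid AND
#' not-excluded.
#'
#' @param search a [search_area].
#' @param response a [response_area].
#' @return An object of class `permissible_set`.
#' @export
permissible_set <- function(search, response) {
  stopifnot(inherits(search, "search_area"), inherits(response, "response_area"))
  structure(list(search = search, response = response),
            class = "permissible_set")
}

#' Membership test for the permissible set
#'
#' Exact evaluation of the box, the ellipsoid quadratic form (closed set,
#' tolerance 1e-12 on the boundary) and every exclusion; all violated
#' constraints are labelled.
#'
#' @param set a [permissible_set].
#' @param mu named K-vector.
#' @return list with `member` (logical) and `violated` (character labels,
#'   `"box:<trait>"`, `"ellipsoid"` or the exclusion label).
#' @export
membership <- function(set, mu) {
  stopifnot(inherits(set, "permissible_set"))
  s <- set$search
  mu <- mu[names(s$lower)]
  violated <- character(0)
  below <- mu < s$lower
  above <- mu > s$upper
  if (any(below | above)) {
    violated <- c(violated, paste0("box:", names(mu)[below | above]))
  }
  qf <- ellipsoid_qf(set$response, mu)
  if (qf > set$response$r^2 + 1e-12) violated <- c(violated, "ellipsoid")
  for (ex in s$exclusions) {
    if (excluded_by(ex, mu)) violated <- c(violated, ex$label)
  }
  list(member = length(violated) == 0L, violated = violated)
}

# project a candidate toward feasibility: clip to box, then shrink toward
# the center onto the ellipsoid (both operations keep the box because the
# center lies in the box)
project_candidate <- function(set, mu) {
  s <- set$search
  mu <- pmin(pmax(mu[names(s$lower)], s$lower), s$upper)
  qf <- ellipsoid_qf(set$response, mu)
  r2 <- set$response$r^2
  if (qf > r2) {
    mu <- set$response$center + (mu - set$response$center) * sqrt(r2 / qf)
    mu <- pmin(pmax(mu, s$lower), s$upper)
  }
  mu
}

#' Maximize an adaptedness objective over the permissible set
#'
#' Multi-start pattern (compass) search in coordinates whitened by the
#' response ellipsoid, with projection onto the ellipsoid and search box
#' and rejection of excluded points. Derivative-free search is used because
#' the closed-form adaptedness objective has kinks at the merit optima.
#' The search always includes the current means as a start, so the result
#' never falls below the objective there (ascent property). Deterministic
#' given the seed; ties broken by the first start that attains the optimum.
#'
#' @param objective function of a named K-vector mu returning a scalar to
#'   maximize (e.g. closed-form [adaptedness_niche()] value).
#' @param set a [permissible_set].
#' @param n_starts number of random feasible starts in addition to the
#'   center.
#' @param seed integer seed for the random starts and search directions.
#' @param tol final step size of the pattern search (whitened scale).
#' @return An object of class `goal_result` with the optimized intermediate
#'   goal `mu_i`, desired gains `delta_mu`, desired-gain index weights `b`
#'   (NULL when no gain is requested), the achieved objective `value`, and
#'   optimizer diagnostics.
#' @export
optimize_goal <- function(objective, set, n_starts = 4L, seed = 1L, tol = 1e-6) {
  stopifnot(inherits(set, "permissible_set"))
  resp <- set$response
  K <- length(resp$center)
  U <- chol(resp$M)                   # qf = || U (mu - c) ||^2
  to_mu <- function(z) resp$center + drop(backsolve(U, z)) * resp$r
  to_z <- function(mu) drop(U %*% (mu[names(resp$center)] - resp$center)) / resp$r

  feasible <- function(mu) membership(set, mu)$member
  fz <- function(z) {
    mu <- project_candidate(set, to_mu(z))
    if (!feasible(mu)) return(list(val = -Inf, mu = mu))
    list(val = objective(mu), mu = mu)
  }

  center_feasible <- feasible(project_candidate(set, resp$center))
  starts <- list()
  if (center_feasible) starts[[1]] <- to_z(project_candidate(set, resp$center))
  with_seed(derive_seed(seed, "goal_starts"), {
    tries <- 0L
    while (length(starts) < n_starts + center_feasible && tries < 200L) {
      z <- stats::rnorm(K)
      z <- z / sqrt(sum(z^2)) * stats::runif(1)^(1 / K) * 0.95
      if (feasible(project_candidate(set, to_mu(z)))) starts[[length(starts) + 1L]] <- z
      tries <- tries + 1L
    }
  })
  if (length(starts) == 0L) {
    stop_ng("no permissible goal: the exclusions swallow the reachable set; ",
            "extend the planning horizon")
  }

  rand_dirs <- with_seed(derive_seed(seed, "goal_dirs"), {
    m <- matrix(stats::rnorm(K * 2 * K), ncol = K)
    m / sqrt(rowSums(m^2))
  })

  best <- NULL
  total_iter <- 0L
  for (si in seq_along(starts)) {
    z <- starts[[si]]
    cur <- fz(z)
    step <- 0.5
    while (step > tol) {
      improved <- FALSE
      dirs <- rbind(diag(K), -diag(K), rand_dirs, -rand_dirs)
      nz <- sqrt(sum(z^2))
      if (nz > 1e-12) dirs <- rbind(dirs, z / nz, -z / nz)
      for (d in seq_len(nrow(dirs))) {
        cand <- fz(z + step * dirs[d, ])
        if (cand$val > cur$val + 1e-15) {
          z <- to_z(cand$mu)
          cur <- cand
          improved <- TRUE
        }
      }
      total_iter <- total_iter + 1L
      if (!improved) step <- step / 2
    }
    if (is.null(best) || cur$val > best$val + 1e-12) {
      best <- list(val = cur$val, mu = cur$mu, start = si)
    }
  }

  mu_i <- best$mu
  delta <- mu_i - resp$center
  b <- if (sqrt(sum(delta^2)) > 1e-10 && !is.null(attr_G(set))) {
    desired_gain_index(list(G = attr_G(set), P = attr_P(set)), delta)
  } else NULL
  structure(list(mu_i = mu_i, delta_mu = delta, b = b, value = best$val,
                 diagnostics = list(starts = length(starts),
                                    iterations = total_iter,
                                    best_start = best$start,
                                    converged = TRUE)),
            class = "goal_result")
}

# Minv = G P^-1 G cannot be decomposed back into (G, P); the desired-gain
# index is therefore only derived when the genetic parameters were attached
# via permissible_set_with_genetics().
attr_G <- function(set) attr(set, "G") %||% NULL
attr_P <- function(set) attr(set, "P") %||% NULL

#' Attach genetic parameters to a permissible set
#'
#' Stores G and P on the set so [optimize_goal()] can derive the
#' desired-gain index of the optimized goal directly.
#'
#' @param set a [permissible_set].
#' @param gen a [genetic_parameters].
#' @export
permissible_set_with_genetics <- function(set, gen) {
  attr(set, "G") <- gen$G
  attr(set, "P") <- gen$P
  set
}

#' @export
print.goal_result <- function(x, ...) {
  cat("<goal_result> objective =", signif(x$value, 8), "\n")
  df <- data.frame(trait = names(x$mu_i), goal = x$mu_i, delta = x$delta_mu,
                   row.names = NULL)
  if (!is.null(x$b)) df$b <- x$b[names(x$mu_i)]
  print(df)
  invisible(x)
}

#' Desired-gain selection index
#'
#' Index weights whose expected multi-trait response is proportional to a
#' prescribed gain vector: `b = P^-1 G (G P^-1 G)^-1 delta_mu`, normalized
#' to unit index variance `b' P b = 1`.
#'
#' @param gen a [genetic_parameters] (or list with elements G, P); G must be
#'   nonsingular.
#' @param delta_mu named K-vector of desired gains (nonzero).
#' @return Named K-vector of index weights.
#' @export
desired_gain_index <- function(gen, delta_mu) {
  G <- gen$G
  P <- gen$P
  if (is.null(G) || is.null(P)) stop_ng("genetic parameters with G and P are required")
  delta_mu <- delta_mu[rownames(G)]
  if (sqrt(sum(delta_mu^2)) == 0) stop_ng("no gain requested: delta_mu is zero")
  Minv <- G %*% solve(P, G)
  b <- solve(P, G %*% solve(Minv, delta_mu))
  b <- drop(b)
  names(b) <- rownames(G)
  b / sqrt(drop(t(b) %*% P %*% b))
}

#' Expected per-generation response of a selection index
#'
#' Multi-trait response to one generation of truncation selection at
#' intensity i on the index b: `i G b / sqrt(b' P b)` (invariant to positive
#' rescaling of b).
#'
#' @param gen a [genetic_parameters].
#' @param b named K-vector of index weights (nonzero).
#' @param intensity selection intensity i.
#' @return Named K-vector: expected genetic gain per generation.
#' @export
expected_response <- function(gen, b, intensity) {
  b <- b[rownames(gen$G)]
  denom <- sqrt(drop(t(b) %*% gen$P %*% b))
  if (!is.finite(denom) || denom == 0) stop_ng("null index: b' P b = 0")
  drop(intensity * gen$G %*% b) / denom
}

#' Smith-Hazel economic selection index
#'
#' The classical index for linear economic weights a: `b = P^-1 G a`,
#' normalized to unit index variance. Serves as the traditional-approach
#' benchmark: when producers solely maximize income, the niche-based
#' optimization reproduces this index.
#'
#' @param gen a [genetic_parameters].
#' @param econ_weights named K-vector of marginal economic values.
#' @return Named K-vector of index weights.
#' @export
smith_hazel_index <- function(gen, econ_weights) {
  a <- econ_weights[rownames(gen$G)]
  b <- drop(solve(gen$P, gen$G %*% a))
  names(b) <- rownames(gen$G)
  b / sqrt(drop(t(b) %*% gen$P %*% b))
}

#' Genetic variance of a selection index
#'
#' Returns `b' G b` and flags the goal as at risk when the index carries
#' (almost) no genetic variance: selection could exhaust the variance in
#' the index before the goal is reached.
#'
#' @param gen a [genetic_parameters].
#' @param b named K-vector of index weights.
#' @param tolerance variance threshold for the flag.
#' @return list with `variance` and `flag` ("ok" or "inadmissible goal risk").
#' @export
index_variance_check <- function(gen, b, tolerance = 1e-10) {
  b <- b[rownames(gen$G)]
  v <- drop(t(b) %*% gen$G %*% b)
  list(variance = v,
       flag = if (v <= tolerance) "inadmissible goal risk" else "ok")
}
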