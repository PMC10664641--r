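#' Owner desire profile
#'
#' An owner's position in the space of desires: nonnegative importance scores
#' grouped into the five desire categories (profit, performance, emotional,
#' easygoing, altruistic). Each category holds a named numeric vector of
#' desire dimensions; a score quantifies how much the owner wants an animal
#' to satisfy that desire. Labels must be unique across all categories so
#' that merit-parameter bindings can address dimensions by name.
#'
#' @param profit,performance,emotional,easygoing,altruistic named numeric
#'   vectors of nonnegative scores (possibly empty).
#' @return An object of class `desire_profile`.
#' @examples
#' desire_profile(profit = c(income = 1), emotional = c(cuteness_desire = 0.8))
#' @export
desire_profile <- function(profit = numeric(0), performance = numeric(0),
                           emotional = numeric(0), easygoing = numeric(0),
                           altruistic = numeric(0)) {
  cats <- list(profit = profit, performance = performance,
               emotional = emotional, easygoing = easygoing,
               altruistic = altruistic)
  cats <- mapply(function(x, nm) assert_named_numeric(x, paste0("desire scores [", nm, "]"),
                                                      nonneg = TRUE),
                 cats, names(cats), SIMPLIFY = FALSE)
  all_labels <- unlist(lapply(cats, names), use.names = FALSE)
  if (anyDuplicated(all_labels)) {
    stop_ng("desire dimension labels must be unique across categories: ",
            paste(unique(all_labels[duplicated(all_labels)]), collapse = ", "))
  }
  structure(cats, class = "desire_profile")
}

#' Influencing variables of an environment
#'
#' The components of an environment that modulate how an owner evaluates an
#' animal's suitability for a desire: owner traits, the physical environment
#' (feed quality, housing, climate), market prices, and legislative
#' conditions. Market prices must be nonnegative; labels unique across
#' categories so they can be referenced from profit coefficients and
#' reaction norms.
#'
#' @param owner,physical,market,legislative named numeric vectors.
#' @return An object of class `influencing_variables`.
#' @examples
#' influencing_variables(market = c(milk_price = 0.4), physical = c(feed_quality = 1))
#' @export
influencing_variables <- function(owner = numeric(0), physical = numeric(0),
                                  market = numeric(0), legislative = numeric(0)) {
  cats <- list(owner = assert_named_numeric(owner, "owner traits"),
               physical = assert_named_numeric(physical, "physical environment"),
               market = assert_named_numeric(market, "market prices", nonneg = TRUE),
               legislative = assert_named_numeric(legislative, "legislative conditions"))
  all_labels <- unlist(lapply(cats, names), use.names = FALSE)
  if (anyDuplicated(all_labels)) {
    stop_ng("influencing-variable labels must be unique across categories: ",
            paste(unique(all_labels[duplicated(all_labels)]), collapse = ", "))
  }
  structure(cats, class = "influencing_variables")
}

# flat named vector of all influencing variables
iv_flatten <- function(v) {
  out <- unlist(unclass(v), use.names = FALSE)
  names(out) <- unlist(lapply(unclass(v), names), use.names = FALSE)
  out
}

iv_get <- function(v, labels, context = "influencing variable") {
  flat <- iv_flatten(v)
  missing <- setdiff(labels, names(flat))
  if (length(missing) > 0) {
    stop_ng("missing ", context, ": ", paste(missing, collapse = ", "))
  }
  flat[labels]
}

# return a copy of v with the named flat values replaced
iv_set <- function(v, values) {
  for (cat in names(v)) {
    hit <- intersect(names(values), names(v[[cat]]))
    if (length(hit)) v[[cat]][hit] <- values[hit]
  }
  v
}

#' Environment of an owner
#'
#' A point e = (d, v) in the space of environments: the owner's desire
#' profile together with the influencing variables. Immutable value object.
#'
#' @param desire a [desire_profile].
#' @param influencing an [influencing_variables].
#' @return An object of class `owner_environment`.
#' @export
owner_environment <- function(desire, influencing) {
  if (!inherits(desire, "desire_profile")) stop_ng("`desire` must be a desire_profile")
  if (!inherits(influencing, "influencing_variables")) {
    stop_ng("`influencing` must be an influencing_variables")
  }
  structure(list(desire = desire, influencing = influencing),
            class = "owner_environment")
}

#' @export
print.owner_environment <- function(x, ...) {
  cat("<owner_environment>\n")
  d <- unlist(lapply(unclass(x$desire), names))
  v <- iv_flatten(x$influencing)
  cat("  desire dims:", if (length(d)) paste(d, collapse = ", ") else "(none)", "\n")
  cat("  influencing:", if (length(v)) paste(names(v), "=", signif(v, 4), collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Subniche: a distribution over environments with a size and growth rate
#'
#' A subniche groups owners with similar desires or physical conditions. Its
#' environment distribution is either a finite set of environment atoms with
#' probabilities, or a multivariate Gaussian over a declared subset of
#' influencing-variable dimensions (all other components held at a base
#' environment). The subniche carries its current size (number of owner
#' places) and a constant annual growth rate.
#'
#' @param label subniche name.
#' @param size current number of owner places (>= 0).
#' @param growth_rate annual exponential growth rate (real; negative = decline).
#' @param atoms optional list of `list(environment=, prob=)` entries; probs
#'   must sum to 1.
#' @param gaussian optional list with `base` (an [owner_environment]), `mean`
#'   (named numeric over influencing-variable labels) and `cov` (matrix,
#'   symmetric positive semidefinite, dimnames matching `mean`).
#' @return An object of class `subniche`.
#' @export
subniche <- function(label, size, growth_rate, atoms = NULL, gaussian = NULL) {
  if (!is.character(label) || length(label) != 1L) stop_ng("`label` must be a string")
  if (!is.numeric(size) || length(size) != 1L || size < 0) stop_ng("subniche size must be >= 0")
  if (!is.numeric(growth_rate) || length(growth_rate) != 1L) stop_ng("growth_rate must be a number")
  if (is.null(atoms) == is.null(gaussian)) {
    stop_ng("exactly one of `atoms` or `gaussian` must be given")
  }
  if (!is.null(atoms)) {
    probs <- vapply(atoms, function(a) a$prob, numeric(1))
    if (any(probs < 0)) stop_ng("atom probabilities must be >= 0")
    if (abs(sum(probs) - 1) > 1e-12) stop_ng("atom probabilities must sum to 1")
    for (a in atoms) {
      if (!inherits(a$environment, "owner_environment")) {
        stop_ng("each atom must contain an owner_environment")
      }
    }
    dist <- list(type = "atoms", atoms = atoms)
  } else {
    m <- assert_named_numeric(gaussian$mean, "gaussian mean")
    cv <- gaussian$cov
    if (!is_symmetric_matrix(cv)) stop_ng("gaussian covariance must be symmetric")
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1)) {
      stop_ng("gaussian covariance must be positive semidefinite")
    }
    if (!inherits(gaussian$base, "owner_environment")) {
      stop_ng("gaussian$base must be an owner_environment")
    }
    iv_get(gaussian$base$influencing, names(m))  # dims must exist in base
    dimnames(cv) <- list(names(m), names(m))
    dist <- list(type = "gaussian", base = gaussian$base, mean = m, cov = cv)
  }
  structure(list(label = label, size = as.numeric(size),
                 growth_rate = as.numeric(growth_rate), distribution = dist),
            class = "subniche")
}

#' Niche of a breed
#'
#' The envisaged niche: a weighted mixture of subniches (weights proportional
#' to subniche sizes) plus the environment the producer offers his animals.
#' A randomly chosen owner environment is a draw from this mixture.
#'
#' @param subniches list of [subniche] objects (at least one).
#' @param producer_env the producer's [owner_environment].
#' @return An object of class `breed_niche`.
#' @export
breed_niche <- function(subniches, producer_env) {
  if (inherits(subniches, "subniche")) subniches <- list(subniches)
  if (length(subniches) < 1L) stop_ng("a niche needs at least one subniche")
  for (s in subniches) if (!inherits(s, "subniche")) stop_ng("all elements must be subniches")
  labs <- vapply(subniches, `[[`, character(1), "label")
  if (anyDuplicated(labs)) stop_ng("subniche labels must be unique")
  if (!inherits(producer_env, "owner_environment")) {
    stop_ng("`producer_env` must be an owner_environment")
  }
  names(subniches) <- labs
  structure(list(subniches = subniches, producer_env = producer_env),
            class = "breed_niche")
}

#' @export
print.breed_niche <- function(x, ...) {
  cat("<breed_niche> with", length(x$subniches), "subniche(s)\n")
  for (s in x$subniches) {
    cat(sprintf("  %-24s size %.6g, growth %+.3g/yr, %s\n", s$label, s$size,
                s$growth_rate, s$distribution$type))
  }
  invisible(x)
}

niche_weights <- function(niche) {
  sizes <- vapply(niche$subniches, `[[`, numeric(1), "size")
  tot <- sum(sizes)
  if (tot <= 0) stop_ng("empty niche: all subniche sizes are zero")
  sizes / tot
}

sample_from_subniche <- function(sub, n) {
  dist <- sub$distribution
  if (dist$type == "atoms") {
    idx <- sample.int(length(dist$atoms), n, replace = TRUE,
                      prob = vapply(dist$atoms, `[[`, numeric(1), "prob"))
    lapply(idx, function(i) dist$atoms[[i]]$environment)
  } else {
    draws <- MASS::mvrnorm(n, mu = dist$mean, Sigma = dist$cov)
    if (n == 1L) draws <- matrix(draws, nrow = 1, dimnames = list(NULL, names(dist$mean)))
    lapply(seq_len(n), function(i) {
      e <- dist$base
      e$influencing <- iv_set(e$influencing, draws[i, ])
      e
    })
  }
}

#' Sample owner environments from a niche
#'
#' Draws i.i.d. environments from the niche mixture: a subniche is chosen
#' with probability proportional to its size, then an environment is drawn
#' from that subniche's distribution.
#'
#' @param niche a [breed_niche].
#' @param n number of draws (>= 1).
#' @param seed integer seed; draws are reproducible given the seed.
#' @return A list of `n` [owner_environment] objects with attribute
#'   `"subniche"` giving the source subniche label per draw.
#' @export
sample_environments <- function(niche, n, seed) {
  stopifnot(inherits(niche, "breed_niche"))
  if (!is.numeric(n) || n < 1) stop_ng("n must be >= 1")
  w <- niche_weights(niche)
  with_seed(derive_seed(seed, "environments"), {
    which_sub <- sample.int(length(w), n, replace = TRUE, prob = w)
    out <- vector("list", n)
    for (u in seq_along(w)) {
      idx <- which(which_sub == u)
      if (length(idx)) out[idx] <- sample_from_subniche(niche$subniches[[u]], length(idx))
    }
    attr(out, "subniche") <- names(niche$subniches)[which_sub]
    out
  })
}

#' Project the size of a niche forward in time
#'
#' Expected number of owner places in the envisaged niche after `t` years,
#' summing per-subniche exponential growth: sum over subniches of
#' `size * exp(growth_rate * t)`.
#'
#' @param niche a [breed_niche].
#' @param t horizon in years (>= 0).
#' @return Projected niche size (count, real-valued).
#' @examples
#' # a single declining subniche halves roughly every 7 years at g = -0.1
#' @export
project_niche_size <- function(niche, t) {
  stopifnot(inherits(niche, "breed_niche"))
  if (!is.numeric(t) || length(t) != 1L || t < 0) stop_ng("t must be >= 0")
  sizes <- vapply(niche$subniches, `[[`, numeric(1), "size")
  rates <- vapply(niche$subniches, `[[`, numeric(1), "growth_rate")
  sum(sizes * exp(rates * t))
}

#' Drop endangered subniches from a niche
#'
#' Removes subniches whose projected size at the planning horizon falls
#' below a threshold; such subniches are expected to vanish and should not
#' shape the breeding goal. Order of remaining subniches is preserved.
#'
#' @param niche a [breed_niche].
#' @param horizon planning horizon in years (> 0).
#' @param threshold minimum projected size to keep a subniche (>= 0).
#' @return A [breed_niche] containing only viable subniches.
#' @export
drop_endangered_subniches <- function(niche, horizon, threshold) {
  stopifnot(inherits(niche, "breed_niche"))
  if (!is.numeric(horizon) || horizon <= 0) stop_ng("horizon must be > 0")
  if (!is.numeric(threshold) || threshold < 0) stop_ng("threshold must be >= 0")
  keep <- vapply(niche$subniches, function(s) {
    s$size * exp(s$growth_rate * horizon) >= threshold
  }, logical(1))
  if (!any(keep)) {
    stop_ng("no viable subniche: every subniche falls below the size threshold ",
            "at the planning horizon")
  }
  breed_niche(unname(niche$subniches[keep]), niche$producer_env)
}
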