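#' Trait space of a breed
#'
#' Defines the K traits of the phenotype space, each assigned to one of the
#' six trait categories (production, performance, conformation/movement,
#' behaviour, functional, supplemental) with a measurement unit.
#'
#' @param traits a data.frame with columns `label`, `category`, `unit`.
#' @return An object of class `trait_space` (validated data.frame).
#' @export
trait_space <- function(traits) {
  traits <- as.data.frame(traits, stringsAsFactors = FALSE)
  needed <- c("label", "category", "unit")
  if (!all(needed %in% names(traits))) {
    stop_ng("traits must have columns: ", paste(needed, collapse = ", "))
  }
  if (nrow(traits) < 1L) stop_ng("at least one trait is required")
  if (anyDuplicated(traits$label)) stop_ng("trait labels must be unique")
  cats <- c("production", "performance", "conformation_movement",
            "behaviour", "functional", "supplemental")
  bad <- setdiff(traits$category, cats)
  if (length(bad)) {
    stop_ng("unknown trait category: ", paste(bad, collapse = ", "),
            " (expected one of ", paste(cats, collapse = ", "), ")")
  }
  structure(traits[needed], class = c("trait_space", "data.frame"))
}

trait_labels <- function(ts) ts$label

#' Genetic and phenotypic covariance parameters
#'
#' @param G K x K genetic (co)variance matrix, symmetric positive
#'   semidefinite, with trait labels as dimnames.
#' @param P K x K phenotypic (co)variance matrix, symmetric positive
#'   definite; per-trait genetic variance must not exceed phenotypic variance
#'   (heritability at most 1).
#' @return An object of class `genetic_parameters`.
#' @export
genetic_parameters <- function(G, P) {
  if (!is_symmetric_matrix(G)) stop_ng("G must be a symmetric matrix")
  if (!is_symmetric_matrix(P)) stop_ng("P must be a symmetric matrix")
  if (!identical(dim(G), dim(P))) stop_ng("G and P must have the same dimension")
  if (is.null(rownames(G)) || is.null(rownames(P))) {
    stop_ng("G and P must carry trait labels as dimnames")
  }
  if (!identical(rownames(G), rownames(P))) stop_ng("G and P trait labels disagree")
  evP <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(evP) <= 1e-10 * max(evP)) stop_ng("P must be positive definite")
  evG <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(evG) < -1e-8 * max(abs(evG), 1)) stop_ng("G must be positive semidefinite")
  if (any(diag(G) > diag(P) + 1e-12)) {
    stop_ng("diag(G) must not exceed diag(P): heritability > 1 for ",
            paste(rownames(G)[diag(G) > diag(P) + 1e-12], collapse = ", "))
  }
  structure(list(G = G, P = P), class = "genetic_parameters")
}

#' Current state of a breed
#'
#' Holds the trait space, the current trait means, the genetic parameters,
#' an optional linear reaction norm (K x M matrix mapping M declared
#' physical-environment variables to mean shifts), and an optional current
#' breeding goal.
#'
#' @param trait_space a [trait_space].
#' @param mu_c named K-vector of current trait means.
#' @param genetics a [genetic_parameters] on the same traits.
#' @param reaction_norm optional K x M matrix; rownames are trait labels,
#'   colnames are influencing-variable labels. `NULL` means trait means are
#'   environment-independent.
#' @param current_goal optional named K-vector.
#' @return An object of class `breed_state`.
#' @export
breed_state <- function(trait_space, mu_c, genetics, reaction_norm = NULL,
                        current_goal = NULL) {
  stopifnot(inherits(trait_space, "trait_space"),
            inherits(genetics, "genetic_parameters"))
  labs <- trait_labels(trait_space)
  mu_c <- assert_named_numeric(mu_c, "mu_c")
  if (!identical(sort(names(mu_c)), sort(labs))) {
    stop_ng("mu_c labels must match the trait space exactly")
  }
  mu_c <- mu_c[labs]
  if (!identical(rownames(genetics$G), labs)) {
    stop_ng("genetic parameters must be labelled by the trait-space traits ",
            "in the same order")
  }
  if (!is.null(reaction_norm)) {
    if (!is.matrix(reaction_norm) || nrow(reaction_norm) != length(labs)) {
      stop_ng("reaction_norm must be a K x M matrix")
    }
    if (is.null(rownames(reaction_norm)) ||
        !identical(rownames(reaction_norm), labs)) {
      stop_ng("reaction_norm rownames must equal the trait labels")
    }
    if (is.null(colnames(reaction_norm)) || anyDuplicated(colnames(reaction_norm))) {
      stop_ng("reaction_norm needs unique influencing-variable colnames")
    }
  }
  if (!is.null(current_goal)) {
    current_goal <- assert_named_numeric(current_goal, "current_goal")
    if (!identical(sort(names(current_goal)), sort(labs))) {
      stop_ng("current_goal labels must match the trait space")
    }
    current_goal <- current_goal[labs]
  }
  structure(list(trait_space = trait_space, mu_c = mu_c, genetics = genetics,
                 reaction_norm = reaction_norm, current_goal = current_goal),
            class = "breed_state")
}

#' @export
print.breed_state <- function(x, ...) {
  cat("<breed_state> K =", length(x$mu_c), "traits\n")
  print(data.frame(trait = names(x$mu_c), mean = x$mu_c,
                   h2 = round(diag(x$genetics$G) / diag(x$genetics$P), 3),
                   row.names = NULL))
  if (!is.null(x$reaction_norm)) {
    cat("reaction norm on:", paste(colnames(x$reaction_norm), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Expected trait means in a given environment
#'
#' The environment-dependent mean vector: the current means shifted by the
#' linear reaction norm applied to the declared influencing variables of the
#' environment. Without a reaction norm the means are constant.
#'
#' @param state a [breed_state].
#' @param e an [owner_environment].
#' @param mu optional named K-vector overriding the stored current means
#'   (used when evaluating putative breeding goals).
#' @return Named K-vector of trait means.
#' @export
mean_in_environment <- function(state, e, mu = NULL) {
  stopifnot(inherits(state, "breed_state"), inherits(e, "owner_environment"))
  base <- if (is.null(mu)) state$mu_c else mu[names(state$mu_c)]
  rn <- state$reaction_norm
  if (is.null(rn)) return(base)
  vals <- iv_get(e$influencing, colnames(rn), "reaction-norm variable")
  base + drop(rn %*% vals)
}

#' Sample phenotypes of animals kept in an environment
#'
#' Draws n i.i.d. multivariate Gaussian phenotype vectors with mean
#' [mean_in_environment()] and the phenotypic covariance P.
#'
#' @inheritParams mean_in_environment
#' @param n number of animals (>= 1).
#' @param seed integer seed.
#' @return An `n x K` matrix with trait labels as colnames.
#' @export
sample_phenotypes <- function(state, e, n, seed, mu = NULL) {
  if (!is.numeric(n) || n < 1) stop_ng("n must be >= 1")
  m <- mean_in_environment(state, e, mu = mu)
  P <- state$genetics$P
  with_seed(derive_seed(seed, "phenotypes"), {
    y <- MASS::mvrnorm(n, mu = m, Sigma = P)
    if (n == 1L) y <- matrix(y, nrow = 1)
    colnames(y) <- names(m)
    y
  })
}
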