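#' Simulate a binary discrete-choice experiment
#'
#' Generates forced-choice tasks between two animal trait profiles drawn
#' uniformly from a per-trait design box (profiles approximately evenly
#' distributed over the search area), with choice probabilities from a
#' binary logit on the merit difference:
#' `P(choose A) = logistic((U(y_A) - U(y_B)) / scale)`.
#' The utility U is the total merit in the given environment, or (for
#' estimating the producer/owner/consumer weights) the full adaptedness
#' combination `alpha_p TM_ep + alpha_n TM_e + alpha_c PQ`.
#'
#' @param params a [merit_params] (the data-generating truth).
#' @param e the respondents' [owner_environment].
#' @param box design box: data.frame with columns `trait`, `lower`, `upper`.
#' @param n number of choice tasks (>= 1).
#' @param scale positive logit scale (noise) parameter.
#' @param seed integer seed.
#' @param niche optional [breed_niche], required for `utility = "adaptedness"`.
#' @param utility `"total_merit"` (default) or `"adaptedness"`.
#' @param vary optional character vector of traits varied between the two
#'   options of a task. All other traits are drawn once per task and shared
#'   by both options, so they cancel from the utility difference -- the
#'   design for estimating one merit function at a time (choice experiments
#'   handle only a few attributes per survey). Default: vary everything.
#' @return A `choice_dataset`: data.frame with columns `respondent`,
#'   `A_<trait>`, `B_<trait>`, `chosen`, plus design metadata in attributes
#'   (`box`, `scale`, `seed`, `environment`, `utility`).
#' @export
simulate_choice_experiment <- function(params, e, box, n, scale = 1, seed = 1L,
                                       niche = NULL,
                                       utility = c("total_merit", "adaptedness"),
                                       vary = NULL) {
  utility <- match.arg(utility)
  if (!is.numeric(n) || n < 1) stop_ng("n must be >= 1")
  if (!is.numeric(scale) || scale <= 0) stop_ng("scale must be > 0")
  box <- as.data.frame(box, stringsAsFactors = FALSE)
  stopifnot(all(c("trait", "lower", "upper") %in% names(box)))
  if (any(box$upper < box$lower)) stop_ng("box upper < lower")
  vary <- vary %||% box$trait
  if (!all(vary %in% box$trait)) stop_ng("`vary` names traits not in the box")
  weighted <- unique(c(names(params$profit$base), names(params$profit$mult),
                       names(params$quality$q), names(params$performance$omega),
                       names(params$emotional$omega), names(params$altruistic$omega),
                       names(params$easygoing$omega)))
  degenerate <- box$trait[box$trait %in% intersect(weighted, vary) &
                            box$upper - box$lower <= 0]
  if (length(degenerate)) {
    stop_ng("degenerate design box (zero width) for weighted trait(s): ",
            paste(degenerate, collapse = ", "))
  }
  if (utility == "adaptedness" && is.null(niche)) {
    stop_ng("utility = \"adaptedness\" requires `niche`")
  }
  K <- nrow(box)
  uval <- function(Y) {
    switch(utility,
      total_merit = total_merit_rows(Y, e, params),
      adaptedness = {
        a <- params$weights$alpha
        a[["p"]] * total_merit_rows(Y, niche$producer_env, params) +
          a[["n"]] * total_merit_rows(Y, e, params) +
          a[["c"]] * product_quality_rows(Y, params)
      })
  }
  with_seed(derive_seed(seed, "choices"), {
    draw <- function() {
      m <- matrix(stats::runif(n * K, rep(box$lower, each = n), rep(box$upper, each = n)),
                  nrow = n)
      colnames(m) <- box$trait
      m
    }
    A <- draw()
    B <- draw()
    shared <- setdiff(box$trait, vary)
    if (length(shared)) B[, shared] <- A[, shared]
    p_a <- stats::plogis((uval(A) - uval(B)) / scale)
    chosen <- ifelse(stats::runif(n) < p_a, "A", "B")
    out <- data.frame(respondent = seq_len(n))
    for (tr in box$trait) out[[paste0("A_", tr)]] <- A[, tr]
    for (tr in box$trait) out[[paste0("B_", tr)]] <- B[, tr]
    out$chosen <- chosen
    attr(out, "box") <- box
    attr(out, "scale") <- scale
    attr(out, "seed") <- as.integer(seed)
    attr(out, "environment") <- e
    attr(out, "utility") <- utility
    attr(out, "vary") <- vary
    class(out) <- c("choice_dataset", "data.frame")
    out
  })
}

choice_profiles <- function(data) {
  traits <- attr(data, "box")$trait
  A <- as.matrix(data[paste0("A_", traits)])
  B <- as.matrix(data[paste0("B_", traits)])
  colnames(A) <- colnames(B) <- traits
  list(A = A, B = B, y = as.integer(data$chosen == "A"), traits = traits)
}

# negative binary-logit log-likelihood for utility difference du
nll_logit <- function(du, y) {
  # numerically stable -sum(y*log(p) + (1-y)*log(1-p)), p = plogis(du)
  sum(log1p(exp(-abs(du))) + pmax(du, 0) - y * du)
}

#' Fit merit-function parameters from choice data by maximum likelihood
#'
#' Maximizes the binary-logit likelihood of a choice dataset in the
#' parameters of one reward-merit component. For fixed optima the weights
#' omega enter the utility linearly through |y - opt| features, so the inner
#' problem is an ordinary logistic regression; the optima are found by an
#' outer derivative-free (Nelder-Mead, with a coarse grid initialization)
#' search over the profile likelihood, which handles the kinks of |.| in
#' opt. Additive constants (tau_max) cancel from choice differences and are
#' not identifiable, hence not estimated. Standard errors come from the
#' observed information (numeric Hessian at the MLE).
#'
#' @param data a `choice_dataset` from [simulate_choice_experiment()].
#' @param structure list with `component` ("performance", "emotional" or
#'   "altruistic"), `traits` (labels whose omega/opt are estimated),
#'   optional `linear_traits` (labels entering the utility linearly, e.g.
#'   profit-relevant traits), optional `fit_opt` (default TRUE) and
#'   `opt_fixed` (named vector used when `fit_opt = FALSE`).
#' @param init optional named vector of starting optima.
#' @param tol convergence tolerance of the outer search.
#' @param max_iter outer iteration cap; exceeding it flags non-convergence
#'   instead of raising an error.
#' @param response_weight the product `lambda * w_component` that multiplies
#'   this reward in the utility that generated the data; recovered omegas
#'   are rescaled by `scale / response_weight` to the merit scale.
#' @return An object of class `merit_fit`: estimates `omega`, `opt`,
#'   `linear`, standard errors `se`, `loglik`, and `converged` /
#'   `separation` flags.
#' @export
fit_merit_params <- function(data, structure, init = NULL, tol = 1e-8,
                             max_iter = 500L, response_weight = 1) {
  stopifnot(inherits(data, "choice_dataset"))
  if (nrow(data) == 0L) stop_ng("choice dataset is empty")
  traits <- structure$traits
  linear_traits <- structure$linear_traits %||% character(0)
  fit_opt <- structure$fit_opt %||% TRUE
  if (length(traits) + length(linear_traits) == 0L) {
    stop_ng("at least one free parameter is required")
  }
  cp <- choice_profiles(data)
  box <- attr(data, "box")
  scale <- attr(data, "scale") %||% 1
  lo <- stats::setNames(box$lower, box$trait)[traits]
  hi <- stats::setNames(box$upper, box$trait)[traits]

  feats <- function(opt) {
    # utility-difference design matrix for the inner logistic regression
    X <- matrix(0, nrow(cp$A), length(traits) + length(linear_traits))
    j <- 0L
    for (k in seq_along(traits)) {
      tr <- traits[k]
      X[, j + k] <- abs(cp$B[, tr] - opt[k]) - abs(cp$A[, tr] - opt[k])
    }
    j <- length(traits)
    for (k in seq_along(linear_traits)) {
      tr <- linear_traits[k]
      X[, j + k] <- cp$A[, tr] - cp$B[, tr]
    }
    X
  }
  inner_fit <- function(opt) {
    X <- feats(opt)
    fit <- suppressWarnings(
      stats::glm.fit(X, cp$y, family = stats::binomial(), intercept = FALSE))
    list(coef = fit$coefficients, nll = nll_logit(drop(X %*% fit$coefficients), cp$y),
         converged = fit$converged, X = X)
  }
  profile_nll <- function(opt) inner_fit(pmin(pmax(opt, lo), hi))$nll

  outer_evals <- 0L
  if (fit_opt && length(traits)) {
    mid <- (lo + hi) / 2
    starts <- list(init %||% mid)
    # coarse grid over each opt dimension to avoid local stalls at kinks
    grid_pts <- lapply(seq_along(traits), function(k) seq(lo[k], hi[k], length.out = 5))
    grid <- as.matrix(expand.grid(grid_pts))
    if (nrow(grid) <= 125) {
      gvals <- apply(grid, 1, profile_nll)
      ord <- order(gvals)[seq_len(min(3, nrow(grid)))]
      starts <- c(starts, lapply(ord, function(i) stats::setNames(grid[i, ], traits)))
    }
    best <- NULL
    conv_outer <- FALSE
    for (st in starts) {
      if (length(traits) == 1L) {
        op <- stats::optim(st, profile_nll, method = "Brent",
                           lower = lo, upper = hi,
                           control = list(maxit = max_iter))
      } else {
        op <- stats::optim(st, profile_nll, method = "Nelder-Mead",
                           control = list(maxit = max_iter, reltol = tol))
      }
      outer_evals <- outer_evals + (op$counts[1] %||% 0)
      if (is.null(best) || op$value < best$value) {
        best <- op
        conv_outer <- op$convergence == 0
      }
    }
    opt_hat <- pmin(pmax(best$par, lo), hi)
    names(opt_hat) <- traits
  } else {
    opt_hat <- (structure$opt_fixed %||% stats::setNames((lo + hi) / 2, traits))[traits]
    conv_outer <- TRUE
  }

  fin <- inner_fit(opt_hat)
  theta <- fin$coef
  du <- drop(fin$X %*% theta)
  p_hat <- stats::plogis(du)
  separation <- all((p_hat > 0.5) == (cp$y == 1L)) &&
    (min(pmax(p_hat, 1 - p_hat)) > 0.9999 || max(abs(theta)) > 50)

  omega_hat <- stats::setNames(theta[seq_along(traits)] * scale / response_weight, traits)
  linear_hat <- if (length(linear_traits)) {
    stats::setNames(theta[length(traits) + seq_along(linear_traits)] * scale,
                    linear_traits)
  } else numeric(0)

  se <- list(omega = stats::setNames(rep(NA_real_, length(traits)), traits),
             opt = stats::setNames(rep(NA_real_, length(traits)), traits),
             linear = stats::setNames(rep(NA_real_, length(linear_traits)), linear_traits))
  if (!separation) {
    full_nll <- function(par) {
      th <- par[seq_along(theta)]
      op <- if (fit_opt && length(traits)) {
        par[length(theta) + seq_along(traits)]
      } else opt_hat
      nll_logit(drop(feats(op) %*% th), cp$y)
    }
    par_hat <- c(theta, if (fit_opt && length(traits)) opt_hat)
    H <- tryCatch(pracma::hessian(full_nll, par_hat), error = function(e) NULL)
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(is.finite(diag(V))) && all(diag(V) > 0)) {
      sd_all <- sqrt(diag(V))
      se$omega[] <- sd_all[seq_along(traits)] * scale / response_weight
      if (length(linear_traits)) {
        se$linear[] <- sd_all[length(traits) + seq_along(linear_traits)] * scale
      }
      if (fit_opt && length(traits)) {
        se$opt[] <- sd_all[length(theta) + seq_along(traits)]
      }
    } else {
      # joint information is singular when an omega is (near) zero: the
      # likelihood is flat in that trait's optimum. Fall back to the
      # conditional (fixed-opt) logistic-regression SEs for the linear
      # coefficients; optimum SEs stay NA where not identified.
      W <- p_hat * (1 - p_hat)
      I_theta <- crossprod(fin$X * sqrt(W))
      V_theta <- tryCatch(solve(I_theta), error = function(e) NULL)
      if (!is.null(V_theta) && all(diag(V_theta) > 0)) {
        sd_th <- sqrt(diag(V_theta))
        se$omega[] <- sd_th[seq_along(traits)] * scale / response_weight
        if (length(linear_traits)) {
          se$linear[] <- sd_th[length(traits) + seq_along(linear_traits)] * scale
        }
      }
    }
  }
  structure(list(omega = omega_hat, opt = opt_hat, linear = linear_hat,
                 se = se, loglik = -fin$nll,
                 converged = isTRUE(conv_outer) && isTRUE(fin$converged),
                 separation = separation, scale = scale,
                 response_weight = response_weight,
                 component = structure$component %||% "performance"),
            class = "merit_fit")
}

#' @export
print.merit_fit <- function(x, ...) {
  cat("<merit_fit>", x$component, "component; logLik =", signif(x$loglik, 6),
      if (!x$converged) "(NOT converged)", if (x$separation) "(separation)", "\n")
  print(data.frame(trait = names(x$omega), omega = x$omega,
                   se_omega = x$se$omega, opt = x$opt, se_opt = x$se$opt,
                   row.names = NULL))
  invisible(x)
}

#' Estimate the producer/owner/consumer weights from choice data
#'
#' Fits a binary logit whose utility features are the three component merits
#' of each profile (producer total merit, owner total merit, product
#' quality) and normalizes the nonnegative coefficients to the simplex,
#' giving estimates of (alpha_p, alpha_n, alpha_c).
#'
#' @param datasets a `choice_dataset` or list of them (all simulated with
#'   `utility = "adaptedness"` or at least carrying an environment).
#' @param params a [merit_params] providing the (known) component merit
#'   functions.
#' @param niche a [breed_niche] for the producer environment.
#' @param tol tolerance used in the collinearity check.
#' @return list with `alpha` (length 3, sums to 1), `identifiable` flag and
#'   `loglik`.
#' @export
fit_alpha_weights <- function(datasets, params, niche, tol = 1e-8) {
  if (inherits(datasets, "choice_dataset")) datasets <- list(datasets)
  Xs <- list()
  ys <- list()
  for (d in datasets) {
    cp <- choice_profiles(d)
    e <- attr(d, "environment")
    featl <- function(Y) cbind(total_merit_rows(Y, niche$producer_env, params),
                               total_merit_rows(Y, e, params),
                               product_quality_rows(Y, params))
    Xs[[length(Xs) + 1L]] <- featl(cp$A) - featl(cp$B)
    ys[[length(ys) + 1L]] <- cp$y
  }
  X <- do.call(rbind, Xs)
  y <- unlist(ys)
  sv <- svd(scale(X, center = FALSE, scale = FALSE))$d
  identifiable <- length(sv) == 3 && sv[3] > max(sv) * 1e-7
  if (!identifiable) {
    warning("weights not identifiable: component merits are collinear",
            call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(), intercept = FALSE))
  co <- fit$coefficients
  co[!is.finite(co)] <- 0   # aliased (collinear) features
  kappa <- pmax(co, 0)
  if (sum(kappa) <= tol) {
    alpha <- c(p = 1, n = 1, c = 1) / 3
  } else {
    alpha <- stats::setNames(kappa / sum(kappa), c("p", "n", "c"))
  }
  list(alpha = alpha, identifiable = identifiable,
       loglik = -nll_logit(drop(X %*% fit$coefficients), y))
}
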