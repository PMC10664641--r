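# the package computes utilities internally; the tests recompute them
# through the exported scalar API to stay independent
total_merit_rows_test <- function(Y, e, params) {
  apply(Y, 1, function(y) total_merit(y, e, params))
}

test_that("choice simulation follows the binary logit on merit differences", {
  ts <- fx_traits(2)
  e <- fx_env()
  params <- fx_params(2, omega = c(t1 = 1.5), opt = c(t1 = 0.7))
  box <- data.frame(trait = c("t1", "t2"), lower = c(-2, -2), upper = c(3, 3))

  dat <- simulate_choice_experiment(params, e, box, n = 500, scale = 1, seed = 1)
  expect_s3_class(dat, "choice_dataset")
  expect_equal(nrow(dat), 500)
  expect_true(all(dat$A_t1 >= -2 & dat$A_t1 <= 3))
  expect_identical(dat, simulate_choice_experiment(params, e, box, n = 500,
                                                   scale = 1, seed = 1))

  # near-deterministic choice in the scale -> 0 limit
  dat0 <- simulate_choice_experiment(params, e, box, n = 2000, scale = 1e-9,
                                     seed = 2)
  cp <- nichegoal:::choice_profiles(dat0)
  better_a <- total_merit_rows_test(cp$A, e, params) >
    total_merit_rows_test(cp$B, e, params)
  expect_true(all((cp$y == 1L) == better_a))

  # zero-width box on a weighted trait is degenerate
  box_bad <- data.frame(trait = c("t1", "t2"), lower = c(1, -2), upper = c(1, 3))
  expect_error(simulate_choice_experiment(params, e, box_bad, n = 10),
               "degenerate")

  # calibration: empirical choice frequencies per merit-difference bin match
  # the logistic curve (Hosmer-Lemeshow-style chi-square, alpha = 0.01)
  datc <- simulate_choice_experiment(params, e, box, n = 1e4, scale = 1, seed = 3)
  cpc <- nichegoal:::choice_profiles(datc)
  du <- total_merit_rows_test(cpc$A, e, params) -
    total_merit_rows_test(cpc$B, e, params)
  p <- stats::plogis(du)
  bins <- cut(p, breaks = stats::quantile(p, seq(0, 1, 0.1)),
              include.lowest = TRUE)
  obs <- tapply(cpc$y, bins, sum)
  expe <- tapply(p, bins, sum)
  nb <- tapply(p, bins, length)
  chi2 <- sum((obs - expe)^2 / (expe * (1 - expe / nb)))
  expect_gt(stats::pchisq(chi2, df = 8, lower.tail = FALSE), 0.01)
})

test_that("maximum likelihood recovers omega and the optimum", {
  ts <- fx_traits(2)
  e <- fx_env()
  box <- data.frame(trait = c("t1", "t2"), lower = c(-2, -2), upper = c(3, 3))
  params <- fx_params(2, omega = c(t1 = 1.5), opt = c(t1 = 0.7))

  dat <- simulate_choice_experiment(params, e, box, n = 5000, scale = 1, seed = 11)
  fit <- fit_merit_params(dat, list(component = "performance", traits = "t1"))
  expect_true(fit$converged)
  expect_false(fit$separation)
  expect_lt(abs(fit$omega[["t1"]] - 1.5), 3 * fit$se$omega[["t1"]])
  expect_lt(abs(fit$opt[["t1"]] - 0.7), 3 * fit$se$opt[["t1"]])

  # log-likelihood at the truth never exceeds the MLE value
  cp <- nichegoal:::choice_profiles(dat)
  du_true <- (abs(cp$B[, "t1"] - 0.7) - abs(cp$A[, "t1"] - 0.7)) * 1.5
  ll_true <- -nichegoal:::nll_logit(du_true, cp$y)
  expect_gte(fit$loglik, ll_true)

  # a trait simulated with omega = 0 is estimated near zero
  params0 <- fx_params(2, omega = c(t1 = 1.5, t2 = 0), opt = c(t1 = 0.7, t2 = 0))
  dat0 <- simulate_choice_experiment(params0, e, box, n = 5000, scale = 1,
                                     seed = 12)
  fit0 <- fit_merit_params(dat0, list(component = "performance",
                                      traits = c("t1", "t2")))
  expect_lt(abs(fit0$omega[["t2"]]), 2 * fit0$se$omega[["t2"]])
})

test_that("estimates are consistent: error shrinks when n doubles", {
  e <- fx_env()
  box <- data.frame(trait = c("t1", "t2"), lower = c(-2, -2), upper = c(3, 3))
  params <- fx_params(2, omega = c(t1 = 1.5), opt = c(t1 = 0.7))
  err <- function(n, seeds) {
    sapply(seeds, function(s) {
      dat <- simulate_choice_experiment(params, e, box, n = n, scale = 1,
                                        seed = s)
      fit <- fit_merit_params(dat, list(component = "performance", traits = "t1"))
      c(abs(fit$omega[["t1"]] - 1.5), abs(fit$opt[["t1"]] - 0.7))
    })
  }
  e_small <- err(1000, 1:8)
  e_big <- err(2000, 1:8)
  expect_lt(stats::median(e_big[1, ]), stats::median(e_small[1, ]))
  expect_lt(stats::median(e_big[2, ]), stats::median(e_small[2, ]))
})

test_that("tau_max is not identifiable and does not affect the data", {
  e <- fx_env()
  box <- data.frame(trait = c("t1", "t2"), lower = c(-2, -2), upper = c(3, 3))
  p_a <- fx_params(2, tau_max = 10)
  p_b <- fx_params(2, tau_max = 1000)
  d_a <- simulate_choice_experiment(p_a, e, box, n = 1000, scale = 1, seed = 5)
  d_b <- simulate_choice_experiment(p_b, e, box, n = 1000, scale = 1, seed = 5)
  expect_identical(as.data.frame(d_a), as.data.frame(d_b))
})

test_that("alpha weights are recovered on the simplex", {
  ts <- fx_traits(2)
  e <- owner_environment(desire_profile(),
                         influencing_variables(physical = c(feed = 0)))
  ep <- owner_environment(desire_profile(),
                          influencing_variables(physical = c(feed = 1)))
  niche <- breed_niche(list(subniche("s", 100, 0,
                                     atoms = list(list(environment = e, prob = 1)))), ep)
  box <- data.frame(trait = c("t1", "t2"), lower = c(-2, -2), upper = c(3, 3))
  mk <- function(alpha) merit_params(
    performance = list(omega = c(t1 = 1), opt = c(t1 = 0), tau_max = 5),
    profit = list(base = c(t2 = 1), mult = list(t1 = c(feed = 0.5))),
    quality = list(q = c(t1 = 0.5, t2 = -0.8)),
    weights = list(lambda = 1, w = c(1, 0, 0), alpha = alpha),
    traits = ts)

  p_n <- mk(c(0, 1, 0))
  dat <- simulate_choice_experiment(p_n, e, box, n = 5000, scale = 1, seed = 13,
                                    niche = niche, utility = "adaptedness")
  fa <- fit_alpha_weights(dat, p_n, niche)
  expect_true(fa$identifiable)
  expect_equal(sum(fa$alpha), 1, tolerance = 1e-9)
  expect_true(all(fa$alpha >= 0))
  expect_gte(fa$alpha[["n"]], 0.9)

  # moving the weight to the consumer component moves the estimate with it
  p_c <- mk(c(0, 0, 1))
  dat_c <- simulate_choice_experiment(p_c, e, box, n = 5000, scale = 0.5,
                                      seed = 14, niche = niche,
                                      utility = "adaptedness")
  fc <- fit_alpha_weights(dat_c, p_c, niche)
  expect_gt(fc$alpha[["c"]], fc$alpha[["p"]])
  expect_gt(fc$alpha[["c"]], 0.5)
})
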