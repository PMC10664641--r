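test_that("profit merit evaluates the linear profit equation", {
  ts <- fx_traits(2)
  v <- influencing_variables(market = c(milk_price = 0.4))

  p0 <- merit_params(traits = ts)
  expect_equal(profit_merit(c(t1 = 3, t2 = -2), v, p0), 0)

  p1 <- merit_params(profit = list(base = c(t1 = 2, t2 = -1), fixed = -3),
                     traits = ts)
  expect_equal(profit_merit(c(t1 = 4, t2 = 2), v, p1), 2 * 4 - 1 * 2 - 3)

  # milk-price multiplier: coefficient = price, contribution = 0.4 * 8000
  p2 <- merit_params(profit = list(mult = list(t1 = c(milk_price = 1))),
                     traits = ts)
  expect_equal(profit_merit(c(t1 = 8000, t2 = 0), v, p2), 3200)

  # referenced variable absent from v
  expect_error(profit_merit(c(t1 = 1, t2 = 0), influencing_variables(), p2),
               "milk_price")
})

test_that("reward merits peak at the optima and never exceed tau_max", {
  ts <- fx_traits(2)
  p <- merit_params(performance = list(omega = c(t1 = 1, t2 = 2),
                                       opt = c(t1 = 0, t2 = 0), tau_max = 10),
                    emotional = list(omega = c(t1 = 0.5), opt = c(t1 = 8),
                                     tau_max = 5),
                    altruistic = list(omega = c(t2 = 1), opt = c(t2 = 0),
                                      tau_max = 3, breed_id = "b"),
                    traits = ts)
  at_opt <- c(t1 = 0, t2 = 0)
  expect_equal(performance_merit(at_opt, p), 10)
  expect_equal(performance_merit(c(t1 = 1, t2 = 1), p), 10 - 1 - 2)
  expect_equal(emotional_merit(c(t1 = 6, t2 = 0), p), 5 - 0.5 * 2)
  expect_equal(altruistic_merit(c(t1 = 0, t2 = 0.5), p), 2.5)

  # moving away from the optimum never increases the value
  set.seed(1)
  for (i in 1:20) {
    y <- c(t1 = rnorm(1), t2 = rnorm(1))
    expect_lte(performance_merit(y, p), 10)
    y_farther <- y + sign(y) * abs(rnorm(2))
    expect_lte(performance_merit(y_farther, p), performance_merit(y, p))
  }

  # empty altruistic component with tau_max = 0 is constantly zero
  p0 <- merit_params(traits = ts)
  expect_equal(altruistic_merit(c(t1 = 99, t2 = -5), p0), 0)

  # all-zero emotional weights give tau_max for any y
  pz <- merit_params(emotional = list(omega = c(t1 = 0), opt = c(t1 = 0),
                                      tau_max = 5), traits = ts)
  expect_equal(emotional_merit(c(t1 = 1e6, t2 = 0), pz), 5)
})

test_that("easygoing cost uses only perceived costs above the monetary cost", {
  ts <- fx_traits(3)
  # perceived equal monetary: zero cost
  p_eq <- merit_params(easygoing = list(omega = c(t1 = 1), omega_mon = c(t1 = 1)),
                       traits = ts)
  expect_equal(easygoing_cost(c(t1 = 5, t2 = 0, t3 = 0), p_eq), 0)

  p <- merit_params(easygoing = list(omega = c(t1 = 2), omega_mon = c(t1 = 0.5)),
                    traits = ts)
  expect_equal(easygoing_cost(c(t1 = 4, t2 = 0, t3 = 0), p), 1.5 * 4)

  # a trait with omega < omega_mon is excluded and changes nothing
  p2 <- merit_params(easygoing = list(omega = c(t1 = 2, t2 = 0.1),
                                      omega_mon = c(t1 = 0.5, t2 = 3)),
                     traits = ts)
  expect_equal(easygoing_cost(c(t1 = 4, t2 = 100, t3 = 0), p2), 1.5 * 4)
})

test_that("total merit composes reward, cost and profit with lambda", {
  ts <- fx_traits(2)
  e <- fx_env()
  mk <- function(lambda) merit_params(
    profit = list(base = c(t1 = 1), fixed = 2),
    performance = list(omega = c(t2 = 1), opt = c(t2 = 0), tau_max = 10),
    easygoing = list(omega = c(t1 = 1), omega_mon = c(t1 = 0)),
    weights = list(lambda = lambda, w = c(1, 1, 1), alpha = c(0, 1, 0)),
    traits = ts)
  y <- c(t1 = 1, t2 = 2)

  # lambda = 0 reduces to profit
  expect_equal(total_merit(y, e, mk(0)), 1 + 2)

  # nonmonetary reward: w = (1,0,0)-style sum over components
  p1 <- mk(1)
  r <- nonmonetary_reward(y, p1)
  expect_equal(r, (10 - 2) + 0 + 0)
  expect_equal(total_merit(y, e, p1), 3 + (r - 1))

  # lambda = 0.5 halves the non-monetary contribution
  tm1 <- total_merit(y, e, mk(1))
  tm05 <- total_merit(y, e, mk(0.5))
  expect_equal(tm05 - 3, (tm1 - 3) / 2)

  # nonmonetary weights: zero weights give zero, unit weights sum components
  pz <- merit_params(performance = list(omega = c(t1 = 1), opt = c(t1 = 0),
                                        tau_max = 7),
                     emotional = list(tau_max = 4),
                     altruistic = list(tau_max = 2.5),
                     weights = list(lambda = 1, w = c(0, 0, 0), alpha = c(0, 1, 0)),
                     traits = ts)
  expect_equal(nonmonetary_reward(c(t1 = 0, t2 = 0), pz), 0)
  pw <- merit_params(performance = list(omega = c(t1 = 1), opt = c(t1 = 0),
                                        tau_max = 7),
                     emotional = list(tau_max = 4),
                     altruistic = list(tau_max = 2.5),
                     weights = list(lambda = 1, w = c(1, 1, 1), alpha = c(0, 1, 0)),
                     traits = ts)
  expect_equal(nonmonetary_reward(c(t1 = 0, t2 = 0), pw), 7 + 4 + 2.5)
})

test_that("product quality is a linear score", {
  ts <- fx_traits(2)
  p0 <- merit_params(quality = list(q0 = 4), traits = ts)
  expect_equal(product_quality(c(t1 = 9, t2 = -3), p0), 4)
  p <- merit_params(quality = list(q0 = 0, q = c(t1 = 1, t2 = -1)), traits = ts)
  expect_equal(product_quality(c(t1 = 5, t2 = 2), p), 3)
  p2 <- merit_params(quality = list(q0 = 1, q = c(t1 = 3, t2 = -3)), traits = ts)
  expect_equal(product_quality(c(t1 = 5, t2 = 2), p2) - 1,
               3 * (product_quality(c(t1 = 5, t2 = 2), p) - 0))
})

test_that("monetary trait costs equal the profit gradient", {
  ts <- fx_traits(2)
  v <- influencing_variables(market = c(price = 0.3))
  p <- merit_params(profit = list(base = c(t1 = 2, t2 = -1),
                                  mult = list(t1 = c(price = 10))),
                    traits = ts)
  mu <- c(t1 = 5, t2 = 1)
  cc <- monetary_trait_costs(p, mu, v)
  expect_equal(cc, c(t1 = 2 + 3, t2 = -1))

  # exact Taylor for the linear equation: independent of the expansion point
  expect_equal(monetary_trait_costs(p, mu * 10, v), cc)

  # finite-difference oracle at step 1e-5 agrees to 1e-6
  h <- 1e-5
  fd <- vapply(names(mu), function(k) {
    up <- mu; up[k] <- up[k] + h
    dn <- mu; dn[k] <- dn[k] - h
    (profit_merit(up, v, p) - profit_merit(dn, v, p)) / (2 * h)
  }, numeric(1))
  expect_equal(unname(cc), unname(fd), tolerance = 1e-6)
})

test_that("merit values are invariant to trait-order permutation", {
  ts <- fx_traits(3)
  p <- merit_params(profit = list(base = c(t2 = 1, t3 = -0.5)),
                    performance = list(omega = c(t1 = 1, t3 = 2),
                                       opt = c(t1 = 0.5, t3 = -1), tau_max = 8),
                    easygoing = list(omega = c(t2 = 1), omega_mon = c(t2 = 0)),
                    weights = list(lambda = 1, w = c(1, 0, 0), alpha = c(0, 1, 0)),
                    traits = ts)
  e <- fx_env()
  y <- c(t1 = 0.2, t2 = 1.5, t3 = -0.3)
  y_perm <- y[c("t3", "t1", "t2")]
  expect_equal(total_merit(y_perm, e, p), total_merit(y, e, p))
  expect_equal(performance_merit(y_perm, p), performance_merit(y, p))
})
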