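test_that("the response area realizes the per-generation index response", {
  # K = 1: interval mu_c +/- T i g / sqrt(p)
  G <- matrix(4, 1, 1, dimnames = list("t1", "t1"))
  P <- matrix(9, 1, 1, dimnames = list("t1", "t1"))
  gen <- genetic_parameters(G, P)
  ra <- build_response_area(gen, c(t1 = 10), intensity = 1.5, generations = 4)
  half_width <- 4 * 1.5 * 4 / 3
  expect_equal(nichegoal:::ellipsoid_qf(ra, c(t1 = 10 + half_width)), ra$r^2)
  expect_equal(nichegoal:::ellipsoid_qf(ra, c(t1 = 10 - half_width)), ra$r^2)

  # G = P = I: Euclidean ball of radius T i
  I2 <- diag(2); dimnames(I2) <- list(c("t1", "t2"), c("t1", "t2"))
  gen_i <- genetic_parameters(I2, I2)
  ra_i <- build_response_area(gen_i, c(t1 = 0, t2 = 0), 1, 2)
  expect_equal(nichegoal:::ellipsoid_qf(ra_i, c(t1 = 2, t2 = 0)), 4)
  expect_equal(nichegoal:::ellipsoid_qf(ra_i, c(t1 = sqrt(2), t2 = sqrt(2))), 4)

  # random SPD: 100 random index vectors land exactly on the boundary
  gen_r <- fx_genetics(3, seed = 70)
  Tgen <- 5; i <- 0.8
  ra_r <- build_response_area(gen_r, c(t1 = 0, t2 = 0, t3 = 0), i, Tgen)
  set.seed(71)
  for (k in 1:100) {
    b <- rnorm(3)
    resp <- Tgen * i * drop(gen_r$G %*% b) / sqrt(drop(t(b) %*% gen_r$P %*% b))
    names(resp) <- rownames(gen_r$G)
    qf <- nichegoal:::ellipsoid_qf(ra_r, resp)
    expect_lt(abs(qf - (Tgen * i)^2), 1e-9 * (Tgen * i)^2)
  }

  # singular G is rejected with advice
  G_s <- gen_r$G; G_s[3, ] <- G_s[, 3] <- 0
  gen_s <- genetic_parameters(G_s, gen_r$P)
  expect_error(build_response_area(gen_s, c(t1 = 0, t2 = 0, t3 = 0), 1, 1),
               "singular")
})

test_that("membership labels every violated constraint exactly", {
  pb <- fx_problem(2, seed = 80, search_k = 1)
  set <- pb$set
  mu_c <- pb$state$mu_c
  m0 <- membership(set, mu_c)
  expect_true(m0$member)
  expect_length(m0$violated, 0)

  # one-trait box violation names the trait
  sds <- sqrt(diag(pb$state$genetics$P))
  mu_out <- mu_c + c(2 * sds[1], 0)
  m1 <- membership(set, mu_out)
  expect_false(m1$member)
  expect_true("box:t1" %in% m1$violated)

  # a point exactly on the ellipsoid boundary is a member (closed set)
  gen <- pb$state$genetics
  b <- c(1, 0.5)
  resp <- pb$response
  d <- resp$r * drop(gen$G %*% b) / sqrt(drop(t(b) %*% gen$P %*% b))
  names(d) <- names(mu_c)
  mu_b <- mu_c + d
  sa_wide <- search_area(pb$state, k = 1e6)
  set_wide <- permissible_set(sa_wide, resp)
  expect_equal(nichegoal:::ellipsoid_qf(resp, mu_b), resp$r^2)
  expect_true(membership(set_wide, mu_b)$member)

  # exclusions report their label
  excl <- exclusion_halfspace("floor_t2", c(t2 = 1), mu_c[["t2"]] + 1)
  sa_e <- search_area(pb$state, k = 10, exclusions = list(excl))
  set_e <- permissible_set(sa_e, resp)
  m2 <- membership(set_e, mu_c)
  expect_false(m2$member)
  expect_identical(m2$violated, "floor_t2")

  # box exclusion
  bx <- exclusion_box("bad_zone", lower = mu_c - 0.1, upper = mu_c + 0.1)
  set_b <- permissible_set(search_area(pb$state, k = 10,
                                       exclusions = list(bx)), resp)
  expect_false(membership(set_b, mu_c)$member)
  expect_true(membership(set_b, mu_c + c(0.2, 0.2))$member)
})

test_that("the optimizer attains the analytic optimum of linear objectives", {
  for (s in 1:3) {
    pb <- fx_problem(3, seed = 90 + s, search_k = 1e6)
    set.seed(95 + s)
    a <- rnorm(3)
    obj <- function(mu) sum(a * (mu - pb$state$mu_c))
    res <- optimize_goal(obj, pb$set, seed = 1)
    gen <- pb$state$genetics
    Minv <- gen$G %*% solve(gen$P, gen$G)
    d_star <- drop(pb$response$r * Minv %*% a / sqrt(drop(t(a) %*% Minv %*% a)))
    expect_equal(unname(res$delta_mu), unname(d_star), tolerance = 1e-4)
    expect_equal(res$value, sum(a * d_star), tolerance = 1e-6)
  }
})

test_that("an interior optimum is found exactly at the merit optima", {
  st <- fx_state(2, seed = 100)
  opt <- st$mu_c + c(t1 = 0.3, t2 = -0.4)  # well inside the reachable set
  params <- merit_params(performance = list(omega = c(t1 = 2, t2 = 1),
                                            opt = opt, tau_max = 20),
                         weights = list(lambda = 1, w = c(1, 0, 0),
                                        alpha = c(0, 1, 0)),
                         traits = st$trait_space)
  e <- fx_env()
  niche <- fx_atom_niche(list(e))
  obj <- function(mu) adaptedness_env(st, e, niche, params, mu = mu)$value
  sa <- search_area(st, k = 3)
  ra <- build_response_area(st$genetics, st$mu_c, 1, 5)
  uset <- permissible_set(sa, ra)
  res <- optimize_goal(obj, uset, seed = 2)
  expect_equal(res$mu_i, opt, tolerance = 1e-4)
})

test_that("optimizer matches a brute-force grid and never descends", {
  for (s in 1:3) {
    pb <- fx_problem(2, seed = 110 + s, search_k = 2)
    obj_fun <- nichegoal:::compile_adaptedness_env(pb$state, pb$e, pb$niche,
                                                   pb$params)
    res <- optimize_goal(obj_fun, pb$set, seed = 3)
    # ascent property
    expect_gte(res$value, obj_fun(pb$state$mu_c) - 1e-12)
    # grid oracle on the box, restricted to feasible points
    sa <- pb$set$search
    g1 <- seq(sa$lower[1], sa$upper[1], length.out = 101)
    g2 <- seq(sa$lower[2], sa$upper[2], length.out = 101)
    best_grid <- -Inf
    for (x in g1) for (y in g2) {
      mu <- c(t1 = x, t2 = y)
      if (membership(pb$set, mu)$member) {
        v <- obj_fun(mu)
        if (v > best_grid) best_grid <- v
      }
    }
    # Lipschitz slack: |d obj / d mu_k| bounded by linear + fold weights
    h <- c(diff(g1[1:2]), diff(g2[1:2]))
    L <- rep(0, 2)
    # generous bound: sum of all omegas plus |profit| coefficients per trait
    om <- pb$params$performance$omega
    L[match(names(om), c("t1", "t2"))] <- om
    slack <- sum(L * h / 2) + 1e-9
    expect_gte(res$value, best_grid - slack)
  }
})

test_that("multi-start and single-start agree on the concave objective", {
  pb <- fx_problem(2, seed = 120)
  obj_fun <- nichegoal:::compile_adaptedness_env(pb$state, pb$e, pb$niche,
                                                 pb$params)
  r1 <- optimize_goal(obj_fun, pb$set, n_starts = 1L, seed = 4)
  r5 <- optimize_goal(obj_fun, pb$set, n_starts = 6L, seed = 5)
  expect_equal(r1$value, r5$value, tolerance = 1e-5)
})

test_that("boundary optima satisfy the tangency condition", {
  # smooth strictly concave objective with maximizer outside the ellipsoid:
  # at the constrained optimum the gradient is parallel to the ellipsoid
  # normal (level sets tangential to the boundary)
  pb <- fx_problem(2, seed = 130, search_k = 1e6)
  target <- pb$state$mu_c + c(t1 = 50, t2 = 30)
  obj <- function(mu) -sum((mu - target)^2)
  res <- optimize_goal(obj, pb$set, seed = 6, tol = 1e-8)
  grad <- 2 * (target - res$mu_i)
  normal <- drop(pb$response$M %*% (res$mu_i - pb$state$mu_c))
  cosang <- sum(grad * normal) / sqrt(sum(grad^2) * sum(normal^2))
  expect_lt(abs(1 - cosang), 1e-6)
})

test_that("an empty permissible set aborts with horizon advice", {
  pb <- fx_problem(2, seed = 140, search_k = 10)
  # exclusion covering the whole reachable region
  excl <- exclusion_halfspace("impossible", c(t1 = 1),
                              pb$state$mu_c[["t1"]] + 1e6)
  sa <- search_area(pb$state, k = 10, exclusions = list(excl))
  uset <- permissible_set(sa, pb$response)
  expect_error(optimize_goal(function(mu) 0, uset, seed = 1),
               "extend the planning horizon")
})

test_that("desired-gain index reproduces the requested response direction", {
  # G = P: b proportional to P^-1 delta
  gen_i <- fx_genetics(2, seed = 150)
  gen_eq <- genetic_parameters(gen_i$P, gen_i$P)
  delta <- c(t1 = 1, t2 = 2)
  b <- desired_gain_index(gen_eq, delta)
  b_ref <- drop(solve(gen_eq$P, delta))
  expect_equal(unname(b / b[1]), unname(b_ref / b_ref[1]), tolerance = 1e-10)

  # diagonal case: P = diag(4,4), G = diag(2,2), delta = (1,1)
  D <- diag(c(4, 4)); dimnames(D) <- list(c("t1", "t2"), c("t1", "t2"))
  Gd <- diag(c(2, 2)); dimnames(Gd) <- dimnames(D)
  gen_d <- genetic_parameters(Gd, D)
  bd <- desired_gain_index(gen_d, c(t1 = 1, t2 = 1))
  expect_equal(bd[["t1"]], bd[["t2"]])
  resp_d <- expected_response(gen_d, bd, 1)
  expect_equal(resp_d[["t1"]], resp_d[["t2"]])

  # random SPD: response collinear with delta to < 1e-8 rad, unit variance
  for (s in 1:5) {
    gen <- fx_genetics(3, seed = 160 + s)
    set.seed(170 + s)
    delta <- stats::setNames(rnorm(3), rownames(gen$G))
    b <- desired_gain_index(gen, delta)
    expect_equal(drop(t(b) %*% gen$P %*% b), 1, tolerance = 1e-10)
    resp <- expected_response(gen, b, intensity = 1)
    u <- resp / sqrt(sum(resp^2))
    v <- delta / sqrt(sum(delta^2))
    expect_lt(sqrt(sum((u - v * sum(u * v))^2)), 1e-8)
  }
  expect_error(desired_gain_index(gen_d, c(t1 = 0, t2 = 0)), "no gain")
})

test_that("expected response is scale-invariant and errors on a null index", {
  gen <- fx_genetics(1, seed = 180)
  g <- gen$G[1, 1]; p <- gen$P[1, 1]
  r1 <- expected_response(gen, c(t1 = 1), 2)
  r9 <- expected_response(gen, c(t1 = 9), 2)
  expect_equal(r1, r9)
  expect_equal(unname(r1), 2 * g / sqrt(p))
  expect_error(expected_response(gen, c(t1 = 0), 1), "null index")
})

test_that("Smith-Hazel index matches its closed forms", {
  gen_i <- fx_genetics(2, seed = 190)
  gen_eq <- genetic_parameters(gen_i$P, gen_i$P)
  a <- c(t1 = 2, t2 = -1)
  b <- smith_hazel_index(gen_eq, a)
  expect_equal(unname(b / b[1]), unname(a / a[1]), tolerance = 1e-10)

  D <- diag(c(4, 9)); dimnames(D) <- list(c("t1", "t2"), c("t1", "t2"))
  Gd <- diag(c(2, 3)); dimnames(Gd) <- dimnames(D)
  gen_d <- genetic_parameters(Gd, D)
  bd <- smith_hazel_index(gen_d, c(t1 = 1, t2 = 1))
  expect_equal(unname(bd / bd[1]), c(1, (3 / 9) / (2 / 4)), tolerance = 1e-10)
})

test_that("index genetic variance is decomposed and flagged correctly", {
  gen <- fx_genetics(3, seed = 200)
  set.seed(201)
  b <- stats::setNames(rnorm(3), rownames(gen$G))
  chk <- index_variance_check(gen, b)
  expect_gt(chk$variance, 0)
  expect_identical(chk$flag, "ok")

  # eigen-decomposition identity
  eg <- eigen(gen$G, symmetric = TRUE)
  contrib <- sum(eg$values * drop(t(eg$vectors) %*% b)^2)
  expect_equal(chk$variance, contrib, tolerance = 1e-10)

  # null-space index of a singular G is flagged
  G_s <- tcrossprod(c(1, 0, 0)) * 4
  dimnames(G_s) <- dimnames(gen$G)
  gen_s <- genetic_parameters(G_s, gen$P * 10)
  chk0 <- index_variance_check(gen_s, c(t1 = 0, t2 = 1, t3 = 0))
  expect_equal(chk0$variance, 0)
  expect_identical(chk0$flag, "inadmissible goal risk")
})
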