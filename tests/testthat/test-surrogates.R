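swg_vars <- c("grass", "sheep", "wolves")

# the mechanistic sheep-wolves-grass model written as an integer-order GMA
mech_as_gma <- function(k) {
  M <- swg_stoichiometry()
  M <- cbind(M[, 1], crowd = c(-1L, 0L, 0L), M[, 2:7])
  G <- rbind(c(1, 0, 0), c(2, 0, 0), c(1, 1, 0), c(1, 1, 0),
             c(0, 1, 0), c(0, 1, 1), c(0, 1, 1), c(0, 0, 1))
  surrogate_gma(M, k, G, swg_vars)
}

test_that("GMA with integer kinetic orders reproduces mass action", {
  k <- c(0.2, 0.001, 0.003, 0.002, 0.1, 0.01, 0.005, 0.08)
  mech <- surrogate_mech_swg(k)
  gma <- mech_as_gma(k)
  set.seed(42)
  for (i in 1:50) {
    x <- runif(3, 0.1, 1000)
    expect_equal(rhs_eval(gma, x), rhs_eval(mech, x), tolerance = 1e-12)
  }
  # hand-expanded polynomial at a fixed state
  x <- c(10, 5, 2)
  expect_equal(unname(rhs_eval(mech, x)),
               c(0.2 * 10 - 0.001 * 100 - 0.003 * 50,
                 0.002 * 50 - 0.1 * 5 - 0.01 * 10,
                 0.005 * 10 - 0.08 * 2))
})

test_that("generic mechanistic RHS composes stoichiometry and processes", {
  M <- matrix(c(1, 0, 0, 1), 2, 2)
  zero <- surrogate_mechanistic(M, list(function(x) 0, function(x) 0),
                                c("a", "b"))
  expect_equal(unname(rhs_eval(zero, c(3, 4))), c(0, 0))
  single <- surrogate_mechanistic(matrix(c(1, 0), 2, 1),
                                  list(function(x) 2.5), c("a", "b"))
  expect_equal(unname(rhs_eval(single, c(9, 9))), c(2.5, 0))
  expect_error(surrogate_mechanistic(M, list(function(x) 0), c("a", "b")))
})

test_that("S-system identities and fixed points hold", {
  n <- 3
  set.seed(7)
  G <- matrix(rnorm(9, 0, 0.5), n, n)
  a <- runif(n, 0.5, 2)
  same <- surrogate_ssystem(a, G, a, G, letters[1:n])
  for (i in 1:20) {
    x <- runif(n, 0.1, 50)
    expect_equal(unname(rhs_eval(same, x)), rep(0, n))
  }
  # n = 1 closed form: 2 sqrt(x) = x at x = 4
  one <- surrogate_ssystem(2, matrix(0.5), 1, matrix(1), "x")
  expect_equal(unname(rhs_eval(one, 4)), 0)
  ss <- steady_state(one, c(x = 1))
  expect_true(ss$converged)
  expect_equal(unname(ss$x), 4, tolerance = 1e-8)
  # random stable-ish S-system: the root balances the two terms exactly
  H <- G + diag(1, n)
  b <- a * 1.3
  sys <- surrogate_ssystem(a, G, b, H, letters[1:n])
  r <- steady_state(sys, rep(1, n))
  if (r$converged) {
    x <- pmax(as.numeric(r$x), 1e-12)
    inflow <- a * exp(G %*% log(x))
    outflow <- b * exp(H %*% log(x))
    expect_equal(as.numeric(inflow), as.numeric(outflow), tolerance = 1e-6)
  }
})

test_that("Taylor surrogates vanish at X0 and reduce to linear when H = 0", {
  n <- 3
  set.seed(11)
  X0 <- runif(n, 5, 50)
  J <- matrix(rnorm(9, 0, 0.3), n, n)
  H0 <- lapply(1:n, function(i) matrix(0, n, n))
  lin <- surrogate_taylor(X0, J, vars = letters[1:n])
  quad0 <- surrogate_taylor(X0, J, H0, vars = letters[1:n])
  expect_equal(unname(rhs_eval(lin, X0)), rep(0, n))
  expect_equal(unname(rhs_eval(quad0, X0)), rep(0, n))
  for (i in 1:20) {
    x <- X0 * runif(n, 0.5, 1.5)
    expect_equal(rhs_eval(quad0, x), rhs_eval(lin, x))
  }
  # exact quadratic field is reproduced exactly by its own expansion
  H <- lapply(1:n, function(i) {
    A <- matrix(rnorm(9, 0, 0.02), n, n)
    A + t(A)
  })
  quad <- surrogate_taylor(X0, J, H, vars = letters[1:n])
  f <- function(x) {
    d <- x - X0
    drop(J %*% d) + 0.5 * vapply(H, function(Hi)
      drop(crossprod(d, Hi %*% d)), numeric(1))
  }
  for (i in 1:10) {
    x <- X0 * runif(n, 0.7, 1.3)
    expect_equal(unname(rhs_eval(quad, x)), f(x), tolerance = 1e-10)
  }
  expect_error(surrogate_taylor(X0, J, lapply(1:n, function(i)
    matrix(rnorm(9), n, n)), vars = letters[1:n]),
    "symmetric")
})

test_that("control terms attach, add the right fluxes, and zero is identity", {
  k <- c(0.2, 0.001, 0.003, 0.002, 0.1, 0.01, 0.005, 0.08)
  mech <- surrogate_mech_swg(k)
  ctl <- with_control(mech, control_spec("removal",
                                         rates = c(sheep = 0.02,
                                                   wolves = 0.015)))
  set.seed(3)
  for (i in 1:30) {
    x <- runif(3, 1, 500)
    expect_equal(unname(rhs_eval(ctl, x) - rhs_eval(mech, x)),
                 c(0, -0.02 * x[2], -0.015 * x[3]))
  }
  zero <- with_control(mech, control_spec("removal",
                                          rates = c(sheep = 0, wolves = 0)))
  for (i in 1:20) {
    x <- runif(3, 1, 500)
    expect_equal(rhs_eval(zero, x), rhs_eval(mech, x))
  }
  mm <- surrogate_mm_metabolic(rep(1, 4), rep(50, 4), rep(100, 2))
  inflow <- with_control(mm, control_spec("inflow", var = "S", q = 0.7))
  x <- c(10, 5, 3, 2, 1)
  expect_equal(unname(rhs_eval(inflow, x) - rhs_eval(mm, x)),
               c(0.7, 0, 0, 0, 0))
  expect_error(with_control(mech, control_spec("removal",
                                               rates = c(lynx = 0.1))),
               "unknown variable")
})

test_that("evaluation is pure and floors power-law bases at extinction", {
  gma <- mech_as_gma(c(0.2, 0.001, 0.003, 0.002, 0.1, 0.01, 0.005, 0.08))
  x <- c(0, 0, 0)
  expect_true(all(is.finite(rhs_eval(gma, x))))
  expect_identical(rhs_eval(gma, c(5, 5, 5)), rhs_eval(gma, c(5, 5, 5)))
})

test_that("parameter counts follow the family formulas", {
  expect_equal(param_count("linear", 3), 9)
  expect_equal(param_count("ssystem", 3), 15)
  expect_equal(param_count("quadratic", 3), 27)
  expect_equal(param_count("gma", 3, m = 7), 28)
  expect_equal(param_count("linear", 5), 25)
  expect_equal(param_count("quadratic", 5), (3 * 25 + 125) / 2)
  expect_equal(param_count("ssystem", 5), 35)
  expect_error(param_count("spline", 3), "unknown family")
})

test_that("integration matches closed forms and reports failures", {
  dec <- surrogate_taylor(0, matrix(-1), vars = "x")
  sol <- integrate_surrogate(dec, c(x = 1), seq(0, 1, 0.25))
  expect_true(sol$success)
  expect_equal(tail(sol$trajectory$x, 1), exp(-1), tolerance = 1e-5)
  # linear system against the matrix exponential
  set.seed(5)
  J <- matrix(rnorm(9, 0, 0.4), 3, 3) - diag(1, 3)
  X0 <- c(10, 20, 30)
  lin <- surrogate_taylor(X0, J, vars = letters[1:3])
  x_init <- X0 + c(3, -2, 1)
  sol2 <- integrate_surrogate(lin, x_init, c(0, 0.5, 1.5))
  expected <- X0 + pracma::expm(1.5 * J) %*% (x_init - X0)
  expect_equal(as.numeric(sol2$trajectory[3, letters[1:3]]),
               as.numeric(expected), tolerance = 1e-4)
  # finite-time blow-up is a structured failure, not an error
  bomb <- surrogate_gma(matrix(1), alpha = 1, G = matrix(2), vars = "x")
  solb <- integrate_surrogate(bomb, c(x = 5), seq(0, 2, 0.1))
  expect_false(solb$success)
  expect_lt(solb$n_ok, 21)
  expect_error(integrate_surrogate(dec, c(x = 1), c(0, 0)), "grid")
})

test_that("steady states are located or reported as unreachable", {
  r <- 0.8; K <- 200
  logi <- surrogate_mechanistic(matrix(c(1, -1), 1, 2),
                                list(function(x) r * x[1],
                                     function(x) r * x[1]^2 / K), "x")
  ss <- steady_state(logi, c(x = K / 2))
  expect_true(ss$converged)
  expect_equal(unname(ss$x), K, tolerance = 1e-8)
  # interior coexistence root of the predator-prey surrogate
  mech <- surrogate_mech_swg(c(0.2, 0.001, 0.003, 0.002, 0.1, 0.01,
                               0.005, 0.08))
  ss2 <- steady_state(mech, c(grass = 500, sheep = 100, wolves = 50))
  expect_true(ss2$converged)
  expect_true(all(ss2$x > 0))
  expect_lt(ss2$residual, 1e-8)
  # constant field has no root
  none <- surrogate_mechanistic(matrix(1), list(function(x) 1), "x")
  ss3 <- steady_state(none, c(x = 1))
  expect_false(ss3$converged)
})
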