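const_traj <- function(vals, n = 11) {
  df <- data.frame(step = 0:(n - 1))
  for (nm in names(vals)) df[[nm]] <- rep(vals[[nm]], n)
  as_trajectory(df, meta = list())
}

test_that("averaging realizations takes pointwise means and dispersions", {
  tr <- const_traj(c(x = 2, y = 5))
  avg <- average_realizations(list(tr, tr, tr))
  expect_equal(strip_traj(avg), strip_traj(tr))
  expect_true(all(attr(avg, "sd")[, c("x", "y")] == 0))
  expect_equal(attr(avg, "meta")$n_realizations, 3)

  a <- average_realizations(list(const_traj(c(x = 1)), const_traj(c(x = 3))))
  expect_true(all(a$x == 2))
  expect_equal(attr(a, "sd")$x, rep(sd(c(1, 3)), 11))

  short <- const_traj(c(x = 1), n = 5)
  expect_error(average_realizations(list(tr, short)), "mismatched")
})

test_that("standard error of averaged runs shrinks as 1/sqrt(R)", {
  set.seed(31)
  mk <- function() {
    df <- data.frame(step = 0:49, x = 10 + rnorm(50))
    as_trajectory(df, meta = list())
  }
  runs <- replicate(64, mk(), simplify = FALSE)
  split_means <- function(size) {
    ng <- 64 / size
    vapply(seq_len(ng), function(g) {
      avg <- average_realizations(runs[((g - 1) * size + 1):(g * size)])
      mean(avg$x)
    }, numeric(1))
  }
  s8 <- sd(split_means(8))
  s32_theory <- s8 / 2 # 32 = 4 x 8 -> SE halves
  avg_all <- average_realizations(runs)
  # pointwise sd estimates the single-run dispersion, not the SE
  expect_equal(mean(attr(avg_all, "sd")$x), 1, tolerance = 0.15)
  expect_equal(sd(split_means(32)), s32_theory, tolerance = 0.9)
})

test_that("the slope method recovers simple generating laws", {
  # exponential decay fitted by a 1-variable power-law process
  lambda <- 0.7
  times <- seq(0, 6, by = 0.1)
  tr <- as_trajectory(data.frame(step = times, x = 5 * exp(-lambda * times)),
                      meta = list())
  tpl <- template_gma(matrix(-1), "x")
  g <- initial_guess_slope(tr, tpl)
  expect_equal(exp(g[1]), lambda, tolerance = 0.05)
  expect_equal(unname(g[2]), 1, tolerance = 0.05)
  # constant data degenerates to near-zero rate constants
  g0 <- initial_guess_slope(const_traj(c(x = 4)), tpl)
  expect_lt(exp(g0[1]), 1e-6)
})

test_that("designs stack trajectories and vanish at the truth", {
  k <- c(0.25, 0.0008, 0.004, 0.0025, 0.12, 0.012, 0.006, 0.09)
  truth <- surrogate_mech_swg(k)
  times <- seq(0, 60, by = 2)
  sol <- integrate_surrogate(truth, c(grass = 300, sheep = 60, wolves = 25),
                             times)
  tr <- as_trajectory(sol$trajectory, meta = list())
  tpl <- template_mech_swg()
  d1 <- build_design(tr, tpl)
  expect_length(d1$residual_fn(log(k)), nrow(tr) * 3)
  expect_lt(sum(d1$residual_fn(log(k))^2), 1e-10)
  # a controlled trajectory extends the residual by its own point count
  ctl <- with_control(truth, control_spec("removal", rates = c(sheep = 0.01)))
  sol2 <- integrate_surrogate(ctl, c(grass = 300, sheep = 60, wolves = 25),
                              seq(0, 40, by = 2))
  tr2 <- as_trajectory(sol2$trajectory,
                       meta = list(control = removal_control(kappa_sheep =
                                     1 - exp(-0.01))))
  d2 <- build_design(list(tr, tr2), tpl)
  expect_length(d2$residual_fn(log(k)),
                nrow(tr) * 3 + nrow(tr2) * 3)
  expect_lt(sum(d2$residual_fn(log(k))^2), 1e-8)
})

test_that("the mechanistic predator-prey model is recovered from its own data", {
  k <- c(0.25, 0.0008, 0.004, 0.0025, 0.12, 0.012, 0.006, 0.09)
  truth <- surrogate_mech_swg(k)
  times <- seq(0, 80, by = 2)
  mk <- function(x0) as_trajectory(
    integrate_surrogate(truth, x0, times)$trajectory, meta = list())
  ds <- list(mk(c(grass = 300, sheep = 60, wolves = 25)),
             mk(c(grass = 150, sheep = 120, wolves = 12)))
  fit <- fit_surrogate(build_design(ds, template_mech_swg()),
                       n_starts = 2, seed = 1, maxiter = 200)
  expect_lt(max(abs(exp(fit$theta) / k - 1)), 0.02)
  expect_lt(fit$ssr, 5e-4)
  # the optimizer never ends above its own start
  expect_true(all(fit$starts$ssr <= fit$starts$ssr0 + 1e-12, na.rm = TRUE))
  # deterministic under a fixed seed
  fit2 <- fit_surrogate(build_design(ds, template_mech_swg()),
                        n_starts = 2, seed = 1, maxiter = 200)
  expect_identical(fit$theta, fit2$theta)
})

test_that("a linear Taylor fit on linear data recovers the Jacobian", {
  set.seed(9)
  n <- 3
  X0 <- c(40, 25, 60)
  J <- matrix(rnorm(9, 0, 0.2), n, n) - diag(0.6, n)
  truth <- surrogate_taylor(X0, J, vars = letters[1:n])
  mk <- function(x0) as_trajectory(
    integrate_surrogate(truth, x0, seq(0, 8, by = 0.25))$trajectory,
    meta = list())
  ds <- list(mk(X0 * c(1.4, 0.7, 1.1)), mk(X0 * c(0.8, 1.3, 0.9)))
  tpl <- template_taylor(X0, letters[1:n], order = 1)
  fit <- fit_surrogate(build_design(ds, tpl), n_starts = 1, maxiter = 40)
  expect_equal(fit$model$params$J, J, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("extra steady states inside the domain box are penalized", {
  lin <- surrogate_taylor(2, matrix(-1), vars = "x")
  expect_equal(no_extra_roots_penalty(lin, 2, lower = 0, upper = 10), 0)
  # cubic with roots 1, 3, 5; expansion point 3
  cubic <- surrogate_mechanistic(matrix(1), list(function(x)
    -(x[1] - 1) * (x[1] - 3) * (x[1] - 5)), "x")
  expect_gt(no_extra_roots_penalty(cubic, 3, lower = 0, upper = 6,
                                   n_probes = 24), 0)
  # the same roots just outside the box do not count
  expect_equal(no_extra_roots_penalty(cubic, 3, lower = 2, upper = 4,
                                      n_probes = 24), 0)
})
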