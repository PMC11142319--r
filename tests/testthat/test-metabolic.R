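test_that("topology matches the declared inventory", {
  topo <- metabolic_topology()
  expect_length(topo$metabolites, 5)
  expect_length(topo$enzymes, 4)
  expect_equal(nrow(topo$reactions), 4)
  expect_equal(nrow(topo$regulation), 2)
  expect_length(topo$complexes, 12)
  expect_true(all(topo$reactions$substrate != topo$reactions$product))
})

test_that("enzymes and batch-mode metabolites are conserved every tick", {
  p <- metabolic_params(width = 60, height = 60,
                        init_counts = c(S = 400, E1 = 20, E2 = 20,
                                        E3 = 20, E4 = 20))
  tr <- simulate_metabolic(p, n_steps = 2500, seed = 3,
                           record_complexes = TRUE)
  m <- as.data.frame(tr)
  st_cols <- matrix(colnames(m)[7:26], nrow = 5) # 5 states x 4 types
  # metabolites: free + one per occupied metabolite slot (+1 extra for
  # substrate+regulator complexes)
  n_bound <- rowSums(m[, st_cols[2, ]]) + rowSums(m[, st_cols[3, ]]) +
    rowSums(m[, st_cols[4, ]]) + 2 * rowSums(m[, st_cols[5, ]])
  total <- rowSums(m[, c("S", "A", "B", "R", "T")]) + n_bound
  expect_true(all(total == 400))
  # enzymes per type
  for (k in 1:4) {
    expect_true(all(rowSums(m[, st_cols[, k]]) == 20))
  }
  # final-state accounting agrees
  fs <- attr(tr, "final_state")
  expect_equal(sum(metabolite_totals(fs)), 400)
  expect_equal(unname(enzyme_totals(fs)), rep(20, 4))
})

test_that("binding probability zero freezes the metabolite census", {
  p <- metabolic_params(width = 40, height = 40, p_bind = 0,
                        init_counts = c(S = 200, E1 = 10, E2 = 10,
                                        E3 = 10, E4 = 10))
  tr <- simulate_metabolic(p, n_steps = 400, seed = 1,
                           record_complexes = TRUE)
  m <- as.data.frame(tr)
  expect_true(all(m$S == 200))
  expect_true(all(m[, c("A", "B", "R", "T")] == 0))
  expect_true(all(m[, "E1"] == 10)) # all enzymes stay free
})

test_that("a vessel without metabolites only moves its enzymes", {
  p <- metabolic_params(init_counts = c(S = 0))
  st0 <- init_metabolic(p, seed = 2)
  set.seed(5)
  st1 <- step_metabolic(st0, p, n_steps = 50)
  expect_equal(nrow(st1$met), 0)
  expect_equal(st1$enz$type, st0$enz$type)
  expect_true(all(st1$enz$bound_met == -1))
  expect_false(all(st1$enz$x == st0$enz$x & st1$enz$y == st0$enz$y))
})

test_that("reactions are irreversible: product-only start never yields substrate", {
  p <- metabolic_params(mode = "batch",
                        init_counts = c(S = 0, A = 300))
  tr <- simulate_metabolic(p, n_steps = 2000, seed = 4)
  expect_true(all(tr$S == 0))           # A never converts back to S
  expect_gt(tail(tr$B, 1) + tail(tr$R, 1) + tail(tr$T, 1) +
              (300 - tail(tr$A, 1)), 0) # but does move forward
  expect_gt(max(tr$R + tr$T), 0)
})

test_that("trajectories are reproducible under a fixed seed", {
  p <- metabolic_params(width = 50, height = 50,
                        init_counts = c(S = 150))
  t1 <- simulate_metabolic(p, n_steps = 200, seed = 8)
  t2 <- simulate_metabolic(p, n_steps = 200, seed = 8)
  expect_identical(strip_traj(t1), strip_traj(t2))
})

test_that("batch runs deplete substrate into the two end products", {
  p <- metabolic_params()
  tr <- simulate_metabolic(p, n_steps = 6000, seed = 2)
  expect_lt(tail(tr$S, 1), 0.05 * 1000)       # most substrate consumed
  fs <- attr(tr, "final_state")
  tot <- metabolite_totals(fs)
  expect_gt(tot[["R"]] + tot[["T"]], 0.7 * 1000) # accumulated in R and T
})

test_that("continuous mode balances inflow against outflow", {
  p <- metabolic_params(mode = "continuous", q_in = 1)
  tr <- simulate_metabolic(p, n_steps = 6000, seed = 6)
  m <- as.data.frame(tr)
  late <- m[5000:6001, c("S", "A", "B", "R", "T")]
  balance <- p$q_in / p$outflow_rate
  expect_gt(mean(rowSums(late)), 0.70 * balance)
  expect_lt(mean(rowSums(late)), 1.10 * balance)
})

test_that("an isolated reaction follows saturating initial-rate kinetics", {
  # single enzyme species on a small, fast-mixing lattice; initial product
  # formation rate (free product + enzyme-product complexes) vs substrate
  S0s <- c(10, 20, 40, 80, 160, 320, 640)
  rate <- sapply(seq_along(S0s), function(i) {
    mean(sapply(1:4, function(s) {
      p <- metabolic_params(width = 40, height = 40,
                            init_counts = c(S = S0s[i], E1 = 15, E2 = 0,
                                            E3 = 0, E4 = 0))
      tr <- simulate_metabolic(p, n_steps = 100, seed = 50 * i + s,
                               record_complexes = TRUE)
      m <- as.data.frame(tr)
      tail(m$A + m$E1A, 1) / 100
    }))
  })
  fit <- nls(rate ~ Vmax * S0s / (K + S0s),
             start = list(Vmax = max(rate), K = 100))
  r2 <- 1 - sum(residuals(fit)^2) / sum((rate - mean(rate))^2)
  expect_gt(r2, 0.98)
  expect_true(all(diff(rate) > 0)) # monotone saturating curve
  # mean-field stochastic oracle of the same elementary scheme
  oracle <- mean(sapply(1:6, function(s)
    ref_mm_oracle(320, 15, 1600, 0.5, 0.02, 0.1, 100, seed = s))) / 100
  expect_lt(abs(rate[S0s == 320] - oracle) / oracle, 0.30)
})
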