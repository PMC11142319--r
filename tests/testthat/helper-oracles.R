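# Independent, deliberately plain R reference implementation of the
# sheep-wolves-grass tick (same rules, written without reference to the
# compiled stepper) used for distributional cross-checks.
ref_swg_run <- function(params, n_steps, seed) {
  set.seed(seed)
  W <- params$world_width; H <- params$world_height; P <- W * H
  regrow <- params$grass_regrowth_time
  grass <- integer(P)
  n_grown <- floor(params$init_grass_fraction * P)
  if (n_grown < P) {
    bare <- sample.int(P, P - n_grown)
    grass[bare] <- sample.int(regrow, P - n_grown, replace = TRUE)
  }
  mk <- function(n, gain) {
    list(x = runif(n, 0, W), y = runif(n, 0, H), h = runif(n, 0, 360),
         e = runif(n, 1, 2 * gain))
  }
  sheep <- mk(params$init_sheep, params$sheep_gain_from_food)
  wolves <- mk(params$init_wolves, params$wolf_gain_from_food)
  patch <- function(a) pmin(floor(a$x), W - 1) + W * pmin(floor(a$y), H - 1) + 1
  macro <- matrix(NA_integer_, n_steps + 1, 3)
  macro[1, ] <- c(sum(grass == 0), length(sheep$x), length(wolves$x))
  keep <- function(a, ok) lapply(a, function(v) v[ok])
  for (t in seq_len(n_steps)) {
    for (nm in c("sheep", "wolves")) {
      a <- get(nm)
      n <- length(a$x)
      if (n) {
        a$h <- a$h + (runif(n) - runif(n)) * 50
        a$x <- (a$x + sin(a$h * pi / 180)) %% W
        a$y <- (a$y + cos(a$h * pi / 180)) %% H
        a$e <- a$e - params$energy_loss_per_step
      }
      assign(nm, a)
    }
    ns <- length(sheep$x)
    if (ns) {
      for (i in sample.int(ns)) {
        pp <- patch(keep(sheep, i))
        if (grass[pp] == 0) {
          grass[pp] <- regrow + 1
          sheep$e[i] <- sheep$e[i] + params$sheep_gain_from_food
        }
      }
    }
    nw <- length(wolves$x)
    if (nw && length(sheep$x)) {
      sp <- patch(sheep)
      alive <- rep(TRUE, length(sp))
      for (i in sample.int(nw)) {
        cand <- which(alive & sp == patch(keep(wolves, i)))
        if (length(cand)) {
          victim <- cand[sample.int(length(cand), 1)]
          alive[victim] <- FALSE
          wolves$e[i] <- wolves$e[i] + params$wolf_gain_from_food
        }
      }
      sheep <- keep(sheep, alive)
    }
    sheep <- keep(sheep, sheep$e >= 0)
    wolves <- keep(wolves, wolves$e >= 0)
    for (nm in c("sheep", "wolves")) {
      a <- get(nm)
      pr <- if (nm == "sheep") params$sheep_reproduce_prob
            else params$wolf_reproduce_prob
      n0 <- length(a$x)
      if (n0) {
        for (i in seq_len(n0)) {
          if (runif(1) < pr) {
            a$e[i] <- a$e[i] / 2
            a$x <- c(a$x, a$x[i]); a$y <- c(a$y, a$y[i])
            a$h <- c(a$h, runif(1) * 360); a$e <- c(a$e, a$e[i])
          }
        }
      }
      assign(nm, a)
    }
    grass[grass > 0] <- grass[grass > 0] - 1L
    macro[t + 1, ] <- c(sum(grass == 0), length(sheep$x), length(wolves$x))
  }
  colnames(macro) <- c("grass", "sheep", "wolves")
  macro
}

# Mean-field stochastic oracle of one isolated enzymatic reaction
# (S + E <-> ES -> EA <-> E + A) with the lattice model's per-tick hazards:
# a free substrate meets a free enzyme with probability
# 1 - (1 - 9/cells)^E_free and binds with p_bind.
ref_mm_oracle <- function(S0, E0, cells, p_bind, p_diss, p_cat, n_steps,
                          seed) {
  set.seed(seed)
  S <- S0; ES <- 0; EA <- 0; A <- 0
  for (t in seq_len(n_steps)) {
    E_free <- E0 - ES - EA
    p_enc <- p_bind * (1 - (1 - 9 / cells)^max(E_free, 0))
    bind <- rbinom(1, S, p_enc)
    bind <- min(bind, E_free)
    S <- S - bind; ES <- ES + bind
    dis <- rbinom(1, ES, p_diss)
    ES <- ES - dis; S <- S + dis
    cat_ <- rbinom(1, ES, p_cat)
    ES <- ES - cat_; EA <- EA + cat_
    rel <- rbinom(1, EA, p_diss)
    EA <- EA - rel; A <- A + rel
    # product rebinding to free enzyme
    E_free <- E0 - ES - EA
    reb <- rbinom(1, A, p_bind * (1 - (1 - 9 / cells)^max(E_free, 0)))
    A <- A - reb; EA <- EA + reb
  }
  c(A_total = A + EA)
}

# Small GMA cascade used for the parameter-recovery studies.
recovery_gma <- function() {
  vars <- c("X1", "X2", "X3")
  M <- cbind(c(1, 0, 0), c(-1, 1, 0), c(0, -1, 1), c(0, 0, -1))
  alpha <- c(2, 0.3, 0.25, 0.4)
  G <- rbind(c(0, 0, 0), c(0.8, 0, -0.3), c(0, 0.7, 0), c(0, 0, 1))
  list(vars = vars, M = M, alpha = alpha, G = G, mask = G != 0,
       model = surrogate_gma(M, alpha, G, vars))
}

recovery_gma_data <- function(sys, x0s, times = seq(0, 20, by = 0.5),
                              noise_sd = 0, seed = 1) {
  set.seed(seed)
  lapply(x0s, function(x0) {
    sol <- integrate_surrogate(sys$model, setNames(x0, sys$vars), times)
    df <- sol$trajectory
    if (noise_sd > 0) {
      for (v in sys$vars)
        df[[v]] <- pmax(df[[v]] * (1 + rnorm(nrow(df), 0, noise_sd)), 1e-6)
    }
    as_trajectory(df, meta = list())
  })
}
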