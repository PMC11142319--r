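#' Substrate-waste loss of a pathway trajectory
#'
#' The running objective of the inflow control problem: the sum over
#' recorded ticks k = 1..Nt of S_k / max(R_k + T_k, floor), i.e. substrate
#' still unconverted relative to accumulated end products. The denominator
#' floor (default 1 molecule, the smallest nonzero census) handles early
#' ticks where no product exists yet; the initial row (k = 0) is excluded.
#'
#' @param traj a trajectory (data frame) with `S`, `R`, `T` columns.
#' @param floor denominator floor.
#' @return The loss (non-negative scalar).
#' @export
yield_loss <- function(traj, floor = 1) {
  df <- as.data.frame(traj)
  if (!all(c("S", "R", "T") %in% names(df)))
    stop("trajectory must have S, R and T columns")
  if (nrow(df) < 2) return(0)
  df <- df[-1, ]
  sum(df$S / pmax(df$R + df$T, floor))
}

#' Solve the steady-state-shift removal problem on a surrogate
#'
#' Finds constant per-capita removal rates (continuous-time kappas) for the
#' controlled variables such that the controlled surrogate's steady state
#' matches the target (multiplicative factors applied to the baseline
#' steady state X0), choosing, among rate pairs that reach the target
#' within tolerance, the one minimizing the total number of individuals
#' removed over the horizon. The search is a coarse feasibility grid
#' followed by root-finding on the steady-state mismatch and a final
#' verification; it is deterministic.
#'
#' @param model fitted `surrogate` (uncontrolled).
#' @param X0 named baseline steady state.
#' @param target named multiplicative factors for the targeted variables
#'   (e.g. `c(sheep = 1.1, wolves = 0.5)`); unnamed variables are free.
#' @param control_vars variables carrying removal control (defaults to the
#'   names of `target`).
#' @param bounds per-variable upper bounds on the removal rates (recycled).
#' @param horizon ticks over which removals are accumulated.
#' @param tol relative tolerance declaring the target reached (default 2%).
#' @param n_grid coarse grid resolution per dimension.
#' @return A `control_solution`: removal rates `kappa`, their per-tick ABM
#'   lift `kappa_tick`, the achieved steady state, relative distance to
#'   target, total removals, and a `feasible` flag (infeasibility within
#'   the bounds is reported, not raised).
#' @export
solve_removal_rates <- function(model, X0, target = c(sheep = 1.1,
                                                      wolves = 0.5),
                                control_vars = names(target),
                                bounds = 0.05, horizon = 1000, tol = 0.02,
                                n_grid = 13) {
  stopifnot(inherits(model, "surrogate"), all(control_vars %in% model$vars),
            all(names(target) %in% model$vars))
  X0 <- X0[model$vars]
  x_target <- X0[names(target)] * target
  bounds <- rep_len(bounds, length(control_vars))
  nd <- length(control_vars)

  controlled_ss <- function(kappa) {
    mc <- with_control(model, control_spec(
      "removal", rates = setNames(kappa, control_vars)))
    ss <- steady_state(mc, X0)
    if (!ss$converged || any(ss$x < -1e-6)) {
      # fall back to the horizon endpoint of the controlled trajectory
      sol <- integrate_surrogate(mc, X0, seq(0, horizon, length.out = 201))
      if (sol$n_ok < 10) return(NULL)
      ss$x <- setNames(as.numeric(sol$trajectory[sol$n_ok, model$vars]),
                       model$vars)
    }
    ss$x
  }
  mismatch <- function(kappa) {
    x <- controlled_ss(pmin(pmax(kappa, 0), bounds))
    if (is.null(x)) return(rep(1e3, length(target)))
    unname(x[names(target)] / x_target - 1)
  }
  dist_fn <- function(kappa) sqrt(sum(mismatch(kappa)^2))
  removals_fn <- function(kappa) {
    mc <- with_control(model, control_spec(
      "removal", rates = setNames(kappa, control_vars)))
    sol <- integrate_surrogate(mc, X0, seq(0, horizon, length.out = 201))
    if (!sol$n_ok) return(Inf)
    tr <- sol$trajectory
    dt <- diff(tr$step)
    flux <- as.matrix(tr[control_vars]) %*% kappa
    sum(dt * (head(flux, -1) + tail(flux, -1)) / 2)
  }

  # coarse grid scan for a starting point
  axes <- lapply(bounds, function(b) seq(0, b, length.out = n_grid))
  grid <- as.matrix(expand.grid(axes))
  d <- apply(grid, 1, dist_fn)
  k0 <- grid[which.min(d), ]

  # refine by root-finding on the steady-state mismatch (square system);
  # an exact interior root is the unique feasible-and-cheapest solution
  kap <- k0
  if (length(target) == nd) {
    kr <- tryCatch(newton_root(mismatch, as.numeric(k0),
                               h = pmax(bounds, 1e-3) * 1e-3),
                   error = function(e) NULL)
    if (!is.null(kr) && all(is.finite(kr))) {
      kr <- pmin(pmax(kr, 0), bounds)
      if (dist_fn(kr) < dist_fn(kap)) kap <- kr
    }
  }
  if (dist_fn(kap) > 1e-5) {
    # no exact match inside the bounds: feasibility (within tol) first,
    # then fewest removals
    pen_obj <- function(k) {
      k <- pmin(pmax(k, 0), bounds)
      dd <- dist_fn(k)
      if (dd > tol) 1e6 * (1 + dd) else removals_fn(k)
    }
    op <- if (nd == 1) {
      optim(kap, pen_obj, method = "Brent", lower = 0, upper = bounds,
            control = list(maxit = 200))
    } else {
      optim(kap, pen_obj, method = "Nelder-Mead",
            control = list(maxit = 200, reltol = 1e-10))
    }
    if (op$value < pen_obj(kap)) kap <- pmin(pmax(op$par, 0), bounds)
  }

  achieved <- controlled_ss(kap)
  dd <- dist_fn(kap)
  structure(list(kappa = setNames(as.numeric(kap), control_vars),
                 kappa_tick = setNames(1 - exp(-as.numeric(kap)),
                                       control_vars),
                 achieved = achieved, target = x_target,
                 distance = dd, feasible = dd <= tol,
                 removals = removals_fn(kap), horizon = horizon,
                 family = model$family, kind = "removal"),
            class = "control_solution")
}

# damped Newton on a square nonlinear system with finite-difference
# Jacobian; returns the best iterate found
newton_root <- function(f, x0, h, max_iter = 40) {
  x <- x0
  nrm <- function(v) sqrt(sum(v^2))
  for (it in seq_len(max_iter)) {
    fx <- f(x)
    if (!all(is.finite(fx)) || nrm(fx) < 1e-10) break
    J <- jacobian_fd(f, x, h = h)
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    lam <- 1
    repeat {
      fn <- f(x + lam * step)
      if (all(is.finite(fn)) && nrm(fn) < nrm(fx)) break
      lam <- lam / 2
      if (lam < 1e-6) break
    }
    if (lam < 1e-6) break
    x <- x + lam * step
  }
  x
}

#' @export
print.control_solution <- function(x, ...) {
  cat("<control_solution>", x$kind, "|",
      paste(names(x$kappa %||% x$q_opt),
            signif(x$kappa %||% x$q_opt, 4), sep = "=", collapse = " "),
      if (!is.null(x$feasible)) paste("| feasible:", x$feasible), "\n")
  invisible(x)
}

#' Solve the optimal-inflow problem on a surrogate
#'
#' Minimizes the substrate-waste loss ([yield_loss()]) of the controlled
#' surrogate trajectory over the constant substrate inflow Q. The surrogate
#' need not be integrable over the whole range: the integrable sub-domain
#' is reported together with whether a minimum exists in its interior.
#'
#' @param model fitted metabolic `surrogate` (continuous-mode dynamics are
#'   supplied through `outflow_rate`).
#' @param x0 named initial state (defaults to all zero).
#' @param bounds inflow range searched.
#' @param horizon ticks per evaluation.
#' @param outflow_rate per-tick outflow applied to all state variables.
#' @param n_scan scan resolution over `bounds`.
#' @param record_every trajectory recording stride (the loss is accumulated
#'   at this resolution and rescaled to per-tick).
#' @return A `control_solution` with `q_opt`, `loss_opt`, the scan table,
#'   the integrable range and an `interior_min` flag; if the model can be
#'   integrated nowhere, `success = FALSE`.
#' @export
solve_inflow <- function(model, x0 = NULL, bounds = c(0, 1), horizon = 5000,
                         outflow_rate = 5e-4, n_scan = 21,
                         record_every = 10) {
  stopifnot(inherits(model, "surrogate"))
  if (is.null(x0)) x0 <- setNames(rep(0, length(model$vars)), model$vars)
  times <- seq(0, horizon, by = record_every)
  eval_q <- function(q) {
    specs <- list(control_spec("inflow", var = "S", q = q))
    if (outflow_rate > 0)
      specs <- c(specs, list(control_spec(
        "removal", rates = setNames(rep(-log(1 - outflow_rate),
                                        length(model$vars)), model$vars))))
    mc <- with_control(model, specs)
    sol <- integrate_surrogate(mc, x0, times)
    if (!sol$success) return(NA_real_)
    tr <- sol$trajectory
    tr[model$vars] <- pmax(tr[model$vars], 0)
    yield_loss(tr) * record_every
  }
  qs <- seq(bounds[1], bounds[2], length.out = n_scan)
  losses <- vapply(qs, eval_q, numeric(1))
  scan <- data.frame(q = qs, loss = losses)
  ok <- which(is.finite(losses))
  if (!length(ok)) {
    return(structure(list(kind = "inflow", success = FALSE, scan = scan,
                          message = "surrogate not integrable anywhere in bounds"),
                     class = "control_solution"))
  }
  integrable <- range(qs[ok])
  i_min <- ok[which.min(losses[ok])]
  interior <- i_min > min(ok) && i_min < max(ok)
  q_opt <- qs[i_min]
  loss_opt <- losses[i_min]
  if (interior) {
    refine <- optimize(function(q) {
      v <- eval_q(q)
      if (is.na(v)) 1e12 else v
    }, lower = qs[i_min - 1], upper = qs[i_min + 1])
    if (refine$objective < loss_opt) {
      q_opt <- refine$minimum
      loss_opt <- refine$objective
    }
  }
  structure(list(kind = "inflow", success = TRUE, q_opt = q_opt,
                 loss_opt = loss_opt, scan = scan,
                 integrable_range = integrable, interior_min = interior,
                 family = model$family),
            class = "control_solution")
}

#' Lift a surrogate control solution back to ABM terms
#'
#' A continuous per-capita removal rate kappa (per tick of unit length)
#' becomes the per-tick Bernoulli removal probability 1 - exp(-kappa); a
#' continuous constant inflow becomes the mean of the per-tick Poisson
#' inflow. Probabilities outside the unit interval are errors.
#'
#' @param solution a `control_solution`.
#' @param abm `"swg"` or `"metabolic"`.
#' @return For `"swg"` a [removal_control()]; for `"metabolic"` a list with
#'   the Poisson inflow mean `q_in`.
#' @export
lift_to_abm <- function(solution, abm = c("swg", "metabolic")) {
  abm <- match.arg(abm)
  if (abm == "swg") {
    stopifnot(solution$kind == "removal")
    p <- 1 - exp(-solution$kappa)
    if (any(p < 0 | p > 1)) stop("removal probability out of [0, 1]")
    removal_control(kappa_sheep = p[["sheep"]] %||% 0,
                    kappa_wolves = p[["wolves"]] %||% 0)
  } else {
    stopifnot(solution$kind == "inflow")
    if (solution$q_opt < 0) stop("negative inflow")
    list(q_in = solution$q_opt)
  }
}

#' Grid search over ABM control settings
#'
#' Evaluates a (possibly vector-valued) objective at every grid point,
#' averaging `reps` seeded realizations per point, and returns the full
#' surface with per-point dispersion, the argmin of the first objective
#' component, and the suboptimal set within one standard deviation of it.
#'
#' @param grid data frame, one row per control setting.
#' @param simulate_fn `function(row, seed)` returning a trajectory (or any
#'   object the objective understands).
#' @param objective_fn `function(result, row)` returning a named numeric
#'   vector; the first component is minimized.
#' @param reps realizations per grid point.
#' @param seed global seed; realization r of grid row i runs under seed
#'   `seed + (i - 1) * 10000 + r`.
#' @return List with `surface` (grid + mean and sd columns), `argmin` (row
#'   index), `best` (that row of the surface) and `within_1sd` (logical
#'   vector marking grid points whose mean objective lies within one
#'   standard deviation of the optimum).
#' @export
grid_search_abm <- function(grid, simulate_fn, objective_fn, reps = 10,
                            seed = 1) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1, reps >= 1)
  obj_mean <- NULL; obj_sd <- NULL
  for (i in seq_len(nrow(grid))) {
    vals <- sapply(seq_len(reps), function(r) {
      s <- (seed + (i - 1) * 10000 + r) %% .Machine$integer.max
      res <- simulate_fn(grid[i, , drop = FALSE], s)
      objective_fn(res, grid[i, , drop = FALSE])
    })
    if (is.null(dim(vals))) {
      nm <- if (is.null(names(vals))) "objective" else names(vals)[1]
      vals <- matrix(vals, nrow = 1, dimnames = list(nm, NULL))
    }
    if (is.null(obj_mean)) {
      obj_mean <- matrix(NA_real_, nrow(grid), nrow(vals),
                         dimnames = list(NULL, rownames(vals)))
      obj_sd <- obj_mean
    }
    obj_mean[i, ] <- rowMeans(vals)
    s_ <- apply(vals, 1, sd)
    obj_sd[i, ] <- ifelse(is.na(s_), 0, s_)
  }
  surface <- cbind(grid, mean = obj_mean, sd = obj_sd)
  names(surface) <- c(names(grid), paste0(colnames(obj_mean), "_mean"),
                      paste0(colnames(obj_sd), "_sd"))
  argmin <- unname(which.min(obj_mean[, 1]))
  within <- unname(obj_mean[, 1] <= obj_mean[argmin, 1] + obj_sd[argmin, 1])
  list(surface = surface, argmin = argmin,
       best = surface[argmin, , drop = FALSE], within_1sd = within)
}

#' Grid-search validation of the sheep-wolves-grass control problem
#'
#' Two-stage grid search over per-tick removal fractions (sheep, wolves):
#' a coarse scan over the full box, then a finer scan around the coarse
#' argmin. Every point is scored by averaging `reps` seeded controlled runs
#' started at the uncontrolled steady state `x0`: the relative Euclidean
#' distance of the long-run (tail-mean) sheep and wolf populations from the
#' target, plus the total number of animals removed. The reported optimum
#' minimizes the distance; a secondary selection minimizing removals among
#' statistically indistinguishable points is returned alongside.
#'
#' @param params [swg_params()].
#' @param x0 named uncontrolled steady-state counts (grass, sheep, wolves).
#' @param target multiplicative factors, as in [solve_removal_rates()].
#' @param kappa_sheep_max,kappa_wolves_max search box (per-tick fractions).
#' @param step1,step2 grid steps of the two stages.
#' @param reps realizations per grid point.
#' @param warmup,horizon,tail_frac controlled-run schedule, see
#'   [swg_controlled_run()].
#' @param tol floor of the statistical-equivalence band used by the
#'   removal-minimizing secondary selection.
#' @param seed global seed.
#' @return List with the selected `kappa` (per-tick fractions), the stage
#'   surfaces, and the removal-minimizing variant `kappa_minremoval`.
#' @export
swg_grid_search <- function(params, x0, target = c(sheep = 1.1, wolves = 0.5),
                            kappa_sheep_max = 0.02, kappa_wolves_max = 0.015,
                            step1 = 0.0025, step2 = 0.001, reps = 32,
                            warmup = 200, horizon = 1400, tail_frac = 0.5,
                            tol = 0.02, seed = 1) {
  y_target <- x0[["sheep"]] * target[["sheep"]]
  z_target <- x0[["wolves"]] * target[["wolves"]]
  sim <- function(row, s) {
    swg_controlled_run(params,
                       removal_control(kappa_sheep = row$kappa_sheep,
                                       kappa_wolves = row$kappa_wolves),
                       x0 = x0, warmup = warmup, horizon = horizon,
                       tail_frac = tail_frac, seed = s)
  }
  obj <- function(res, row) {
    c(sheep = res$tail_mean[["sheep"]], wolves = res$tail_mean[["wolves"]],
      dist = sqrt((res$tail_mean[["sheep"]] / y_target - 1)^2 +
                    (res$tail_mean[["wolves"]] / z_target - 1)^2),
      removed = sum(res$removed))
  }
  # score each grid point by the distance of its MEAN long-run state from
  # the target (averaging before the distance removes the per-realization
  # noise floor); the per-realization distance spread is kept as the
  # dispersion measure
  add_dist <- function(gs) {
    gs$surface$dist_mean <- sqrt(
      (gs$surface$sheep_mean / y_target - 1)^2 +
        (gs$surface$wolves_mean / z_target - 1)^2)
    gs
  }
  # the reported optimum is the distance-minimizing grid point; a variant
  # minimizing removals among points statistically indistinguishable from
  # it (within one standard error, at least `tol`) is returned alongside
  pick <- function(gs) which.min(gs$surface$dist_mean)
  pick_removal <- function(gs) {
    dist <- gs$surface$dist_mean
    i_best <- which.min(dist)
    band <- max(tol, gs$surface$dist_sd[i_best] / sqrt(reps))
    cand <- which(dist <= dist[i_best] + band)
    cand[which.min(gs$surface$removed_mean[cand])]
  }
  grid1 <- expand.grid(kappa_sheep = seq(0, kappa_sheep_max, by = step1),
                       kappa_wolves = seq(0, kappa_wolves_max, by = step1))
  gs1 <- add_dist(grid_search_abm(grid1, sim, obj, reps = reps, seed = seed))
  sel1 <- pick(gs1)
  k1 <- grid1[sel1, ]
  ks <- seq(max(0, k1$kappa_sheep - 2 * step1),
            min(kappa_sheep_max, k1$kappa_sheep + 2 * step1), by = step2)
  kw <- seq(max(0, k1$kappa_wolves - 2 * step1),
            min(kappa_wolves_max, k1$kappa_wolves + 2 * step1), by = step2)
  grid2 <- expand.grid(kappa_sheep = ks, kappa_wolves = kw)
  gs2 <- add_dist(grid_search_abm(grid2, sim, obj, reps = reps,
                                  seed = seed + 500000))
  sel2 <- pick(gs2)
  list(kappa = unlist(grid2[sel2, ]),
       kappa_minremoval = unlist(grid2[pick_removal(gs2), ]),
       stage1 = gs1, stage2 = gs2,
       surface = gs2$surface)
}

#' Grid-search validation of the metabolic inflow problem
#'
#' Scores each candidate inflow by the mean substrate-waste loss
#' ([yield_loss()]) of `reps` seeded continuous-mode runs.
#'
#' @param params continuous-mode [metabolic_params()]; its `q_in` is
#'   overridden by the grid.
#' @param q_grid inflow values tested.
#' @param reps realizations per value.
#' @param n_steps ticks per run.
#' @param seed global seed.
#' @return As [grid_search_abm()], plus `q_opt`, the loss-minimizing
#'   inflow.
#' @export
metabolic_inflow_grid_search <- function(params, q_grid = seq(0, 1, by = 0.1),
                                         reps = 10, n_steps = 5000,
                                         seed = 1) {
  stopifnot(params$mode == "continuous")
  sim <- function(row, s) {
    p <- params
    p$q_in <- row$q_in
    simulate_metabolic(p, n_steps = n_steps, seed = s)
  }
  obj <- function(res, row) c(loss = yield_loss(res))
  gs <- grid_search_abm(data.frame(q_in = q_grid), sim, obj, reps = reps,
                        seed = seed)
  gs$q_opt <- q_grid[gs$argmin]
  gs
}
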