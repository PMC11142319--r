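# Fitting templates: a template knows how to build a surrogate from a free
# parameter vector theta, and carries box bounds. Rate constants are
# optimized on the log scale (positivity by construction); kinetic orders
# are bounded to [-5, 5].

new_template <- function(family, vars, make, lower, upper, theta_names,
                         neutral = NULL, ...) {
  if (is.null(neutral)) neutral <- pmin(pmax(0, lower), upper)
  structure(list(family = family, vars = vars, make = make,
                 n_par = length(lower), lower = lower, upper = upper,
                 theta_names = theta_names, neutral = neutral, ...),
            class = "fit_template")
}

#' @export
print.fit_template <- function(x, ...) {
  cat("<fit_template>", x$family, "|", x$n_par, "free parameters\n")
  invisible(x)
}

#' Fitting template for the mechanistic sheep-wolves-grass surrogate
#'
#' Eight rate constants, optimized on the log scale.
#' @return A `fit_template`.
#' @export
template_mech_swg <- function() {
  new_template("mech_swg", c("grass", "sheep", "wolves"),
               make = function(theta) surrogate_mech_swg(exp(theta)),
               lower = rep(-25, 8), upper = rep(8, 8),
               theta_names = paste0("log_k", 1:8),
               neutral = rep(log(1e-4), 8))
}

#' Fitting template for a GMA surrogate
#'
#' Free parameters are the log rate constants and the unmasked kinetic
#' orders; masked orders are fixed at zero and excluded from optimization.
#'
#' @param M n x m stoichiometric matrix.
#' @param vars state-variable names.
#' @param mask m x n logical matrix, `TRUE` where the kinetic order is free
#'   (default: all free).
#' @param order_bound bound on kinetic orders (default 5).
#' @return A `fit_template`.
#' @export
template_gma <- function(M, vars, mask = NULL, order_bound = 5) {
  M <- as.matrix(M)
  m <- ncol(M); n <- length(vars)
  if (is.null(mask)) mask <- matrix(TRUE, m, n)
  stopifnot(all(dim(mask) == c(m, n)))
  ng <- sum(mask)
  make <- function(theta) {
    alpha <- exp(theta[seq_len(m)])
    G <- matrix(0, m, n)
    G[mask] <- theta[m + seq_len(ng)]
    surrogate_gma(M, alpha, G, vars)
  }
  new_template("gma", vars, make,
               lower = c(rep(-25, m), rep(-order_bound, ng)),
               upper = c(rep(8, m), rep(order_bound, ng)),
               theta_names = c(paste0("log_alpha", seq_len(m)),
                               paste0("g", which(mask))),
               neutral = c(rep(log(1e-4), m), rep(0, ng)),
               M = M, mask = mask)
}

#' Fitting template for an S-system surrogate
#'
#' @param vars state-variable names.
#' @param gmask,hmask n x n logical masks of free kinetic orders.
#' @param order_bound bound on kinetic orders.
#' @return A `fit_template`.
#' @export
template_ssystem <- function(vars, gmask = NULL, hmask = NULL,
                             order_bound = 5) {
  n <- length(vars)
  if (is.null(gmask)) gmask <- matrix(TRUE, n, n)
  if (is.null(hmask)) hmask <- matrix(TRUE, n, n)
  ng <- sum(gmask); nh <- sum(hmask)
  make <- function(theta) {
    alpha <- exp(theta[seq_len(n)])
    beta <- exp(theta[n + seq_len(n)])
    G <- matrix(0, n, n); G[gmask] <- theta[2 * n + seq_len(ng)]
    H <- matrix(0, n, n); H[hmask] <- theta[2 * n + ng + seq_len(nh)]
    surrogate_ssystem(alpha, G, beta, H, vars)
  }
  new_template("ssystem", vars, make,
               lower = c(rep(-25, 2 * n), rep(-order_bound, ng + nh)),
               upper = c(rep(8, 2 * n), rep(order_bound, ng + nh)),
               theta_names = c(paste0("log_alpha", 1:n),
                               paste0("log_beta", 1:n),
                               paste0("g", which(gmask)),
                               paste0("h", which(hmask))),
               neutral = c(rep(log(1e-4), 2 * n), rep(0, ng + nh)),
               gmask = gmask, hmask = hmask)
}

#' Fitting template for a Taylor surrogate at a fixed steady state
#'
#' The expansion point X0 is estimated from the data beforehand (e.g. with
#' [steady_state_tail()]) and held fixed; free parameters are the Jacobian
#' entries and, at order 2, the upper triangles of the per-equation
#' Hessians. To keep the optimization well scaled the Jacobian and Hessians
#' are parameterized in X0-normalized coordinates z = X / X0.
#'
#' @param X0 expansion point (all entries positive).
#' @param vars state-variable names.
#' @param order 1 (linear) or 2 (quadratic).
#' @return A `fit_template`.
#' @export
template_taylor <- function(X0, vars, order = 1) {
  n <- length(vars)
  X0 <- unname(as.numeric(X0))
  stopifnot(length(X0) == n, all(X0 > 0), order %in% c(1, 2))
  nJ <- n^2
  nHi <- n * (n + 1) / 2
  ut <- upper.tri(matrix(0, n, n), diag = TRUE)
  D0 <- diag(X0, n); D0i <- diag(1 / X0, n)
  make <- function(theta) {
    Jz <- matrix(theta[seq_len(nJ)], n, n)
    J <- D0 %*% Jz %*% D0i
    H <- NULL
    if (order == 2) {
      H <- vector("list", n)
      for (i in seq_len(n)) {
        Hz <- matrix(0, n, n)
        Hz[ut] <- theta[nJ + (i - 1) * nHi + seq_len(nHi)]
        Hz <- Hz + t(Hz) - diag(diag(Hz), n)
        H[[i]] <- X0[i] * D0i %*% Hz %*% D0i
      }
    }
    surrogate_taylor(X0, J, H, vars)
  }
  npar <- nJ + if (order == 2) n * nHi else 0
  new_template(if (order == 1) "linear" else "quadratic", vars, make,
               lower = rep(-Inf, npar), upper = rep(Inf, npar),
               theta_names = c(paste0("Jz", seq_len(nJ)),
                               if (order == 2)
                                 paste0("Hz", seq_len(n * nHi))),
               X0 = X0, order = order)
}

#' Fitting template for the Michaelis-Menten metabolic surrogate
#'
#' Ten parameters (4 Vmax, 4 Km, 2 Ki), optimized on the log scale.
#' @return A `fit_template`.
#' @export
template_mm_metabolic <- function() {
  make <- function(theta) {
    p <- exp(theta)
    surrogate_mm_metabolic(p[1:4], p[5:8], p[9:10])
  }
  new_template("mm_metabolic", c("S", "A", "B", "R", "T"), make,
               lower = rep(-15, 10), upper = rep(15, 10),
               theta_names = c(paste0("log_Vmax", 1:4),
                               paste0("log_Km", 1:4), paste0("log_Ki", 1:2)),
               neutral = log(c(rep(0.01, 4), rep(100, 4), rep(1e3, 2))))
}

# Map a trajectory's recorded control metadata to control_spec objects.
# Per-tick probabilities p become continuous rates -log(1 - p).
traj_control_specs <- function(traj, vars) {
  ctl <- attr(traj, "meta")$control
  if (is.null(ctl)) return(list())
  if (inherits(ctl, "control_spec")) return(list(ctl))
  if (is.list(ctl) && length(ctl) && inherits(ctl[[1]], "control_spec"))
    return(ctl)
  specs <- list()
  if (!is.null(ctl$kappa_sheep)) { # sheep-wolves-grass removal control
    p <- c(grass = ctl$kappa_grass %||% 0, sheep = ctl$kappa_sheep,
           wolves = ctl$kappa_wolves %||% 0)
    p <- p[p > 0]
    if (length(p))
      specs <- c(specs, list(control_spec("removal", rates = -log(1 - p))))
  }
  if (!is.null(ctl$mode) && identical(ctl$mode, "continuous")) {
    if (ctl$q_in > 0)
      specs <- c(specs, list(control_spec("inflow", var = "S", q = ctl$q_in)))
    if (ctl$outflow_rate > 0)
      specs <- c(specs, list(control_spec(
        "removal",
        rates = setNames(rep(-log(1 - ctl$outflow_rate), length(vars)),
                         vars))))
  }
  specs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the least-squares fitting problem for a dataset
#'
#' Stacks every trajectory of the dataset into one residual vector: each
#' trajectory is re-simulated from its own initial row with its own control
#' constants, and the pointwise differences are scaled per variable by the
#' trajectory-wide mean magnitude so that variables of different size
#' contribute comparably. Integration failures are penalized with a large
#' finite residual on the uncompleted portion of the grid. For quadratic
#' Taylor templates a no-extra-roots penalty can be appended.
#'
#' @param dataset an `abm_trajectory` or list of them, each carrying its
#'   control setting in its metadata.
#' @param template a `fit_template`.
#' @param no_extra_roots optional list with elements `lower`, `upper` (the
#'   domain box), `n_probes`, `weight`: adds the penalty of
#'   [no_extra_roots_penalty()] to the objective.
#' @param fail_resid residual assigned to each point the integrator failed
#'   to reach.
#' @return A `fit_design` list; `residual_fn(theta)` is the Eq.-style
#'   stacked residual function of the free parameters.
#' @export
build_design <- function(dataset, template, no_extra_roots = NULL,
                         fail_resid = 1e3) {
  if (inherits(dataset, "abm_trajectory")) dataset <- list(dataset)
  stopifnot(length(dataset) >= 1, inherits(template, "fit_template"))
  vars <- template$vars
  parts <- lapply(dataset, function(traj) {
    stopifnot(all(vars %in% names(traj)))
    obs <- as.matrix(as.data.frame(traj)[vars])
    list(times = as.numeric(traj$step), obs = obs,
         x0 = obs[1, ], specs = traj_control_specs(traj, vars))
  })
  # one scale per variable across the whole dataset: a series driven near
  # extinction in one condition must not dominate the fit through a tiny
  # per-trajectory scale
  w_all <- colMeans(do.call(rbind, lapply(parts, function(p) abs(p$obs))))
  w_all <- pmax(w_all, 1e-8)
  parts <- lapply(parts, function(p) {
    p$w <- w_all
    p
  })
  n_resid <- sum(vapply(parts, function(p) length(p$obs), integer(1))) +
    as.integer(!is.null(no_extra_roots))
  resid_var <- unlist(lapply(parts, function(p)
    rep(vars, each = nrow(p$obs))))
  residual_fn <- function(theta) {
    model <- tryCatch(template$make(theta), error = function(e) NULL)
    if (is.null(model)) return(rep(fail_resid, n_resid))
    res <- lapply(parts, function(p) {
      mc <- if (length(p$specs)) with_control(model, p$specs) else model
      r <- matrix(fail_resid, nrow(p$obs), ncol(p$obs))
      sol <- integrate_surrogate(mc, p$x0, p$times, rtol = 1e-6, atol = 1e-8)
      k <- sol$n_ok
      if (k > 0) {
        sim <- as.matrix(sol$trajectory[vars])
        r[seq_len(k), ] <- sweep(sim - p$obs[seq_len(k), , drop = FALSE],
                                 2, p$w, "/")
      }
      as.numeric(r)
    })
    out <- unlist(res)
    if (!is.null(no_extra_roots)) {
      pen <- no_extra_roots_penalty(
        model, X0 = template$X0,
        lower = no_extra_roots$lower, upper = no_extra_roots$upper,
        n_probes = no_extra_roots$n_probes %||% 16)
      out <- c(out, sqrt((no_extra_roots$weight %||% 1e3) * pen))
    }
    out
  }
  structure(list(residual_fn = residual_fn, template = template,
                 dataset = dataset, parts = parts, n_resid = n_resid,
                 resid_var = resid_var),
            class = "fit_design")
}

# Finite-difference slopes of a trajectory (central in the interior).
traj_slopes <- function(times, obs) {
  n <- length(times)
  s <- obs * 0
  if (n >= 3) {
    dt <- times[3:n] - times[1:(n - 2)]
    s[2:(n - 1), ] <- (obs[3:n, , drop = FALSE] -
                         obs[1:(n - 2), , drop = FALSE]) / dt
  }
  s[1, ] <- (obs[2, ] - obs[1, ]) / (times[2] - times[1])
  s[n, ] <- (obs[n, ] - obs[n - 1, ]) / (times[n] - times[n - 1])
  s
}

#' Slope-method starting values for a fitting template
#'
#' Finite-difference slopes dX/dt (with each trajectory's known control
#' contribution subtracted) are regressed on the template's process terms:
#' ordinary least squares on the polynomial terms for the mechanistic and
#' Taylor families, log-linear regression of pseudo-inverse process fluxes
#' for the power-law families. Never returns out-of-bounds values;
#' degenerate (constant) data falls back to near-zero rate constants.
#'
#' @param dataset an `abm_trajectory` or list of them (>= 3 timepoints
#'   each).
#' @param template a `fit_template`.
#' @return Numeric starting vector `theta` of length `template$n_par`.
#' @export
initial_guess_slope <- function(dataset, template) {
  if (inherits(dataset, "abm_trajectory")) dataset <- list(dataset)
  vars <- template$vars
  n <- length(vars)
  X <- NULL; S <- NULL
  for (traj in dataset) {
    stopifnot(nrow(traj) >= 3)
    obs <- as.matrix(as.data.frame(traj)[vars])
    sl <- traj_slopes(as.numeric(traj$step), obs)
    specs <- traj_control_specs(traj, vars)
    if (length(specs))
      sl <- sl - t(apply(obs, 1, function(x) control_terms(specs, x, vars)))
    X <- rbind(X, obs); S <- rbind(S, sl)
  }
  clamp <- function(theta) pmin(pmax(theta, template$lower), template$upper)
  # keep power-law starts well inside the search box: extreme kinetic orders
  # or rate constants from a misbehaved regression make the first
  # integrations blow up and strand the optimizer
  clamp_pl <- function(la, g) {
    list(la = pmin(pmax(la, -8), 5), g = pmin(pmax(g, -2.5), 2.5))
  }
  degenerate <- all(abs(S) < 1e-10)

  if (template$family == "mech_swg") {
    if (degenerate) return(clamp(rep(log(1e-10), 8)))
    x <- X[, 1]; y <- X[, 2]; z <- X[, 3]
    pos <- function(v) pmax(v, 1e-10)
    cx <- coef(lm(S[, 1] ~ 0 + x + I(-x^2) + I(-x * y)))
    cy <- coef(lm(S[, 2] ~ 0 + I(x * y) + I(-y) + I(-y * z)))
    cz <- coef(lm(S[, 3] ~ 0 + I(y * z) + I(-z)))
    return(clamp(log(pos(c(cx, cy, cz)))))
  }

  if (template$family %in% c("linear", "quadratic")) {
    X0 <- template$X0
    Z <- sweep(X, 2, X0, "/") - 1            # normalized displacement
    Sz <- sweep(S, 2, X0, "/")               # normalized slopes
    nJ <- n^2
    theta <- numeric(template$n_par)
    if (template$family == "quadratic") {
      ut <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
      Q <- apply(ut, 1, function(ij) {
        f <- if (ij[1] == ij[2]) 0.5 else 1
        f * Z[, ij[1]] * Z[, ij[2]]
      })
      D <- cbind(Z, Q)
      for (i in seq_len(n)) {
        ci <- coef(lm(Sz[, i] ~ 0 + D))
        ci[!is.finite(ci)] <- 0
        theta[(i - 1) + seq(1, nJ, by = n)] <- ci[seq_len(n)]
        theta[nJ + (i - 1) * nrow(ut) + seq_len(nrow(ut))] <-
          ci[n + seq_len(nrow(ut))]
      }
    } else {
      for (i in seq_len(n)) {
        ci <- coef(lm(Sz[, i] ~ 0 + Z))
        ci[!is.finite(ci)] <- 0
        theta[(i - 1) + seq(1, nJ, by = n)] <- ci
      }
    }
    return(theta)
  }

  lX <- log(pmax(X, EPS_STATE))

  if (template$family == "gma") {
    m <- ncol(template$M)
    if (degenerate)
      return(clamp(c(rep(log(1e-10), m), rep(0, template$n_par - m))))
    Fm <- t(MASS::ginv(template$M) %*% t(S))   # least-norm process fluxes
    la <- numeric(m)
    G <- matrix(0, m, n)
    for (j in seq_len(m)) {
      fj <- Fm[, j]
      ok <- fj > max(1e-8, 0.01 * median(abs(fj)))
      free <- template$mask[j, ]
      if (sum(ok) >= sum(free) + 2 && any(free)) {
        fit <- tryCatch(lm(log(fj[ok]) ~ lX[ok, free, drop = FALSE]),
                        error = function(e) NULL)
        cf <- if (is.null(fit)) NULL else coef(fit)
        if (!is.null(cf) && all(is.finite(cf))) {
          la[j] <- cf[1]
          G[j, free] <- cf[-1]
        } else {
          la[j] <- log(max(median(fj[ok]), 1e-8))
        }
      } else {
        la[j] <- log(max(median(abs(fj)), 1e-8))
      }
    }
    cl <- clamp_pl(la, G)
    return(clamp(c(cl$la, cl$g[template$mask])))
  }

  if (template$family == "ssystem") {
    if (degenerate)
      return(clamp(c(rep(log(1e-10), 2 * n), rep(0, template$n_par - 2 * n))))
    la <- numeric(n); lb <- numeric(n)
    G <- matrix(0, n, n); H <- matrix(0, n, n)
    for (i in seq_len(n)) {
      si <- S[, i]
      scale_i <- max(median(abs(si)), 1e-8)
      for (sign_case in c(1, -1)) {
        ok <- sign_case * si > 0.05 * scale_i
        free <- if (sign_case > 0) template$gmask[i, ] else template$hmask[i, ]
        cf <- NULL
        if (sum(ok) >= sum(free) + 2 && any(free))
          cf <- tryCatch(coef(lm(log(sign_case * si[ok]) ~
                                   lX[ok, free, drop = FALSE])),
                         error = function(e) NULL)
        if (!is.null(cf) && all(is.finite(cf))) {
          if (sign_case > 0) { la[i] <- cf[1]; G[i, free] <- cf[-1] }
          else { lb[i] <- cf[1]; H[i, free] <- cf[-1] }
        } else {
          if (sign_case > 0) la[i] <- log(scale_i)
          else { lb[i] <- log(scale_i / max(mean(X[, i]), 1)); H[i, i] <- 1 }
        }
      }
    }
    clg <- clamp_pl(la, G); clh <- clamp_pl(lb, H)
    return(clamp(c(clg$la, clh$la, clg$g[template$gmask],
                   clh$g[template$hmask])))
  }

  if (template$family == "mm_metabolic") {
    M <- matrix(c(-1, 1, 0, 0, 0,
                  0, -1, 1, 0, 0,
                  0, 0, -1, 1, 0,
                  0, 0, -1, 0, 1), 5, 4)
    Fm <- t(MASS::ginv(M) %*% t(S))
    Vmax <- pmax(apply(Fm, 2, function(f) 2 * quantile(pmax(f, 0), 0.95)),
                 1e-4)
    subs <- c(1, 2, 3, 3)
    Km <- pmax(vapply(subs, function(j) median(X[, j]), numeric(1)), 1)
    Ki <- pmax(c(median(X[, 4]), median(X[, 5])), 1)
    return(clamp(log(c(Vmax, Km, Ki))))
  }

  stop("unknown template family: ", template$family)
}

#' Fit a surrogate by multi-start bounded nonlinear least squares
#'
#' Levenberg-Marquardt (via `minpack.lm`) from the slope-method start and
#' seeded perturbations of it; the best (lowest residual sum of squares)
#' start wins. Deterministic given the seed.
#'
#' @param design a [build_design()] object.
#' @param n_starts number of starts (first is unperturbed).
#' @param seed integer seed for the start perturbations.
#' @param theta0 optional starting vector overriding the slope method.
#' @param perturb_sd standard deviation of start perturbations.
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @return A `surrogate_fit`: list with the fitted `model`, `theta`, `ssr`,
#'   per-variable residual sums `rss_by_var`, start-by-start summary and
#'   convergence diagnostics.
#' @export
fit_surrogate <- function(design, n_starts = 10, seed = 1, theta0 = NULL,
                          perturb_sd = 0.3, maxiter = 100) {
  stopifnot(inherits(design, "fit_design"))
  set.seed(as.integer(seed))
  tpl <- design$template
  base <- if (is.null(theta0)) initial_guess_slope(design$dataset, tpl)
          else pmin(pmax(theta0, tpl$lower), tpl$upper)
  # a start whose residual is dominated by integration-failure penalties
  # gives the optimizer no gradient; shrink such starts toward the
  # template's neutral (always-integrable) point until they integrate
  fail_level <- 0.5 * 1e3^2 # half of one failed grid point
  repair <- function(theta) {
    for (t_mix in c(0, 0.33, 0.67, 1)) {
      cand <- (1 - t_mix) * theta + t_mix * tpl$neutral
      if (sum(design$residual_fn(cand)^2) < fail_level) return(cand)
    }
    tpl$neutral
  }
  base <- repair(base)
  starts <- list(base)
  if (n_starts > 1) {
    for (i in seq_len(n_starts - 1)) {
      pert <- base + stats::rnorm(length(base), 0, perturb_sd)
      starts[[i + 1]] <- repair(pmin(pmax(pert, tpl$lower), tpl$upper))
    }
  }
  best <- NULL
  start_log <- data.frame(start = seq_along(starts), ssr0 = NA_real_,
                    ssr = NA_real_, converged = NA)
  for (i in seq_along(starts)) {
    r0 <- design$residual_fn(starts[[i]])
    start_log$ssr0[i] <- sum(r0^2)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[[i]], lower = tpl$lower,
                         upper = tpl$upper, fn = design$residual_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ptol = 1e-10, ftol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- fit$deviance
    start_log$ssr[i] <- ssr
    start_log$converged[i] <- fit$info %in% 1:4
    if (is.finite(ssr) && (is.null(best) || ssr < best$deviance)) {
      best <- fit
      best$start_index <- i
    }
  }
  if (is.null(best)) stop("all starts failed to produce a finite residual")
  # Levenberg-Marquardt slows down near sloppy optima; restarting from the
  # incumbent resets the trust region and reliably grinds further down
  for (polish in 1:2) {
    ref <- tryCatch(
      minpack.lm::nls.lm(par = as.numeric(best$par), lower = tpl$lower,
                         upper = tpl$upper, fn = design$residual_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ptol = 1e-12, ftol = 1e-12)),
      error = function(e) NULL)
    if (is.null(ref) || !is.finite(ref$deviance) ||
        ref$deviance > best$deviance) break
    improved <- best$deviance - ref$deviance > 1e-4 * best$deviance
    ref$start_index <- best$start_index
    best <- ref
    if (!improved) break
  }
  theta <- as.numeric(best$par)
  resid <- design$residual_fn(theta)
  nv <- length(design$resid_var)
  rss_by_var <- tapply(resid[seq_len(nv)]^2, design$resid_var, sum)
  structure(list(theta = setNames(theta, tpl$theta_names),
                 model = tpl$make(theta), family = tpl$family,
                 ssr = sum(resid^2), residuals = resid,
                 rss_by_var = rss_by_var, info = best$info,
                 message = best$message, start_index = best$start_index,
                 starts = start_log, seed = seed),
            class = "surrogate_fit")
}

#' @export
print.surrogate_fit <- function(x, ...) {
  cat("<surrogate_fit>", x$family, "| ssr =", format(x$ssr, digits = 5),
      "| best start", x$start_index, "of", nrow(x$starts), "\n")
  invisible(x)
}

#' Penalty for steady states other than the expansion point
#'
#' Runs root-finding from quasi-random (Halton) starting points inside the
#' domain box; every distinct root found inside the box at a relative
#' distance greater than `dist_tol` from X0 adds 1 to the penalty. A
#' root-finding failure counts as no root; roots outside the box are
#' ignored. Zero iff no extra root was found.
#'
#' @param model a `surrogate`.
#' @param X0 the intended steady state.
#' @param lower,upper domain box (the region of interest of the control
#'   problem).
#' @param n_probes number of quasi-random starts.
#' @param dist_tol relative distance below which a root is identified with
#'   X0.
#' @return Non-negative integer penalty.
#' @export
no_extra_roots_penalty <- function(model, X0, lower, upper, n_probes = 16,
                                   dist_tol = 0.02) {
  n <- length(model$vars)
  stopifnot(length(lower) == n, length(upper) == n, all(upper > lower))
  pts <- halton_seq(n_probes, n)
  scale <- pmax(abs(X0), upper - lower)
  roots <- list()
  for (i in seq_len(n_probes)) {
    start <- lower + pts[i, ] * (upper - lower)
    ss <- tryCatch(steady_state(model, start, tol = 1e-6),
                   error = function(e) list(converged = FALSE))
    if (!isTRUE(ss$converged)) next
    x <- as.numeric(ss$x)
    if (any(x < lower) || any(x > upper)) next         # outside the box
    if (sqrt(sum(((x - X0) / scale)^2)) <= dist_tol) next  # it's X0
    dup <- any(vapply(roots, function(r)
      sqrt(sum(((x - r) / scale)^2)) < 1e-3, logical(1)))
    if (!dup) roots[[length(roots) + 1]] <- x
  }
  length(roots)
}

# Halton low-discrepancy sequence (radical inverse in coprime bases).
halton_seq <- function(n, dim) {
  bases <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29)[seq_len(dim)]
  sapply(bases, function(b) {
    vapply(seq_len(n), function(i) {
      f <- 1; r <- 0; k <- i
      while (k > 0) {
        f <- f / b
        r <- r + f * (k %% b)
        k <- k %/% b
      }
      r
    }, numeric(1))
  })
}

#' Fit a surrogate family to sheep-wolves-grass training datasets
#'
#' Convenience wrapper choosing the right template and starting strategy
#' per family. Power-law (GMA) fits start from the fitted mechanistic
#' model mapped onto the power-law processes (mass action being the
#' integer-order special case), which is markedly more reliable than a
#' generic slope start for this system; Taylor templates expand around the
#' tail-window steady state of the first (uncontrolled) dataset.
#'
#' @param datasets list of training `abm_trajectory` objects (typically
#'   from [swg_datasets()]).
#' @param family one of `"mech_swg"`, `"gma"`, `"ssystem"`, `"linear"`,
#'   `"quadratic"`.
#' @param seed,n_starts,maxiter passed to [fit_surrogate()].
#' @param X0 expansion point for the Taylor families (default: tail mean
#'   of the first dataset).
#' @return A `surrogate_fit`.
#' @export
fit_swg_surrogate <- function(datasets, family = c("mech_swg", "gma",
                                                   "ssystem", "linear",
                                                   "quadratic"),
                              seed = 1, n_starts = 3, maxiter = 60,
                              X0 = NULL) {
  family <- match.arg(family)
  vars <- c("grass", "sheep", "wolves")
  if (family %in% c("linear", "quadratic")) {
    if (is.null(X0)) X0 <- steady_state_tail(datasets[[1]])
    tpl <- template_taylor(X0, vars, order = if (family == "linear") 1 else 2)
    return(fit_surrogate(build_design(datasets, tpl), n_starts = n_starts,
                         seed = seed, maxiter = maxiter))
  }
  if (family == "ssystem") {
    return(fit_surrogate(build_design(datasets, template_ssystem(vars)),
                         n_starts = n_starts, seed = seed,
                         maxiter = maxiter))
  }
  mech <- fit_surrogate(build_design(datasets, template_mech_swg()),
                        n_starts = n_starts, seed = seed, maxiter = maxiter)
  if (family == "mech_swg") return(mech)
  k <- exp(unname(mech$theta))
  G0 <- rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 0), c(0, 1, 0),
              c(0, 1, 1), c(0, 1, 1), c(0, 0, 1))
  theta0 <- c(log(pmax(k[-2], 1e-8)), as.numeric(G0))
  fit_surrogate(build_design(datasets, template_gma(swg_stoichiometry(),
                                                    vars)),
                n_starts = n_starts, seed = seed, theta0 = theta0,
                maxiter = maxiter)
}
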