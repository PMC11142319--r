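# Power-law bases are floored at EPS_STATE so that derivatives stay finite
# at extinction states (a documented deviation from the pure formulas).
EPS_STATE <- 1e-12

new_surrogate <- function(family, vars, params, rhs_core, ...) {
  structure(list(family = family, vars = vars, params = params,
                 rhs_core = rhs_core, control = list(), ...),
            class = "surrogate")
}

#' @export
print.surrogate <- function(x, ...) {
  cat("<surrogate> family:", x$family, "| vars:",
      paste(x$vars, collapse = ", "),
      if (length(x$control)) sprintf("| %d control term(s)", length(x$control)),
      "\n")
  invisible(x)
}

#' Generic mechanistic surrogate from a stoichiometric matrix
#'
#' Builds the right-hand side dX/dt = M F(X) from an n x m stoichiometric
#' matrix and a list of m process-flux functions, each mapping the named
#' state vector to a scalar flux.
#'
#' @param M n x m stoichiometric matrix (rows = variables).
#' @param processes list of m functions `function(x) flux`.
#' @param vars state-variable names (length n).
#' @return A `surrogate` of family `"mechanistic"`.
#' @export
surrogate_mechanistic <- function(M, processes, vars) {
  M <- as.matrix(M)
  stopifnot(nrow(M) == length(vars), ncol(M) == length(processes))
  new_surrogate("mechanistic", vars, list(M = M, processes = processes),
                rhs_core = function(x) {
                  F <- vapply(processes, function(f) f(x), numeric(1))
                  drop(M %*% F)
                })
}

#' Mechanistic (Lotka-Volterra) surrogate of the sheep-wolves-grass model
#'
#' Seven processes over grass X, sheep Y, wolves Z: logistic grass growth
#' (two constants k1 X - k2 X^2), grazing k3 X Y, sheep birth k4 X Y, sheep
#' death k5 Y, predation k6 Y Z, wolf birth k7 Y Z, wolf death k8 Z:
#' \deqn{dX/dt = k_1 X - k_2 X^2 - k_3 X Y}
#' \deqn{dY/dt = k_4 X Y - k_5 Y - k_6 Y Z}
#' \deqn{dZ/dt = k_7 Y Z - k_8 Z}
#'
#' @param k numeric vector of 8 non-negative rate constants, in the order
#'   above.
#' @return A `surrogate` of family `"mech_swg"` over
#'   `c("grass", "sheep", "wolves")`.
#' @export
surrogate_mech_swg <- function(k) {
  stopifnot(length(k) == 8, all(k >= 0))
  k <- unname(k)
  new_surrogate("mech_swg", c("grass", "sheep", "wolves"), list(k = k),
                rhs_core = function(x) {
                  X <- x[1]; Y <- x[2]; Z <- x[3]
                  c(k[1] * X - k[2] * X^2 - k[3] * X * Y,
                    k[4] * X * Y - k[5] * Y - k[6] * Y * Z,
                    k[7] * Y * Z - k[8] * Z)
                })
}

#' Generalized mass action (power-law) surrogate
#'
#' Every process j is the power law \eqn{F_j = \alpha_j \prod_k X_k^{g_{jk}}}
#' with positive rate constant and real kinetic orders (positive =
#' activation, negative = inhibition, zero = no dependence); processes
#' combine through the stoichiometric matrix, dX/dt = M F. Mass action is
#' the integer-order special case. States are floored at 1e-12 before
#' exponentiation.
#'
#' @param M n x m stoichiometric matrix.
#' @param alpha positive rate constants (length m).
#' @param G m x n kinetic-order matrix.
#' @param vars state-variable names.
#' @return A `surrogate` of family `"gma"`.
#' @export
surrogate_gma <- function(M, alpha, G, vars) {
  M <- as.matrix(M); G <- as.matrix(G)
  stopifnot(nrow(M) == length(vars), ncol(M) == length(alpha),
            nrow(G) == length(alpha), ncol(G) == length(vars),
            all(alpha > 0))
  new_surrogate("gma", vars, list(M = M, alpha = alpha, G = G),
                rhs_core = function(x) {
                  lx <- log(pmax(x, EPS_STATE))
                  drop(M %*% (alpha * exp(drop(G %*% lx))))
                })
}

#' S-system surrogate
#'
#' Each state's derivative is the difference of one aggregate inflow and one
#' aggregate outflow power law,
#' \deqn{\dot X_i = \alpha_i \prod_j X_j^{g_{ij}} - \beta_i \prod_j X_j^{h_{ij}},}
#' for a total of 2n + n^2 parameters.
#'
#' @param alpha,beta positive rate constants (length n).
#' @param G,H n x n kinetic-order matrices.
#' @param vars state-variable names.
#' @return A `surrogate` of family `"ssystem"`.
#' @export
surrogate_ssystem <- function(alpha, G, beta, H, vars) {
  G <- as.matrix(G); H <- as.matrix(H)
  n <- length(vars)
  stopifnot(length(alpha) == n, length(beta) == n,
            all(dim(G) == n), all(dim(H) == n),
            all(alpha > 0), all(beta > 0))
  new_surrogate("ssystem", vars,
                list(alpha = alpha, G = G, beta = beta, H = H),
                rhs_core = function(x) {
                  lx <- log(pmax(x, EPS_STATE))
                  alpha * exp(drop(G %*% lx)) - beta * exp(drop(H %*% lx))
                })
}

#' Taylor (steady-state expansion) surrogate
#'
#' First order: dX/dt = J (X - X0). Second order adds the quadratic term
#' \eqn{\frac12 (X - X_0)^T H_i (X - X_0)} to equation i, with symmetric
#' Hessian matrices. Parameter counts are n^2 and (3 n^2 + n^3) / 2.
#'
#' @param X0 steady-state vector (length n).
#' @param J n x n Jacobian.
#' @param H optional list of n symmetric n x n Hessians (order 2).
#' @param vars state-variable names.
#' @return A `surrogate` of family `"linear"` or `"quadratic"`.
#' @export
surrogate_taylor <- function(X0, J, H = NULL, vars) {
  J <- as.matrix(J)
  n <- length(vars)
  stopifnot(length(X0) == n, all(dim(J) == n))
  if (!is.null(H)) {
    stopifnot(length(H) == n)
    for (Hi in H) {
      Hi <- as.matrix(Hi)
      if (!isTRUE(all.equal(Hi, t(Hi), tolerance = 1e-8)))
        stop("Hessian matrices must be symmetric")
    }
  }
  X0 <- unname(X0)
  new_surrogate(if (is.null(H)) "linear" else "quadratic", vars,
                list(X0 = X0, J = J, H = H),
                rhs_core = function(x) {
                  d <- x - X0
                  out <- drop(J %*% d)
                  if (!is.null(H))
                    out <- out + 0.5 * vapply(H, function(Hi)
                      drop(crossprod(d, Hi %*% d)), numeric(1))
                  out
                })
}

#' Michaelis-Menten mechanistic surrogate of the metabolic pathway
#'
#' Irreversible Michaelis-Menten fluxes v = Vmax X / (Km + X) for the four
#' reactions S -> A -> B -> (R, T), with the two feedback inhibitions
#' entering as Vmax / (1 + I / Ki) factors (R inhibits the first reaction,
#' T the second). State variables are the five free-metabolite counts.
#'
#' @param Vmax,Km positive vectors of length 4 (one per reaction).
#' @param Ki positive vector of length 2 (inhibition constants of R on
#'   reaction 1 and T on reaction 2).
#' @return A `surrogate` of family `"mm_metabolic"` over S, A, B, R, T.
#' @export
surrogate_mm_metabolic <- function(Vmax, Km, Ki) {
  stopifnot(length(Vmax) == 4, length(Km) == 4, length(Ki) == 2,
            all(Vmax > 0), all(Km > 0), all(Ki > 0))
  new_surrogate("mm_metabolic", c("S", "A", "B", "R", "T"),
                list(Vmax = Vmax, Km = Km, Ki = Ki),
                rhs_core = function(x) {
                  x <- pmax(x, 0)
                  v1 <- Vmax[1] * x[1] / (Km[1] + x[1]) / (1 + x[4] / Ki[1])
                  v2 <- Vmax[2] * x[2] / (Km[2] + x[2]) / (1 + x[5] / Ki[2])
                  v3 <- Vmax[3] * x[3] / (Km[3] + x[3])
                  v4 <- Vmax[4] * x[3] / (Km[4] + x[3])
                  c(-v1, v1 - v2, v2 - v3 - v4, v3, v4)
                })
}

#' Continuous control terms for a surrogate
#'
#' Three kinds are supported: `"removal"` adds -rate_i * X_i to the named
#' variables (constant per-capita removal, the continuous counterpart of
#' per-tick Bernoulli removal); `"inflow"` adds a constant +q to one
#' variable; `"additive"` adds B u for a constant input vector u. Zero
#' constants leave the right-hand side unchanged.
#'
#' @param kind one of `"removal"`, `"inflow"`, `"additive"`.
#' @param rates named non-negative rates (removal kind).
#' @param var target variable name (inflow kind).
#' @param q constant inflow (inflow kind).
#' @param B,u input matrix and constant input vector (additive kind).
#' @return An object of class `control_spec`.
#' @export
control_spec <- function(kind = c("removal", "inflow", "additive"),
                         rates = NULL, var = NULL, q = NULL,
                         B = NULL, u = NULL) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    removal = {
      stopifnot(!is.null(rates), !is.null(names(rates)), all(rates >= 0))
      list(kind = kind, rates = rates)
    },
    inflow = {
      stopifnot(is.character(var), length(var) == 1, q >= 0)
      list(kind = kind, var = var, q = q)
    },
    additive = {
      B <- as.matrix(B)
      stopifnot(nrow(B) >= 1, ncol(B) == length(u))
      list(kind = kind, B = B, u = u)
    })
  structure(spec, class = "control_spec")
}

control_terms <- function(specs, x, vars) {
  out <- numeric(length(vars))
  for (sp in specs) {
    out <- out + switch(sp$kind,
      removal = {
        v <- numeric(length(vars))
        ix <- match(names(sp$rates), vars)
        v[ix] <- -sp$rates * x[ix]
        v
      },
      inflow = {
        v <- numeric(length(vars))
        v[match(sp$var, vars)] <- sp$q
        v
      },
      additive = drop(sp$B %*% sp$u))
  }
  out
}

#' Attach control terms to a surrogate
#'
#' Returns a new surrogate whose right-hand side adds the control term(s);
#' the original model is unchanged. A zero-valued specification is the
#' identity on the RHS.
#'
#' @param model a `surrogate`.
#' @param spec a [control_spec()] or a list of them.
#' @return The controlled `surrogate`.
#' @export
with_control <- function(model, spec) {
  stopifnot(inherits(model, "surrogate"))
  if (inherits(spec, "control_spec")) spec <- list(spec)
  for (sp in spec) {
    bad <- switch(sp$kind,
      removal = setdiff(names(sp$rates), model$vars),
      inflow = setdiff(sp$var, model$vars),
      additive = if (nrow(sp$B) != length(model$vars)) "B" else character(0))
    if (length(bad))
      stop("control references unknown variable(s): ",
           paste(bad, collapse = ", "))
  }
  model$control <- c(model$control, spec)
  model
}

#' Evaluate a surrogate right-hand side
#'
#' Pure function of the state: the family RHS plus any attached control
#' terms.
#'
#' @param model a `surrogate`.
#' @param x state vector (named or in `model$vars` order).
#' @param t time (ignored; present for integrator compatibility).
#' @return Named derivative vector.
#' @export
rhs_eval <- function(model, x, t = 0) {
  if (!is.null(names(x))) x <- x[model$vars]
  x <- unname(x)
  if (length(x) != length(model$vars))
    stop("state dimension mismatch: expected ", length(model$vars))
  out <- model$rhs_core(x)
  if (length(model$control))
    out <- out + control_terms(model$control, x, model$vars)
  setNames(out, model$vars)
}

# Pre-compose the RHS with its control terms into one lean closure over an
# unnamed state vector (the hot path of integration and root-finding).
compile_rhs <- function(model) {
  core <- model$rhs_core
  if (!length(model$control)) return(core)
  n <- length(model$vars)
  cvec <- numeric(n)
  rvec <- numeric(n)
  for (sp in model$control) {
    switch(sp$kind,
           removal = {
             ix <- match(names(sp$rates), model$vars)
             rvec[ix] <- rvec[ix] + sp$rates
           },
           inflow = {
             ix <- match(sp$var, model$vars)
             cvec[ix] <- cvec[ix] + sp$q
           },
           additive = {
             cvec <- cvec + drop(sp$B %*% sp$u)
           })
  }
  function(x) core(x) + cvec - rvec * x
}

#' Parameter count of a surrogate family
#'
#' Linear Taylor: n^2. Quadratic Taylor: (3 n^2 + n^3) / 2. S-system:
#' 2n + n^2. GMA: m (1 + n) before masking. Mechanistic families report
#' their rate-constant count.
#'
#' @param family one of `"linear"`, `"quadratic"`, `"ssystem"`, `"gma"`,
#'   `"mech_swg"`, `"mm_metabolic"`.
#' @param n number of state variables.
#' @param m number of processes (GMA only).
#' @return Integer parameter count.
#' @export
param_count <- function(family, n, m = NULL) {
  stopifnot(n >= 1)
  switch(family,
         linear = n^2,
         quadratic = (3 * n^2 + n^3) / 2,
         ssystem = 2 * n + n^2,
         gma = {
           stopifnot(!is.null(m))
           m * (1 + n)
         },
         mech_swg = 8,
         mm_metabolic = 10,
         stop("unknown family: ", family))
}

#' Integrate a surrogate over a time grid
#'
#' Adaptive, stiffness-capable integration (lsoda). Failures -- a state
#' going non-finite, step-size collapse, or the integrator giving up before
#' the end of the grid -- are reported as a structured outcome rather than
#' an error, so that fitting and control search can penalize them.
#'
#' @param model a `surrogate` (with any control already attached).
#' @param x0 initial state, named or in `model$vars` order.
#' @param times strictly increasing time grid.
#' @param rtol,atol integration tolerances.
#' @param method a `deSolve` method name.
#' @return A `surrogate_solution`: list with `success`, `trajectory` (data
#'   frame `step` + variables, possibly truncated on failure), `n_ok`
#'   (completed grid points) and `message`.
#' @export
integrate_surrogate <- function(model, x0, times, rtol = 1e-6, atol = 1e-9,
                                method = "lsoda") {
  stopifnot(length(times) >= 2)
  if (any(diff(times) <= 0)) stop("invalid time grid")
  if (!is.null(names(x0))) x0 <- x0[model$vars]
  x0 <- unname(as.numeric(x0))
  if (any(!is.finite(x0))) stop("non-finite initial state")
  f <- compile_rhs(model)
  fn <- function(t, y, parms) list(f(y))
  msgs <- character(0)
  # capture.output() swallows the solver's Fortran diagnostics, which
  # bypass R's condition system
  utils::capture.output(out <- withCallingHandlers(
    tryCatch(deSolve::ode(y = setNames(x0, model$vars), times = times,
                          func = fn, parms = NULL, method = method,
                          rtol = rtol, atol = atol,
                          maxsteps = 10000),
             error = function(e) e),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    }))
  if (inherits(out, "error")) {
    return(structure(list(success = FALSE, trajectory = NULL, n_ok = 0L,
                          message = conditionMessage(out)),
                     class = "surrogate_solution"))
  }
  m <- as.matrix(out)
  finite <- apply(is.finite(m), 1, all)
  n_ok <- if (all(finite)) nrow(m) else max(0L, which(!finite)[1] - 1L)
  full <- n_ok == length(times) && length(msgs) == 0
  df <- as.data.frame(m[seq_len(n_ok), , drop = FALSE])
  names(df) <- c("step", model$vars)
  structure(list(success = full, trajectory = df, n_ok = n_ok,
                 message = if (length(msgs)) paste(msgs, collapse = "; ")
                           else if (!full) "non-finite state" else ""),
            class = "surrogate_solution")
}

#' Locate a steady state of a surrogate
#'
#' Numerical root of the (controlled) right-hand side, by damped Newton
#' iteration with a finite-difference Jacobian and a least-squares fallback.
#' For ABM data the alternative estimator is [steady_state_tail()].
#'
#' @param model a `surrogate`.
#' @param guess starting state.
#' @param lower,upper optional domain box; roots outside are rejected.
#' @param tol residual norm declaring convergence.
#' @return List with `x` (root), `residual` and `converged`.
#' @export
steady_state <- function(model, guess, lower = NULL, upper = NULL,
                         tol = 1e-9) {
  if (!is.null(names(guess))) guess <- guess[model$vars]
  f <- compile_rhs(model)
  guess <- as.numeric(guess)
  scale <- pmax(abs(guess), 1)
  snorm <- function(x) {
    fx <- f(x)
    if (!all(is.finite(fx))) return(Inf)
    sqrt(sum((fx / scale)^2))
  }
  newton <- function(x) {
    for (it in 1:60) {
      fx <- f(x)
      if (!all(is.finite(fx))) return(NULL)
      nrm <- sqrt(sum((fx / scale)^2))
      if (nrm < 1e-13) return(x)
      J <- jacobian_fd(f, x)
      step <- tryCatch(solve(J, -fx), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) return(x)
      lam <- 1
      repeat {
        xn <- x + lam * step
        if (snorm(xn) < nrm) break
        lam <- lam / 2
        if (lam < 1e-8) return(x)
      }
      x <- x + lam * step
    }
    x
  }
  # Newton from the guess, then from geometric perturbations of it (robust
  # against a singular Jacobian exactly at the guess)
  starts <- list(guess)
  for (fac in c(2, 0.5, 4, 8, 0.25))
    starts[[length(starts) + 1]] <- guess * fac + 0.1 * scale * (fac - 1)
  best <- guess
  for (s in starts) {
    cand <- newton(s)
    if (!is.null(cand) && snorm(cand) < snorm(best)) best <- cand
    if (snorm(best) < 1e-13) break
  }
  if (snorm(best) > tol) {
    obj <- function(z) {
      v <- snorm(z)
      if (!is.finite(v)) 1e12 else v^2
    }
    op <- optim(best, obj, method = if (length(guess) == 1) "BFGS"
                                    else "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-15))
    polished <- newton(op$par)
    if (!is.null(polished) && snorm(polished) < snorm(best)) best <- polished
    else if (snorm(op$par) < snorm(best)) best <- op$par
  }
  x <- best
  res <- sqrt(sum(f(x)^2))
  inside <- TRUE
  if (!is.null(lower)) inside <- inside && all(x >= lower - 1e-9)
  if (!is.null(upper)) inside <- inside && all(x <= upper + 1e-9)
  list(x = setNames(x, model$vars), residual = res,
       converged = snorm(x) <= tol && inside)
}

jacobian_fd <- function(f, x, h = NULL) {
  n <- length(x)
  if (is.null(h)) h <- pmax(abs(x), 1) * 1e-7
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    xp <- x; xp[j] <- xp[j] + h[j]
    xm <- x; xm[j] <- xm[j] - h[j]
    J[, j] <- (f(xp) - f(xm)) / (2 * h[j])
  }
  J
}
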