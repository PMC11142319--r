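#' Construct a macrostate trajectory
#'
#' A trajectory is a data frame with an integer `step` column (strictly
#' increasing), one non-negative numeric column per state variable, and a
#' metadata list (source, params, control, seed, realizations averaged)
#' carried in `attr(, "meta")`. Trajectories are the currency between the
#' ABM simulators and the surrogate-fitting machinery.
#'
#' @param df data frame with a `step` column first.
#' @param meta metadata list.
#' @param vars state-variable columns; defaults to all non-`step` columns.
#' @return An object of class `abm_trajectory`.
#' @export
as_trajectory <- function(df, meta = list(), vars = NULL) {
  stopifnot(is.data.frame(df), "step" %in% names(df))
  if (is.null(vars)) vars <- setdiff(names(df), "step")
  if (nrow(df) > 1 && any(diff(df$step) <= 0))
    stop("trajectory time must be strictly increasing")
  if (any(vapply(df[vars], function(v) any(!is.finite(v)), logical(1))))
    stop("trajectory contains missing or non-finite values")
  if (any(vapply(df[vars], function(v) any(v < 0), logical(1))))
    stop("trajectory contains negative values")
  structure(df, meta = meta, vars = vars,
            class = c("abm_trajectory", "data.frame"))
}

#' @export
print.abm_trajectory <- function(x, ...) {
  vars <- attr(x, "vars")
  cat("<abm_trajectory> ", nrow(x), " timepoints, vars: ",
      paste(vars, collapse = ", "), "\n", sep = "")
  print(head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

#' Variable columns of a trajectory
#' @param traj an `abm_trajectory`.
#' @return Character vector of state-variable names.
#' @export
trajectory_vars <- function(traj) attr(traj, "vars")

#' Thin a trajectory to every `by`-th timepoint
#'
#' Keeps the first row and every `by`-th row thereafter (the last row is
#' always retained). Used to keep least-squares designs to a manageable
#' number of residuals.
#'
#' @param traj an `abm_trajectory`.
#' @param by positive integer stride.
#' @return The thinned `abm_trajectory`.
#' @export
thin_trajectory <- function(traj, by) {
  stopifnot(by >= 1)
  keep <- sort(unique(c(seq(1, nrow(traj), by = by), nrow(traj))))
  out <- as.data.frame(traj)[keep, , drop = FALSE]
  rownames(out) <- NULL
  as_trajectory(out, meta = attr(traj, "meta"), vars = attr(traj, "vars"))
}

#' Pointwise average of repeated ABM realizations
#'
#' All runs must share the same time grid and variables. Returns the
#' pointwise mean trajectory; the pointwise standard deviation across runs
#' is attached as `attr(, "sd")`.
#'
#' @param runs list of `abm_trajectory` objects.
#' @return The averaged `abm_trajectory`; its metadata records the number of
#'   realizations and the seeds of the runs averaged.
#' @export
average_realizations <- function(runs) {
  stopifnot(length(runs) >= 1)
  vars <- attr(runs[[1]], "vars")
  steps <- runs[[1]]$step
  for (r in runs) {
    if (!identical(r$step, steps) || !identical(attr(r, "vars"), vars))
      stop("realizations have mismatched time grids or variables")
  }
  arr <- vapply(runs, function(r) as.matrix(as.data.frame(r)[vars]),
                matrix(0, length(steps), length(vars)))
  mu <- apply(arr, c(1, 2), mean)
  sdev <- if (length(runs) > 1) apply(arr, c(1, 2), sd) else mu * 0
  df <- data.frame(step = steps, mu)
  names(df) <- c("step", vars)
  meta <- attr(runs[[1]], "meta")
  meta$n_realizations <- length(runs)
  meta$seeds <- vapply(runs, function(r) {
    s <- attr(r, "meta")$seed
    if (is.null(s)) NA_integer_ else as.integer(s)
  }, integer(1))
  out <- as_trajectory(df, meta = meta, vars = vars)
  attr(out, "sd") <- data.frame(step = steps, sdev)
  out
}

#' Write a trajectory as CSV plus a JSON metadata sidecar
#'
#' The CSV holds `step` and the variable columns; the sidecar (same path
#' with extension `.json`) serializes the metadata. The round trip through
#' [read_trajectory()] is lossless up to numeric formatting.
#'
#' @param traj an `abm_trajectory`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  meta <- attr(traj, "meta")
  meta$vars <- attr(traj, "vars")
  jsonlite::write_json(serialize_meta(meta), sidecar_path(path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]*$", ".json", path)

serialize_meta <- function(x) {
  if (is.function(x)) return(NULL)
  if (is.list(x)) return(lapply(unclass(x), serialize_meta))
  x
}

#' Read a trajectory written by [write_trajectory()]
#'
#' Validates monotone time and non-negative values on read. A missing
#' sidecar is not an error: the trajectory is returned with empty metadata
#' and a warning.
#'
#' @param path CSV file path.
#' @return An `abm_trajectory`.
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!"step" %in% names(df))
    stop("malformed trajectory file (no 'step' column): ", path)
  if (nrow(df) > 1 && any(diff(df$step) <= 0)) {
    bad <- which(diff(df$step) <= 0)[1] + 1
    stop("non-increasing time at line ", bad + 1, " of ", path)
  }
  sc <- sidecar_path(path)
  meta <- list()
  vars <- NULL
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    vars <- meta$vars
    meta$vars <- NULL
  } else {
    warning("no metadata sidecar for ", path)
  }
  as_trajectory(df, meta = meta, vars = vars)
}

#' @export
plot.abm_trajectory <- function(x, ...) {
  vars <- attr(x, "vars")
  graphics::matplot(x$step, as.matrix(as.data.frame(x)[vars]), type = "l",
                    lty = 1, xlab = "step", ylab = "count", ...)
  graphics::legend("topright", legend = vars, col = seq_along(vars), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Tail-window mean of (averaged) trajectories
#'
#' Steady-state estimator for stochastic ABM data: the mean of each state
#' variable over the final `tail_frac` of the time window, averaged over
#' the supplied trajectories.
#'
#' @param trajs an `abm_trajectory` or list of them (e.g. repeated runs).
#' @param tail_frac fraction of timepoints in the tail window (default 0.5).
#' @return Named vector of steady-state estimates.
#' @export
steady_state_tail <- function(trajs, tail_frac = 0.5) {
  if (inherits(trajs, "abm_trajectory")) trajs <- list(trajs)
  vars <- attr(trajs[[1]], "vars")
  est <- vapply(trajs, function(tr) {
    n <- nrow(tr)
    rows <- seq.int(ceiling(n * (1 - tail_frac)) + 1L, n)
    colMeans(as.data.frame(tr)[rows, vars, drop = FALSE])
  }, numeric(length(vars)))
  if (is.null(dim(est))) est <- matrix(est, nrow = length(vars))
  setNames(rowMeans(est), vars)
}
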