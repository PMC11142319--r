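#' Read / write an experiment configuration
#'
#' Configurations are YAML (or JSON) files with fields `abm` ("swg" or
#' "metabolic"), `params` (ABM parameter overrides), `datasets` (n_steps,
#' n_real, thin), `family` (surrogate family), `fitting` (n_starts,
#' maxiter), `control` (problem settings) and a global `seed` from which
#' every stage derives its child streams deterministically. The round trip
#' through [write_config()] is lossless.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return The configuration list.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config configuration list.
#' @return `write_config` returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  else yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the simulate - fit - solve - lift - validate pipeline
#'
#' Executes the full surrogate-control loop for one configuration:
#' (1) generate the training datasets, (2) fit the configured surrogate
#' family, (3) solve the configured control problem on the surrogate,
#' (4) lift the solution to ABM terms, and (5, optional) validate by an
#' ABM grid search. Each stage writes its output under `out_dir` and is
#' skipped on re-run if its output already exists, so deleting one output
#' re-executes only that stage and the ones after it. A manifest recording
#' the configuration hash, per-stage seeds and output files is written at
#' the end.
#'
#' @param config configuration list (see [read_config()]).
#' @param out_dir output directory.
#' @param validate run the ABM grid-search validation stage.
#' @return The manifest list, invisibly; its `results` entry holds the
#'   fitted model summary, the control solution and the lifted policy.
#' @export
run_pipeline <- function(config, out_dir, validate = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1
  family <- config$family %||% "mech_swg"
  known <- c("mech_swg", "gma", "ssystem", "linear", "quadratic",
             "mm_metabolic")
  if (!family %in% known)
    stop("unknown surrogate family: ", family)
  stages <- character(0)

  # stage 1: datasets
  ds_dir <- file.path(out_dir, "datasets")
  if (!file.exists(file.path(ds_dir, "manifest.json"))) {
    make_datasets(config, ds_dir)
    stages <- c(stages, "datasets")
  }
  man <- jsonlite::read_json(file.path(ds_dir, "manifest.json"),
                             simplifyVector = TRUE)
  dataset <- lapply(man$datasets, function(nm)
    read_trajectory(file.path(ds_dir, paste0("dataset_", nm, ".csv"))))
  names(dataset) <- man$datasets
  use <- config$fitting$use_datasets %||% names(dataset)
  train <- dataset[use]

  # stage 2: fit
  fit_path <- file.path(out_dir, "fit.json")
  if (!file.exists(fit_path)) {
    tpl <- template_for(family, config, train)
    design <- build_design(train, tpl)
    fit <- fit_surrogate(design,
                         n_starts = config$fitting$n_starts %||% 5,
                         seed = seed + 11,
                         maxiter = config$fitting$maxiter %||% 60)
    jsonlite::write_json(
      list(family = family, theta = unclass(fit$theta), ssr = fit$ssr,
           start_index = fit$start_index,
           X0 = if (!is.null(tpl$X0)) tpl$X0),
      fit_path, auto_unbox = TRUE, digits = NA)
    stages <- c(stages, "fit")
  }
  fitrec <- jsonlite::read_json(fit_path, simplifyVector = TRUE)
  tpl <- template_for(family, config, train, X0 = fitrec$X0)
  model <- tpl$make(as.numeric(fitrec$theta))

  # stages 3-4: solve the configured control problem and lift it
  sol_path <- file.path(out_dir, "solution.json")
  if (identical(config$abm, "swg")) {
    x0 <- steady_state_tail(dataset[["I"]])
    sol <- solve_removal_rates(
      model, x0,
      target = unlist(config$control$target %||%
                        list(sheep = 1.1, wolves = 0.5)),
      horizon = config$control$horizon %||% 1000)
    policy <- lift_to_abm(sol, "swg")
    rec <- list(kind = "removal", kappa = as.list(sol$kappa),
                kappa_tick = as.list(sol$kappa_tick),
                feasible = sol$feasible, distance = sol$distance)
  } else {
    sol <- solve_inflow(model,
                        bounds = config$control$bounds %||% c(0, 1),
                        horizon = config$control$horizon %||% 5000)
    policy <- if (sol$success) lift_to_abm(sol, "metabolic") else NULL
    rec <- list(kind = "inflow", success = sol$success,
                q_opt = sol$q_opt %||% NA, loss_opt = sol$loss_opt %||% NA)
  }
  jsonlite::write_json(rec, sol_path, auto_unbox = TRUE, digits = NA)
  stages <- c(stages, "solve")

  # stage 5: grid-search validation on the ABM
  validation <- NULL
  if (validate) {
    if (identical(config$abm, "swg")) {
      params <- do.call(swg_params, config$params %||% list())
      x0v <- steady_state_tail(dataset[["I"]])
      validation <- swg_grid_search(
        params, x0v, reps = config$validate$reps %||% 5,
        seed = seed + 77)
    } else {
      cp <- do.call(metabolic_params,
                    c(list(mode = "continuous"),
                      config$params_continuous %||% list()))
      validation <- metabolic_inflow_grid_search(
        cp, reps = config$validate$reps %||% 5,
        n_steps = config$validate$n_steps %||% 2000, seed = seed + 77)
    }
    stages <- c(stages, "validate")
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_path)),
                   seed = seed, stages_run = stages,
                   files = list.files(out_dir, recursive = TRUE),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$results <- list(fit = fitrec, solution = rec, policy = policy,
                           validation = validation, model = model)
  invisible(manifest)
}

# Build the fitting template a configuration asks for.
template_for <- function(family, config, train, X0 = NULL) {
  if (identical(config$abm, "swg")) {
    vars <- c("grass", "sheep", "wolves")
    switch(family,
           mech_swg = template_mech_swg(),
           gma = template_gma(swg_stoichiometry(), vars),
           ssystem = template_ssystem(vars),
           linear = ,
           quadratic = {
             if (is.null(X0)) X0 <- steady_state_tail(train[["I"]])
             template_taylor(X0, vars,
                             order = if (family == "linear") 1 else 2)
           },
           stop("family ", family, " not available for the swg ABM"))
  } else {
    vars <- c("S", "A", "B", "R", "T")
    switch(family,
           mm_metabolic = template_mm_metabolic(),
           gma = template_gma(metabolic_stoichiometry(), vars),
           ssystem = template_ssystem(vars),
           linear = ,
           quadratic = {
             if (is.null(X0))
               X0 <- pmax(steady_state_tail(train[[length(train)]]), 1)
             template_taylor(X0, vars,
                             order = if (family == "linear") 1 else 2)
           },
           stop("family ", family, " not available for the metabolic ABM"))
  }
}

#' Stoichiometric matrices of the two reference systems
#'
#' `swg_stoichiometry()`: grass/sheep/wolves against the seven processes
#' (grass growth, grazing, sheep birth, sheep death, predation, wolf birth,
#' wolf death) used by the power-law surrogate. `metabolic_stoichiometry()`:
#' the five free metabolites against the four reactions.
#'
#' @return Integer matrix with named rows (variables) and columns
#'   (processes).
#' @export
swg_stoichiometry <- function() {
  M <- matrix(0L, 3, 7,
              dimnames = list(c("grass", "sheep", "wolves"),
                              c("growth", "grazing", "sheep_birth",
                                "sheep_death", "predation", "wolf_birth",
                                "wolf_death")))
  M["grass", c("growth", "grazing")] <- c(1L, -1L)
  M["sheep", c("sheep_birth", "sheep_death", "predation")] <- c(1L, -1L, -1L)
  M["wolves", c("wolf_birth", "wolf_death")] <- c(1L, -1L)
  M
}

#' @rdname swg_stoichiometry
#' @export
metabolic_stoichiometry <- function() {
  M <- matrix(0L, 5, 4,
              dimnames = list(c("S", "A", "B", "R", "T"),
                              c("v1", "v2", "v3", "v4")))
  M["S", "v1"] <- -1L
  M["A", c("v1", "v2")] <- c(1L, -1L)
  M["B", c("v2", "v3", "v4")] <- c(1L, -1L, -1L)
  M["R", "v3"] <- 1L
  M["T", "v4"] <- 1L
  M
}
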