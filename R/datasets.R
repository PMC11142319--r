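# Training-dataset presets. The surrogate models are trained against
# averaged ABM realizations: uncontrolled baselines from two initial
# conditions plus runs with control exerted on each controllable variable,
# so that solving the control problem on the surrogate is an interpolation
# rather than an extrapolation task.

#' Build the five sheep-wolves-grass training datasets
#'
#' Datasets I and II are uncontrolled runs from two initial conditions (II
#' doubles the sheep and halves the wolves of I); datasets III, IV and V
#' start from the initial condition of I and exert control on grass, sheep
#' and wolves respectively (grass blight 2%, sheep removal 2%, wolf removal
#' 1.5% per tick -- removal levels set above the expected optimum). Each
#' dataset is the pointwise average of `n_real` realizations.
#'
#' @param params [swg_params()].
#' @param n_steps ticks per realization.
#' @param n_real realizations averaged per dataset.
#' @param seed global seed; dataset d realization r runs under seed
#'   `seed + 1000 * d + r`.
#' @param thin keep every `thin`-th timepoint of the averaged series.
#' @param controls optional named list overriding the control settings of
#'   datasets III-V.
#' @return Named list of five averaged `abm_trajectory` objects
#'   (`I` ... `V`).
#' @export
swg_datasets <- function(params, n_steps = 500, n_real = 20, seed = 1,
                         thin = 5, controls = NULL) {
  ctl <- list(I = removal_control(),
              II = removal_control(),
              III = removal_control(kappa_grass = 0.02),
              IV = removal_control(kappa_sheep = 0.02),
              V = removal_control(kappa_wolves = 0.015))
  if (!is.null(controls)) ctl[names(controls)] <- controls
  counts <- list(I = NULL,
                 II = c(sheep = 2 * params$init_sheep,
                        wolves = max(1, params$init_wolves %/% 2)),
                 III = NULL, IV = NULL, V = NULL)
  out <- list()
  for (d in seq_along(ctl)) {
    nm <- names(ctl)[d]
    runs <- lapply(seq_len(n_real), function(r) {
      simulate_swg(params, ctl[[d]], n_steps = n_steps,
                   seed = seed + 1000 * d + r, counts = counts[[nm]])
    })
    out[[nm]] <- thin_trajectory(average_realizations(runs), thin)
  }
  out
}

#' Build the five metabolic-pathway training datasets
#'
#' Datasets I and II are single simulations: I in batch mode (substrate
#' depleted, products accumulate) and II in continuous mode with substrate
#' supplied at 1 molecule per tick. Datasets III and IV average `n_real`
#' realizations of the same two settings; dataset V averages `n_real`
#' continuous-mode realizations with inflow 0.2. All continuous runs remove
#' free metabolites at `outflow_rate` per tick.
#'
#' @param batch_params,cont_params batch- and continuous-mode
#'   [metabolic_params()].
#' @param n_steps ticks per realization.
#' @param n_real realizations averaged in datasets III-V.
#' @param seed global seed (same child-stream scheme as [swg_datasets()]).
#' @param thin keep every `thin`-th timepoint.
#' @return Named list of five `abm_trajectory` objects.
#' @export
metabolic_datasets <- function(batch_params = metabolic_params(),
                               cont_params = metabolic_params(mode = "continuous"),
                               n_steps = 5000, n_real = 10, seed = 1,
                               thin = 25) {
  q_low <- 0.2
  cont_low <- cont_params
  cont_low$q_in <- q_low
  cfg <- list(I = list(p = batch_params, n = 1),
              II = list(p = cont_params, n = 1),
              III = list(p = batch_params, n = n_real),
              IV = list(p = cont_params, n = n_real),
              V = list(p = cont_low, n = n_real))
  out <- list()
  for (d in seq_along(cfg)) {
    runs <- lapply(seq_len(cfg[[d]]$n), function(r) {
      simulate_metabolic(cfg[[d]]$p, n_steps = n_steps,
                         seed = seed + 1000 * d + r)
    })
    avg <- if (length(runs) > 1) average_realizations(runs) else runs[[1]]
    out[[names(cfg)[d]]] <- thin_trajectory(avg, thin)
  }
  out
}

#' Materialize configured datasets as CSV files with manifests
#'
#' Runs the dataset preset named in the configuration and writes one CSV
#' (plus JSON sidecar) per dataset into `out_dir`, together with a
#' `manifest.json` recording the configuration and seeds. Partial outputs
#' are removed if any stage fails. Re-running with the same configuration
#' reproduces the files byte for byte.
#'
#' @param config an experiment configuration, see [read_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
make_datasets <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop("dataset generation failed (partial outputs removed): ",
         conditionMessage(e))
  }
  manifest <- tryCatch({
    ds <- build_datasets_from_config(config)
    for (nm in names(ds)) {
      path <- file.path(out_dir, paste0("dataset_", nm, ".csv"))
      write_trajectory(ds[[nm]], path)
      written <- c(written, path, sidecar_path(path))
    }
    man <- list(abm = config$abm, seed = config$seed,
                datasets = names(ds), files = basename(written),
                config = config)
    jsonlite::write_json(serialize_meta(man),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    man
  }, error = on_fail)
  invisible(manifest)
}

build_datasets_from_config <- function(config) {
  seed <- config$seed %||% 1
  dcfg <- config$datasets %||% list()
  if (identical(config$abm, "swg")) {
    params <- do.call(swg_params, config$params %||% list())
    do.call(swg_datasets,
            c(list(params = params, seed = seed),
              dcfg[intersect(names(dcfg),
                             c("n_steps", "n_real", "thin"))]))
  } else if (identical(config$abm, "metabolic")) {
    bp <- do.call(metabolic_params, config$params %||% list())
    cp <- do.call(metabolic_params,
                  c(list(mode = "continuous"),
                    config$params_continuous %||% list()))
    do.call(metabolic_datasets,
            c(list(batch_params = bp, cont_params = cp, seed = seed),
              dcfg[intersect(names(dcfg),
                             c("n_steps", "n_real", "thin"))]))
  } else {
    stop("config$abm must be 'swg' or 'metabolic'")
  }
}
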