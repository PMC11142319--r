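# Integer species codes shared with the compiled stepper.
MET_SPECIES <- c("S", "A", "B", "R", "T")
ENZ_TYPES <- c("E1", "E2", "E3", "E4")
# per enzyme-entity state: 5*type + {0 free, 1 substrate complex, 2 product
# complex, 3 regulator-bound enzyme, 4 substrate + regulator}
ENZ_STATE_NAMES <- c("E1", "E1S", "E1A", "E1.R", "E1S.R",
                     "E2", "E2A", "E2B", "E2.T", "E2A.T",
                     "E3", "E3B", "E3R", "E3.x", "E3Bx",
                     "E4", "E4B", "E4T", "E4.x", "E4Bx")

#' Topology of the branched metabolic pathway
#'
#' A linear chain with a terminal branch point -- E1: S -> A, E2: A -> B,
#' E3: B -> R, E4: B -> T -- plus two feedback inhibitions, R on E1 and T on
#' E2, realized as regulator binding that sequesters the enzyme in a
#' catalytically inactive complex. All reactions are irreversible. Enzymes
#' also form (dead-end) complexes with their products. The admissible
#' complex species are the four substrate complexes, four product complexes,
#' and the four regulator-bound species E1.R, E1S.R, E2.T, E2A.T: 12 in all.
#'
#' @return List with `metabolites`, `enzymes`, `reactions` (data frame
#'   enzyme/substrate/product), `regulation` (data frame regulator/target)
#'   and `complexes` (the 12 complex species names).
#' @export
metabolic_topology <- function() {
  list(metabolites = MET_SPECIES,
       enzymes = ENZ_TYPES,
       reactions = data.frame(enzyme = ENZ_TYPES,
                              substrate = c("S", "A", "B", "B"),
                              product = c("A", "B", "R", "T")),
       regulation = data.frame(regulator = c("R", "T"),
                               target = c("E1", "E2")),
       complexes = c("E1S", "E1A", "E1.R", "E1S.R",
                     "E2A", "E2B", "E2.T", "E2A.T",
                     "E3B", "E3R", "E4B", "E4T"))
}

#' Parameters of the metabolic pathway lattice model
#'
#' Defaults describe a 100 x 100 torus loaded with 50 copies of each enzyme
#' and 1,000 substrate molecules (both modes share this initial condition).
#' Batch mode is a closed vessel; in continuous mode substrate additionally
#' arrives as a Poisson stream with mean `q_in` molecules per tick and every
#' free metabolite leaves with probability `outflow_rate` per tick (0.05%
#' by default), while enzymes and complexes stay in the vessel. Metabolites
#' take 10 lattice steps per tick against 1 for enzymes and complexes.
#'
#' @param width,height lattice dimensions.
#' @param init_counts named integer vector of initial copy numbers; any of
#'   S, A, B, R, T, E1..E4 may be given, the rest default per mode.
#' @param metabolite_speed,enzyme_speed lattice steps per tick.
#' @param p_bind probability that a metabolite adjacent (3 x 3 Moore
#'   neighbourhood) to a compatible partner binds it.
#' @param p_diss per-tick release probability of each bound molecule.
#' @param p_cat per-tick catalysis probability of an unregulated
#'   enzyme-substrate complex.
#' @param mode `"batch"` or `"continuous"`.
#' @param q_in mean substrate inflow (molecules/tick, continuous mode).
#' @param outflow_rate per-tick removal probability of each free metabolite
#'   (continuous mode).
#' @return An object of class `metabolic_params`.
#' @export
metabolic_params <- function(width = 100L, height = 100L, init_counts = NULL,
                             metabolite_speed = 10L, enzyme_speed = 1L,
                             p_bind = 0.5, p_diss = 0.02, p_cat = 0.1,
                             mode = c("batch", "continuous"), q_in = NULL,
                             outflow_rate = NULL) {
  mode <- match.arg(mode)
  if (is.null(q_in)) q_in <- if (mode == "continuous") 1 else 0
  if (is.null(outflow_rate))
    outflow_rate <- if (mode == "continuous") 5e-4 else 0
  base <- c(S = 1000L, A = 0L, B = 0L, R = 0L, T = 0L,
            E1 = 50L, E2 = 50L, E3 = 50L, E4 = 50L)
  if (!is.null(init_counts)) {
    stopifnot(all(names(init_counts) %in% names(base)))
    base[names(init_counts)] <- as.integer(init_counts)
  }
  p <- list(width = as.integer(width), height = as.integer(height),
            init_counts = base,
            metabolite_speed = as.integer(metabolite_speed),
            enzyme_speed = as.integer(enzyme_speed),
            p_bind = p_bind, p_diss = p_diss, p_cat = p_cat,
            mode = mode, q_in = q_in, outflow_rate = outflow_rate)
  validate_metabolic_params(p)
  structure(p, class = "metabolic_params")
}

validate_metabolic_params <- function(p) {
  stopifnot(p$width >= 3, p$height >= 3,
            all(p$init_counts >= 0),
            p$metabolite_speed >= 1, p$enzyme_speed >= 0,
            p$p_bind >= 0, p$p_bind <= 1, p$p_diss >= 0, p$p_diss <= 1,
            p$p_cat >= 0, p$p_cat <= 1, p$q_in >= 0,
            p$outflow_rate >= 0, p$outflow_rate <= 1)
  if (p$mode == "batch" && (p$q_in > 0 || p$outflow_rate > 0))
    stop("batch mode has no inflow or outflow")
  invisible(p)
}

#' Initialize a metabolic pathway microstate
#'
#' All molecules are placed uniformly at random; enzymes start free.
#'
#' @param params a [metabolic_params()] object.
#' @param seed integer seed.
#' @return An object of class `metabolic_state` with `met` (free metabolites:
#'   integer species code 0..4 for S, A, B, R, T and zero-based position),
#'   `enz` (enzyme entities: type 0..3, bound_met / bound_reg species codes
#'   or -1, position) and `step`.
#' @export
init_metabolic <- function(params, seed) {
  validate_metabolic_params(params)
  set.seed(as.integer(seed))
  W <- params$width; H <- params$height
  cnt <- params$init_counts
  n_met <- sum(cnt[MET_SPECIES])
  met <- data.frame(
    species = rep(0:4, times = cnt[MET_SPECIES]),
    x = sample.int(W, n_met, replace = TRUE) - 1L,
    y = sample.int(H, n_met, replace = TRUE) - 1L)
  n_enz <- sum(cnt[ENZ_TYPES])
  enz <- data.frame(
    type = rep(0:3, times = cnt[ENZ_TYPES]),
    bound_met = rep(-1L, n_enz), bound_reg = rep(-1L, n_enz),
    x = sample.int(W, n_enz, replace = TRUE) - 1L,
    y = sample.int(H, n_enz, replace = TRUE) - 1L)
  structure(list(met = met, enz = enz, step = 0L), class = "metabolic_state")
}

#' Advance the metabolic pathway model
#'
#' Each tick applies, in order: (1) movement (metabolites take
#' `metabolite_speed` uniform Moore steps, enzymes/complexes
#' `enzyme_speed`); (2) binding -- each free metabolite, in shuffled order,
#' scans its 3 x 3 neighbourhood and binds a uniformly chosen compatible
#' partner with probability `p_bind`; (3) dissociation -- every bound
#' molecule is released with probability `p_diss`; (4) catalysis -- every
#' unregulated enzyme-substrate complex becomes the enzyme-product complex
#' with probability `p_cat`; (5) in continuous mode, Poisson substrate
#' inflow and Bernoulli outflow of free metabolites. Uses R's RNG (seed via
#' `set.seed()` or [simulate_metabolic()]).
#'
#' @param state a `metabolic_state`.
#' @param params matching [metabolic_params()].
#' @param n_steps ticks to apply.
#' @param record_complexes also record the 20 enzyme-entity state counts.
#' @return New `metabolic_state` with attribute `macro`: per-tick counts of
#'   free S, A, B, R, T (plus complex counts if requested).
#' @export
step_metabolic <- function(state, params, n_steps = 1L,
                           record_complexes = FALSE) {
  stopifnot(inherits(state, "metabolic_state"), n_steps >= 1)
  res <- metabolic_run_cpp(state, params, as.integer(n_steps),
                           record_complexes)
  out <- res$state
  cols <- c("step", MET_SPECIES)
  if (record_complexes) cols <- c(cols, ENZ_STATE_NAMES)
  colnames(res$macro) <- cols
  attr(out, "macro") <- res$macro
  out
}

#' Simulate the metabolic pathway model and record free-metabolite counts
#'
#' @inheritParams step_metabolic
#' @param seed integer seed; identical seeds give identical trajectories.
#' @return An `abm_trajectory` data frame with columns
#'   `step, S, A, B, R, T` (plus complex-state columns when
#'   `record_complexes = TRUE`) and metadata in `attr(, "meta")`.
#' @export
simulate_metabolic <- function(params, n_steps = 1000L, seed = 1L,
                               record_complexes = FALSE) {
  stopifnot(n_steps >= 1)
  st <- init_metabolic(params, seed)
  st <- step_metabolic(st, params, n_steps, record_complexes)
  df <- as.data.frame(attr(st, "macro"))
  traj <- as_trajectory(df, vars = MET_SPECIES,
                        meta = list(source = "metabolic", params = params,
                                    control = list(q_in = params$q_in,
                                                   outflow_rate = params$outflow_rate,
                                                   mode = params$mode),
                                    seed = seed,
                                    n_steps = as.integer(n_steps)))
  attr(traj, "final_state") <- st
  traj
}

#' Metabolite totals including molecules sequestered in complexes
#'
#' Counts each metabolite species as free + bound (substrate/product slot or
#' regulator slot of an enzyme entity). In batch mode the grand total is
#' conserved; enzyme totals per type are conserved in both modes.
#'
#' @param state a `metabolic_state`.
#' @return Named vector over S, A, B, R, T.
#' @export
metabolite_totals <- function(state) {
  cnt <- setNames(numeric(5), MET_SPECIES)
  free <- table(factor(state$met$species, levels = 0:4))
  cnt <- cnt + as.numeric(free)
  for (slot in c("bound_met", "bound_reg")) {
    b <- state$enz[[slot]]
    b <- b[b >= 0]
    if (length(b)) cnt <- cnt + as.numeric(table(factor(b, levels = 0:4)))
  }
  cnt
}

#' Enzyme copy numbers per type (free + complexed)
#'
#' @param state a `metabolic_state`.
#' @return Named vector over E1..E4.
#' @export
enzyme_totals <- function(state) {
  setNames(as.numeric(table(factor(state$enz$type, levels = 0:3))), ENZ_TYPES)
}

#' @export
print.metabolic_state <- function(x, ...) {
  tot <- metabolite_totals(x)
  cat("<metabolic_state> step", x$step, "|", nrow(x$met), "free metabolites,",
      nrow(x$enz), "enzyme entities | totals:",
      paste(names(tot), tot, sep = "=", collapse = " "), "\n")
  invisible(x)
}
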