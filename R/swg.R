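#' Parameters of the sheep-wolves-grass lattice model
#'
#' The default configuration is a 255 x 255 torus initialized with 2,500
#' sheep, 1,250 wolves and 50% grass cover; the rule parameters are the
#' published wolf-sheep-predation (with grass) defaults: sheep gain 4 and
#' wolf gain 20 energy units per meal, reproduction probabilities 4% and 5%
#' per tick, grass regrowth time 30 ticks, and 1 energy unit lost per move.
#'
#' @param world_width,world_height lattice dimensions (patches).
#' @param init_sheep,init_wolves initial animal counts.
#' @param init_grass_fraction initial fraction of grown patches, between 0 and 1.
#' @param sheep_gain_from_food,wolf_gain_from_food energy gained per meal.
#' @param sheep_reproduce_prob,wolf_reproduce_prob per-tick reproduction
#'   probabilities.
#' @param grass_regrowth_time ticks for an eaten patch to regrow.
#' @param energy_loss_per_step energy lost per move.
#' @return An object of class `swg_params`.
#' @seealso [swg_reference_params()] for the 51 x 51 reference preset.
#' @export
swg_params <- function(world_width = 255L, world_height = 255L,
                       init_sheep = 2500L, init_wolves = 1250L,
                       init_grass_fraction = 0.5,
                       sheep_gain_from_food = 4, wolf_gain_from_food = 20,
                       sheep_reproduce_prob = 0.04, wolf_reproduce_prob = 0.05,
                       grass_regrowth_time = 30L, energy_loss_per_step = 1) {
  p <- list(world_width = as.integer(world_width),
            world_height = as.integer(world_height),
            init_sheep = as.integer(init_sheep),
            init_wolves = as.integer(init_wolves),
            init_grass_fraction = init_grass_fraction,
            sheep_gain_from_food = sheep_gain_from_food,
            wolf_gain_from_food = wolf_gain_from_food,
            sheep_reproduce_prob = sheep_reproduce_prob,
            wolf_reproduce_prob = wolf_reproduce_prob,
            grass_regrowth_time = as.integer(grass_regrowth_time),
            energy_loss_per_step = energy_loss_per_step)
  validate_swg_params(p)
  structure(p, class = "swg_params")
}

validate_swg_params <- function(p) {
  stopifnot(p$world_width >= 1, p$world_height >= 1,
            p$init_sheep >= 0, p$init_wolves >= 0,
            p$init_grass_fraction >= 0, p$init_grass_fraction <= 1,
            p$sheep_reproduce_prob >= 0, p$sheep_reproduce_prob <= 1,
            p$wolf_reproduce_prob >= 0, p$wolf_reproduce_prob <= 1,
            p$grass_regrowth_time >= 1, p$energy_loss_per_step >= 0)
  invisible(p)
}

#' Reference (small-world) preset of the sheep-wolves-grass model
#'
#' A 51 x 51 world with 100 sheep and 50 wolves: the same stocking densities
#' as the default 255 x 255 setup at 1/25 of the area.
#'
#' @param ... overrides passed on to [swg_params()].
#' @return An object of class `swg_params`.
#' @export
swg_reference_params <- function(...) {
  defaults <- list(world_width = 51L, world_height = 51L,
                   init_sheep = 100L, init_wolves = 50L)
  do.call(swg_params, modifyList(defaults, list(...)))
}

#' Per-tick fractional-removal control for the sheep-wolves-grass model
#'
#' Each animal is removed independently with the per-tick probability of its
#' species (binomial removal in aggregate, matching a constant per-capita
#' removal rate in the ODE lift); each grown patch is blighted back to a full
#' regrowth countdown with probability `kappa_grass`. All zero means
#' uncontrolled.
#'
#' @param kappa_sheep,kappa_wolves,kappa_grass per-tick removal
#'   probabilities between 0 and 1.
#' @return An object of class `removal_control`.
#' @export
removal_control <- function(kappa_sheep = 0, kappa_wolves = 0,
                            kappa_grass = 0) {
  stopifnot(kappa_sheep >= 0, kappa_sheep <= 1,
            kappa_wolves >= 0, kappa_wolves <= 1,
            kappa_grass >= 0, kappa_grass <= 1)
  structure(list(kappa_sheep = kappa_sheep, kappa_wolves = kappa_wolves,
                 kappa_grass = kappa_grass),
            class = "removal_control")
}

#' Initialize a sheep-wolves-grass microstate
#'
#' Animals are placed uniformly at random (continuous torus coordinates)
#' with uniform random headings and energies drawn uniformly on
#' [1, 2 * gain_from_food); exactly `floor(init_grass_fraction * patches)`
#' patches start grown, the rest with a uniform regrowth countdown in
#' 1..grass_regrowth_time. Identical seeds give identical states.
#'
#' @param params an [swg_params()] object.
#' @param seed integer seed.
#' @param counts optional named vector `c(grass=, sheep=, wolves=)`
#'   overriding the initial macrostate (used, e.g., to start a run at an
#'   estimated steady state); `grass` is a patch count.
#' @return An object of class `swg_state` with components `grass` (matrix of
#'   regrowth countdowns, 0 = grown), `sheep`, `wolves` (data frames with
#'   continuous x, y in `[0, W) x [0, H)`, heading in degrees, energy) and
#'   `step`; an animal occupies the patch `(floor(x), floor(y))`.
#' @export
init_swg <- function(params, seed, counts = NULL) {
  validate_swg_params(params)
  set.seed(as.integer(seed))
  W <- params$world_width; H <- params$world_height; P <- W * H
  n_sheep <- params$init_sheep
  n_wolves <- params$init_wolves
  n_grown <- floor(params$init_grass_fraction * P)
  if (!is.null(counts)) {
    if (!is.na(counts["sheep"])) n_sheep <- as.integer(counts["sheep"])
    if (!is.na(counts["wolves"])) n_wolves <- as.integer(counts["wolves"])
    if (!is.na(counts["grass"])) n_grown <- min(P, as.integer(counts["grass"]))
  }
  grass <- integer(P)
  if (n_grown < P) {
    bare <- sample.int(P, P - n_grown)
    grass[bare] <- sample.int(params$grass_regrowth_time, P - n_grown,
                              replace = TRUE)
  }
  place <- function(n, gain) {
    data.frame(x = runif(n, 0, W), y = runif(n, 0, H),
               heading = runif(n, 0, 360),
               energy = runif(n, 1, 2 * gain))
  }
  structure(list(grass = matrix(grass, W, H),
                 sheep = place(n_sheep, params$sheep_gain_from_food),
                 wolves = place(n_wolves, params$wolf_gain_from_food),
                 step = 0L),
            class = "swg_state")
}

#' Macrostate of a sheep-wolves-grass microstate
#'
#' @param state an `swg_state`.
#' @return Named vector `c(grass=, sheep=, wolves=)`: grown-patch count and
#'   animal counts. A pure function of the state.
#' @export
swg_macrostate <- function(state) {
  c(grass = sum(state$grass == 0L),
    sheep = nrow(state$sheep),
    wolves = nrow(state$wolves))
}

#' Advance the sheep-wolves-grass model
#'
#' Applies `n_steps` ticks, each in fixed sub-phase order: (1) every animal
#' wiggles its heading by up to +/-50 degrees, takes a unit step forward
#' (correlated random walk on the torus) and loses energy; (2) sheep on
#' grown patches graze (shuffled order, one meal per patch); (3) each wolf
#' sharing a patch with sheep eats one uniformly chosen sheep; (4) animals
#' with negative energy starve; (5) survivors reproduce with their species
#' probability, halving their energy and passing the other half to the
#' offspring; (6) regrowth countdowns decrement, patches regrowing at zero;
#' (7) removal control. Draws from R's RNG: call `set.seed()` beforehand for
#' reproducibility (or use [simulate_swg()], which seeds for you).
#'
#' @param state an `swg_state`.
#' @param params matching [swg_params()].
#' @param control a [removal_control()]; defaults to uncontrolled.
#' @param n_steps number of ticks.
#' @param bookkeeping if `TRUE` the per-tick event counts (births, predation,
#'   starvation, removals, grazed patches) are attached.
#' @return The new `swg_state`, with attributes `macro` (matrix of
#'   step/grass/sheep/wolves including the entry row) and, if requested,
#'   `book`.
#' @export
step_swg <- function(state, params, control = removal_control(),
                     n_steps = 1L, bookkeeping = FALSE) {
  stopifnot(inherits(state, "swg_state"), n_steps >= 1)
  res <- swg_run_cpp(state, params, control, as.integer(n_steps), bookkeeping)
  out <- res$state
  colnames(res$macro) <- c("step", "grass", "sheep", "wolves")
  attr(out, "macro") <- res$macro
  if (bookkeeping) {
    colnames(res$book) <- c("sheep_births", "sheep_eaten", "sheep_starved",
                            "sheep_removed", "wolf_births", "wolf_starved",
                            "wolf_removed", "grass_eaten")
    attr(out, "book") <- res$book
  }
  out
}

#' Simulate the sheep-wolves-grass model and record its macrostate
#'
#' @inheritParams step_swg
#' @param seed integer seed; identical seeds give identical trajectories.
#' @param n_steps number of ticks (>= 0); the returned series has
#'   `n_steps + 1` rows including the initial state.
#' @param init_state optional pre-built `swg_state` (e.g. the endpoint of a
#'   warm-up run); when supplied the seed still governs the run itself.
#' @param counts optional initial macrostate override, see [init_swg()].
#' @return An `abm_trajectory` data frame with columns
#'   `step, grass, sheep, wolves` and metadata (params, control, seed) in
#'   `attr(, "meta")`. Extinctions are not errors; the series continues with
#'   zeros.
#' @export
simulate_swg <- function(params, control = removal_control(), n_steps = 1000L,
                         seed = 1L, init_state = NULL, counts = NULL,
                         bookkeeping = FALSE) {
  stopifnot(n_steps >= 0)
  if (is.null(init_state)) {
    init_state <- init_swg(params, seed, counts = counts)
  } else {
    set.seed(as.integer(seed))
  }
  if (n_steps == 0) {
    m <- swg_macrostate(init_state)
    df <- data.frame(step = init_state$step, grass = m[["grass"]],
                     sheep = m[["sheep"]], wolves = m[["wolves"]])
    return(as_trajectory(df, meta = list(source = "swg", params = params,
                                         control = control, seed = seed,
                                         n_steps = 0L)))
  }
  st <- step_swg(init_state, params, control, n_steps,
                 bookkeeping = bookkeeping)
  df <- as.data.frame(attr(st, "macro"))
  traj <- as_trajectory(df, meta = list(source = "swg", params = params,
                                        control = control, seed = seed,
                                        n_steps = as.integer(n_steps)))
  if (bookkeeping) attr(traj, "book") <- attr(st, "book")
  attr(traj, "final_state") <- st
  traj
}

#' Simulate a controlled run started from (near) the uncontrolled steady state
#'
#' Runs an uncontrolled warm-up from an initial state at the supplied
#' steady-state counts, then switches the removal control on for `horizon`
#' ticks. This mirrors the control problem of shifting an established
#' steady state rather than controlling a transient.
#'
#' @inheritParams simulate_swg
#' @param x0 named steady-state counts `c(grass=, sheep=, wolves=)`.
#' @param warmup uncontrolled ticks before control switches on.
#' @param horizon controlled ticks.
#' @param tail_frac fraction of the controlled window used for the long-run
#'   mean (default last 50%).
#' @return List with `traj` (controlled window trajectory), `tail_mean`
#'   (named mean macrostate over the tail window), `removed`
#'   (total sheep/wolves removed over the horizon) and `exposure`
#'   (summed sheep/wolf census over the horizon, for realized-rate checks).
#' @export
swg_controlled_run <- function(params, control, x0, warmup = 200L,
                               horizon = 800L, tail_frac = 0.5, seed = 1L) {
  init <- init_swg(params, seed, counts = x0)
  warm <- step_swg(init, params, removal_control(), n_steps = warmup)
  ctrl <- step_swg(warm, params, control, n_steps = horizon,
                   bookkeeping = TRUE)
  macro <- attr(ctrl, "macro")
  book <- attr(ctrl, "book")
  n <- nrow(macro)
  tail_rows <- seq.int(ceiling(n * (1 - tail_frac)) + 1L, n)
  tail_mean <- colMeans(macro[tail_rows, c("grass", "sheep", "wolves"),
                              drop = FALSE])
  list(traj = as_trajectory(as.data.frame(macro),
                            meta = list(source = "swg", params = params,
                                        control = control, seed = seed)),
       tail_mean = tail_mean,
       removed = c(sheep = sum(book[, "sheep_removed"]),
                   wolves = sum(book[, "wolf_removed"])),
       exposure = c(sheep = sum(macro[-n, "sheep"]),
                    wolves = sum(macro[-n, "wolves"])))
}

#' @export
print.swg_state <- function(x, ...) {
  m <- swg_macrostate(x)
  cat("<swg_state> step", x$step, "|", m[["grass"]], "grass,",
      m[["sheep"]], "sheep,", m[["wolves"]], "wolves\n")
  invisible(x)
}
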