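---
title: "Surrogate ODE models for controlling agent-based simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate ODE models for controlling agent-based simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abmode)
```

## The problem

Agent-based models (ABMs) are rule-based stochastic simulations of discrete
agents on a spatial substrate. They are the natural language for many
biomedical and ecological systems, but they are not equation-based, so the
well-developed machinery of optimal control for ordinary differential
equations (ODEs) does not apply to them directly. `abmode` implements a
surrogate-modeling loop around this gap:

1. simulate the ABM and record its population-level macrostates;
2. fit a low-dimensional ODE system (the *surrogate*) to those
   trajectories, including trajectories recorded *under control*, so that
   solving the control problem on the surrogate is an interpolation rather
   than an extrapolation task;
3. solve the control problem on the surrogate with standard numerical
   tools;
4. lift the continuous solution back to the ABM's per-tick semantics and
   validate it with a grid search directly on the ABM.

Two reference ABMs ship with the package. Both are deliberately simple
enough to be simulated exhaustively, which is what makes honest validation
of the control solutions possible.

## The sheep-wolves-grass model

A predator-prey-resource lattice model in the tradition of the classic
NetLogo wolf-sheep-predation model (with grass). Sheep and wolves live in
continuous coordinates on a torus of square patches; each tick they turn by
a uniform angle up to ±50 degrees, step one unit forward, and lose one unit
of energy. Sheep eat a grown grass patch where they stand (gaining 4 energy
units; the patch regrows after 30 ticks), wolves eat one sheep sharing
their patch (gaining 20), animals with negative energy die, and survivors
reproduce with probability 4% (sheep) or 5% (wolves), halving their energy
with the offspring. The default world is 255 × 255 with 2,500 sheep, 1,250
wolves and 50% grass; `swg_reference_params()` is the same system at 1/25
of the area (51 × 51, 100 sheep, 50 wolves), which is the scale used
throughout the package's validation runs.

Movement uses persistent headings (a correlated random walk) rather than
uncorrelated jumps between lattice neighbours. This matters: with an
uncorrelated walk the predator-prey encounter rate falls well below the
well-mixed expectation (sheep cluster on grass-rich regions that wolves
re-sample slowly), wolf energy intake drops below maintenance, and wolves
go extinct for every seed. With the correlated walk the three populations
coexist in noisy oscillation around a well-defined mean state, which is the
regime the control problem assumes.

The control problem: remove a constant fraction of sheep (κ₂) and wolves
(κ₃) per tick — independent Bernoulli removal per animal, the discrete
counterpart of a constant per-capita removal rate — so that the system
settles at a new steady state with 10% more sheep and 50% fewer wolves,
removing as few animals as possible.

```{r swg, eval = FALSE}
p <- swg_reference_params()
traj <- simulate_swg(p, n_steps = 1000, seed = 1)
steady_state_tail(traj) # tail-window mean: about 940 grass, 170 sheep, 70 wolves
```

## The metabolic pathway model

A branched enzymatic pathway simulated at the level of elementary events:
five metabolites (S, A, B, R, T), four enzymes with irreversible reactions
E1: S→A, E2: A→B, E3: B→R, E4: B→T, and two feedback inhibitions (R on E1,
T on E2) realized as regulator binding that sequesters the enzyme in a
catalytically inactive complex. Enzymes also form dead-end complexes with
their products, giving 12 admissible complex species. Metabolites take 10
lattice steps per tick against 1 for enzymes and complexes; a metabolite
adjacent to a compatible partner binds with probability 0.5 per tick, any
bound molecule is released with probability 0.02, and an unregulated
enzyme-substrate complex converts with probability 0.1.

The pathway runs in *batch* mode (closed vessel: 1,000 substrate molecules
are gradually converted into the end products R and T, with both enzyme
copy numbers and total metabolite counts conserved exactly) or in
*continuous* mode (stirred-tank analogy: Poisson substrate inflow with mean
Q_in molecules per tick, and every free metabolite leaves the vessel with
probability 0.05% per tick while enzymes and complexes stay). Both modes
start from the same loaded initial condition; an empty-vessel start would
make the inflow control problem below degenerate, since never feeding the
reactor would trivially minimize the loss.

The control problem: choose the constant inflow Q_in that minimizes the
substrate-waste loss
\[
\mathrm{Loss}(Q) = \sum_{k=1}^{N_t} \frac{S_k}{\max(R_k + T_k,\,1)},
\]
i.e. minimize unconverted substrate relative to accumulated end products.
The denominator grouping of this objective is typeset ambiguously in some
statements of the problem; `abmode` reads it as S over the product sum
(matching the stated intent — minimize S, maximize R + T) and floors the
denominator at one molecule, the smallest nonzero census, to handle early
ticks before any product exists. Skipping zero-denominator ticks instead is
available through the `floor` argument of `yield_loss()`.

## The four surrogate families

All surrogates act on the macrostate vector only (grass/sheep/wolves counts
or the five free-metabolite counts; complexes are aggregated away, since
only control-relevant states need representation).

* **Mechanistic** — the stoichiometric form dX/dt = M·F with process fluxes
  in their standard functional forms. For the predator-prey system this is
  a Lotka–Volterra model with seven processes (logistic grass growth
  carrying two rate constants, grazing, sheep birth, sheep death,
  predation, wolf birth, wolf death — eight constants in all); for the
  pathway it is irreversible Michaelis–Menten fluxes
  v = Vmax·X/(Km + X) with the two inhibitions as 1/(1 + I/Ki) factors.
* **Generalized mass action (GMA)** — every process is a power law
  α·∏Xᵏ with real kinetic orders, combined through the same stoichiometric
  matrix; mass action is the integer-order special case. With all orders
  free this is m(1 + n) parameters.
* **Taylor expansions at the steady state** — linear dX/dt = J(X − X₀)
  (n² parameters) or quadratic with per-equation symmetric Hessians
  ((3n² + n³)/2 parameters). X₀ is estimated from data as the tail-window
  mean of averaged trajectories and held fixed during fitting.
* **S-system** — per variable one aggregate inflow and one aggregate
  outflow power law, 2n + n² parameters.

Power-law bases are floored at 10⁻¹² so that derivatives stay finite at
extinction states; this is a documented deviation from the pure formulas
that only matters on the boundary of the state space.

## Fitting

Training data are averaged ABM realizations under several conditions:
uncontrolled baselines from two initial conditions plus runs with control
exerted on each controllable variable at levels above the expected optimum
(for the sheep-wolves-grass case: 2% grass blight, 2% sheep removal, 1.5%
wolf removal per tick). Parameters are estimated by bounded nonlinear least
squares: every trajectory is re-simulated from its own initial row with its
own control constants, and pointwise residuals are scaled per variable by
the dataset-wide mean magnitude so that grass (~10³–10⁴) and wolves
(~10¹–10³) contribute comparably — one scale per variable across all
conditions, so that a series driven near extinction in one controlled
condition does not dominate the objective through a tiny local scale. Per-tick removal probabilities p enter
the ODE as rates −log(1 − p), the exact continuous-time equivalent.

Numerical choices that matter:

* rate constants are optimized on the log scale (positivity by
  construction); kinetic orders are box-bounded to [−5, 5], and
  slope-method starting values are clamped to [−2.5, 2.5] because extreme
  starting orders make the very first integrations blow up;
* starting values come from the time-course slope method: finite-difference
  slopes (with the known control contribution subtracted) regressed on the
  family's process terms — ordinary least squares for the mechanistic and
  Taylor families (exact on noiseless linear data), log-linear regression
  of pseudo-inverse process fluxes for the power-law families;
* optimization is multi-start (default 10: the slope start plus seeded
  perturbations) Levenberg–Marquardt; after the best start finishes, the
  optimizer is restarted from the incumbent up to twice, which resets the
  trust region and reliably improves sloppy fits;
* integrations use lsoda (stiffness-capable) with rtol 10⁻⁶; a failed or
  truncated integration contributes a large finite residual (10³ per
  missing point) rather than an error, so the optimizer is pushed away
  from non-integrable regions instead of crashing — the same mechanism
  reports, rather than hides, surrogates that can only be integrated on
  part of the control domain;
* quadratic Taylor fits can add a no-extra-roots penalty: root searches
  from Halton-sequence starts inside the domain box of the control
  problem, each distinct extra steady state adding a large penalty. This
  counters the tendency of second-order expansions to acquire spurious
  equilibria that derail control optimization.

## Solving and lifting the control problems

For the steady-state-shift problem the solver looks for removal rates at
which the *controlled surrogate's* steady state (root of the controlled
RHS, with a finite-horizon endpoint as fallback) matches the target. A
coarse grid scan provides the starting point, damped Newton iteration on
the two-dimensional mismatch refines it; when an exact interior root
exists it is the unique feasible minimizer of total removals, otherwise
feasibility within a 2% band is traded against the number of animals
removed. For the inflow problem the loss of the controlled surrogate
trajectory is scanned over the inflow range; sub-domains where the
surrogate cannot be integrated are reported as such, mirroring how
power-law surrogates of saturating systems often blow up at one end of the
control range.

Lifting is exact rather than approximate: a continuous removal rate κ per
unit time becomes the per-tick removal probability 1 − e^(−κ), and a
continuous inflow becomes the mean of the per-tick Poisson arrival count —
memoryless arrivals with the correct mean for any real rate.

Validation uses seeded grid searches on the ABMs themselves. Each
sheep-wolves-grass grid point runs the ABM from the estimated uncontrolled
steady state (a 200-tick uncontrolled warm-up, then 1,400 controlled
ticks), and is scored by the distance of the *mean* long-run state — tail
means averaged across realizations before the distance is taken, which
removes the per-realization noise floor that would otherwise flatten the
optimum — plus the number of animals removed. The reported optimum
minimizes the distance; a secondary selection minimizes removals among
points statistically indistinguishable from it (within one standard
error). The search is two-stage: a coarse scan at 0.25 percentage points
over sheep removal in [0, 2%] and wolf removal in [0, 1.5%], then a 0.1
percentage-point grid around the coarse optimum, with 32 seeded
realizations per point by default.

## Problem sizes used in the shipped checks

The package's test suite and the acceptance script run everything at desk
scale, chosen to keep full reproduction on a single CPU comfortable: the
51 × 51 reference world (the pre-scaling size of the published model) with
24–40 realizations per grid point; metabolic grid searches with 10
realizations of 5,000 ticks per inflow value; and training datasets of
10–20 averaged realizations over 500 ticks. The fitted families and all
exact identities (conservation laws, mass-action equivalence, parameter
counts, closed-form control solutions) are scale-independent.

## What the generators do and do not emulate

The simulators are faithful to the published rule sets at the level that
matters for population dynamics: stochastic scheduling with shuffled
within-phase order, energy bookkeeping, exact conservation in the closed
pathway. They do not attempt heterogeneous per-agent traits beyond energy,
spatial structure in the surrogates, reversible reactions, or volume
changes, and the pathway's exact wiring (the identity of the two
regulatory interactions, the composition of the 12 complex species, copy
numbers and event probabilities) follows the package's own documented
defaults where the published description leaves them open. Passing tests
therefore demonstrate that the surrogate-control loop works as specified
on these reference systems, not that any particular parameterization
matches an external dataset.

One empirical caveat is worth stating plainly, because it shapes what the
inflow experiment can show. In this pathway parameterization the
substrate-waste loss is a non-decreasing function of the inflow: in quasi-
steady state the per-tick loss equals the outflow rate times the mean
substrate residence time, and that residence time can only grow with
inflow here, because both the feedback regulators and the dead-end product
complexes sequester enzymes in proportion to product levels, which scale
with the inflow. An interior optimum would require a mechanism (such as
cooperative, Hill-type turnover) that makes per-molecule conversion faster
at higher substrate load; the shipped topology has none, so the measured
optimal inflow sits at the low end of the grid rather than at an interior
point. The solver and grid-search machinery handle both shapes, as the
test suite demonstrates with a cooperative toy reactor that does have an
interior optimum.

## Reproducibility

Every stochastic stage takes an integer seed and derives per-realization
child streams from it by fixed offsets; identical seeds give bit-identical
trajectories, datasets and fits. `run_pipeline()` executes
simulate → fit → solve → lift (→ validate) end to end, writes each stage's
output under the chosen directory, re-executes only missing stages on
re-run, and records a manifest with the configuration hash and per-stage
seeds sufficient to reproduce any output file.

## What the validation runs show

Measured at the package's desk scale, the sheep-wolves-grass grid search
places the ABM optimum near 0.7% sheep and 0.4% wolf removal per tick, and
the effect of training with control data is family-dependent: the flexible
GMA surrogate, badly wrong when fit only to uncontrolled data (its
unconstrained kinetic orders extrapolate the removal response almost
arbitrarily), lands close to the ABM optimum once the controlled datasets
pin the response down; the mechanistic Lotka-Volterra surrogate
extrapolates acceptably even without control data, and its remaining
sheep-removal bias is structural (the bilinear grazing term cannot
represent the regrowth-flux-limited compensation of the lattice model,
whose standing grass barely moves under sheep removal), so control data do
not improve it further. Interpolation helps exactly where the model class
is too flexible to extrapolate - the mechanism the training-design is
built around.
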