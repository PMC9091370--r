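---
title: "Coupling genome-scale metabolism to chemostat dynamics with Flexible Nets"
author: "fermenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling genome-scale metabolism to chemostat dynamics with Flexible Nets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermenet)
```

## The model

fermenet answers a bioprocess question: at which feed concentration,
dilution rate and cell density does a continuous culture of an engineered
organism produce its target chemical fastest — and what do the cells'
internal fluxes look like at that optimum? Neither classical tool answers
it alone. Flux balance analysis (FBA) optimizes intracellular fluxes
`v` over `{S·v = 0, L ≤ v ≤ U}` but is blind to the reactor; chemostat
mass-balance models track tank concentrations but treat the cell as a
fixed yield coefficient.

The package's container for both is the Flexible Net, a tripartite
structure with three vertex classes:

* **places** hold state: intracellular metabolites (whose concentrations
  FBA disregards) and the macroscopic tank species — substrate `G` (mM),
  product `C` (mM) and biomass `X` (gDW/L);
* **transitions** carry processes: metabolic reactions, the reservoir feed,
  the effluent flows;
* **handlers** connect the two. *Event handlers* encode stoichiometry (the
  signed change of each place per unit occurrence of a transition);
  *intensity handlers* encode kinetics (how concentrations set transition
  speeds).

A constraint-based model maps onto this exactly: one place per metabolite,
one transition per reaction carrying the flux bounds as its default
intensity `lambda0`, one event handler per reaction carrying the
stoichiometry — and no intensity handlers, because constraint-based models
have no concentration dependence. Transition fluxes are non-negative, so
reversible reactions are first unfolded into forward/backward copies
(`<id>_f`, `<id>_b`); the net flux `v_f - v_b` spans the original range,
and LP optima are invariant under the split (a property the test suite
checks against an independent LP formulation on random models). At steady
state every place's inflow equals its outflow; the resulting LP *is* FBA.

The chemostat side adds three tank places and seven flow transitions. At
steady state:

* biomass: `mu·X = D·X`, hence the identity `mu = D` imposed explicitly
  (the dilution rate selects the growth rate);
* substrate: `D·c_g = u_g·X + D·s_g`, feed split between uptake and
  washout;
* product: `|u_c|·X = D·s_c`, secretion balanced by effluent. The model's
  secretion flux is oriented so the transition flux is non-negative; the
  sign convention "negative exchange = secretion" is absorbed by the arc
  orientation, and `s_c >= 0` holds in every optimum.

The interface handlers `h_u`, `h_r`, `h_c` carry the couplings
`u_t = u_g·X`, `r_t = mu·X`, `c_t = u_c·X`: tank-scale fluxes (mM/h) equal
specific cell rates (mmol/gDW/h) times the cell density. These are
bilinear — the crux of the whole problem.

## The region-wise relaxation

Each bilinear relation `w = v·X` is replaced, over a partition
`Xmin = X_0 < X_1 < ... < X_n = Xmax` of the biomass range, by the
region-`i` bracketing

`X_{i-1}·v <= w <= X_i·v` with `X` clamped to `[X_{i-1}, X_i]`.

One partition serves all three couplings, since all involve `X` —
partitioning `X` rather than `u_g` keeps the region count independent of
the number of interface handlers. Every exact solution of the bilinear
system is feasible in the region containing its `X`, so the best objective
over regions is an **upper bound** on the true optimum, non-increasing
under nested refinement. Rather than one mixed-integer program with a
binary per region, the regions are solved as independent LPs and the
maximum taken; the two are equivalent by construction, and the LP family is
embarrassingly simple. (A MILP mode is deliberately absent: no
mixed-integer solver is available to R here, and the region-wise sweep is
the faster route anyway.) Ties between regions break to the lowest index,
for determinism. Interior breakpoints belong to both adjacent region LPs
(closed intervals); harmless under maximization, and it avoids boundary
infeasibilities.

The matching lower bound comes from `oracle_solve()`: enumerate `X` on a
uniform grid, fix it, and solve the then-exactly-linear problem at each
grid point. Together they sandwich the truth:

`oracle(grid) <= true optimum <= piecewise(n)`

with both ends converging as the grid and partition refine. On the built-in
toy producer the sandwich closes around the hand-derived closed form
`VP* = D·c_g·(1 - D/(k·u_max))` — the package's central correctness
argument, exercised in the acceptance tests at `n` up to 256 (within 1% of
the closed form) and oracle grids of 2001 points.

Guarded intensity handlers (different linear rate laws in different
concentration regions, evaluated by `active_region()`) use half-open
activation intervals `[lo, hi)`, closed at the top of the final region, so
membership at a threshold is deterministic and exactly one guard is active
anywhere in the admissible range.

## Objectives and modes

For fixed feed concentration `c_s`, volumetric productivity
`VP = s_c·D` (g/L/h), productivity on substrate `PS = mu·Y_P/S = VP/c_s`
(1/h) and yield `Y_P/S = VP/(D·c_s)` are all maximized by the same linear
objective: the product effluent flux (`t_cout`). Every result object
satisfies `VP = PS·c_s` to 1e-9 and `VP = s_c·D` to 1e-6; these identities
are asserted in the test suite rather than re-derived here.

Two solving modes share the constraint machinery:

* **optimization** (`maximize_productivity()`): `X` free in
  `[Xmin, Xmax]`, bilinear terms relaxed region-wise; returns VP, PS,
  yield, the optimal biomass and the winning region.
* **prediction** (`predict_concentrations()`): `X` fixed to a measured
  biomass, which restores the exact bilinearity (each `w = v·X` is linear);
  the model then predicts the tank product concentration and the residual
  substrate for comparison with chemostat measurements. The objective
  remains maximal product export — the natural choice for a producer
  strain, and the one consistent with validation tables that report a
  single predicted concentration per condition. `relative_error()` uses
  `100·(observed - predicted)/predicted`, the orientation that reproduces
  the published validation errors (35.60% and -5.92%) from their
  observed/predicted pairs.

`sweep_grid()` composes per-point optimizations over a `c_g × D` grid
(CSV is the canonical output; plotting is presentation, not method), and
`region_convergence()` traces PS against the region count — non-increasing
for nested counts (n, 2n, 4n, ...).

## Parameters, defaults, and why

* `n_regions = 100`. The relaxation error scales like the region width
  over the optimal biomass (about `(Xmax - Xmin)/(n·X*)` relative); 100
  regions put the toy producer within ~3% and 400 within 1%, and runtimes
  grow linearly in `n`.
* `Xmin = 0`, `Xmax = 0.75·c_g` (gDW/L per g/L of feed). The cap is a
  yield argument: heterotrophic growth rarely exceeds 0.5 gDW per gram of
  glucose, with 50% headroom. The bounds need not be tight — only finite —
  but a slack `Xmax` loosens the relaxation at fixed `n`, so tighter
  user-supplied bounds help.
* Molar masses default to glucose (180.16 g/mol) and citramalate
  (148.12 g/mol); tank metabolites are tracked in mM internally while all
  user I/O is g/L, so conversions happen in exactly one place
  (`convert_units()`).
* Toy producer defaults `k = 0.1`, `u_max = 10` mmol/gDW/h give
  `mu_max = 1.0`/h — an *E. coli*-like scale on which dilution rates
  0.1–0.6/h are the interesting range; the worked example uses 10 g/L feed
  and `D = 0.5`/h.
* Oracle default: 2001 grid points, comfortably inside the 1% tolerances
  the toy-model checks use.
* LP tolerances: pivot/feasibility 1e-9, optimality comparisons 1e-6 —
  standard LP practice. The solver is a package-internal two-phase dense
  simplex with Bland's anti-cycling rule; steady-state nets produce heavily
  degenerate LPs (many zero right-hand sides), and Bland's rule trades a
  little speed for guaranteed termination and determinism. A presolve
  substitutes fixed variables, shifts positive lower bounds to zero, and
  drops linearly dependent equality rows (fixing `X` makes one tank balance
  redundant with `mu = D`). Unboundedness and infeasibility are explicit
  statuses, never large numbers.

## What the synthetic fixtures do and do not show

The toy producer reproduces the *structure* of the real system — substrate
partitioning between growth and product, the growth/production trade-off
`VP* -> 0` as `D -> k·u_max` (washout), carbon limitation forcing
`s_g = 0` — with a closed form against which every solver path is checked.
It does not emulate a genome-scale reconstruction's scale (thousands of
reactions), alternate optima, maintenance ATP, or transporter saturation;
passing the sandwich tests validates the relaxation machinery, not any
particular organism's physiology. Genome-scale predictions additionally
depend on medium uptake bounds and on which transport/exchange steps
accompany the inserted synthase — choices the original study leaves
unstated, which is why the genome-scale validation targets are conditional
on a user-supplied reconstruction (see the final acceptance test) rather
than asserted against the toy.

## Degenerate inputs and edge behavior

Washout (`D` above the model's maximal growth rate) is an infeasible
steady state and is reported as such, per region and overall. A zero feed
admits only the washed-out culture `X = 0`, where all interface fluxes
vanish while the *specific* cell rates remain free — per-gDW rates of zero
biomass. Empty models, missing flux bounds (no silent defaults), duplicate
reaction ids, non-monotone breakpoints and out-of-range measured biomass
are rejected with informative errors.

## Known limitations

Steady states only — no transient integration of the tank ODEs, no batch
or fed-batch modes. One limiting substrate and one product are tracked by
default (the net structure supports more). Specific uptake/export rates
are bounded only by the model's flux bounds, not by transporter saturation
kinetics. The relaxation bounds the optimum from above; reported optima at
finite `n` are upper bounds whose gap the oracle quantifies on small
models but not at genome scale. Problem sizes throughout the
documentation and tests (nets of tens of transitions, grids of hundreds of
points) reflect the package's dense-LP design point; genome-scale models
load and convert, but their region sweeps are best run with coarse
partitions first.
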