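---
title: "Turnover-space objectives and stoichiometry-representation independence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Turnover-space objectives and stoichiometry-representation independence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimbl)
```

## The problem this package addresses

Constraint-based models describe a metabolic network by its stoichiometric
matrix $S$ (rows: intracellular metabolites, columns: reactions) and predict a
flux distribution $v$ by optimizing a biological objective subject to steady
state, $S v = 0$, and flux bounds. The stoichiometric representation of any
single reaction is arbitrary up to a positive scalar: multiplying all
coefficients of reaction $r$ by $\theta > 0$ (and dividing its finite bounds
by $\theta$) describes the same biochemistry, with every solution's flux
mapping as $v_r \mapsto v_r/\theta$. A sound simulation method must therefore
give the same predictions for every such representation.

Objectives built from linear combinations of raw fluxes do not. Minimizing
total flux, or the Manhattan/Euclidean distance to a reference flux
distribution (lMoMA/qMoMA), weighs reaction $r$ by the numerical size of its
flux, which is representation-dependent; rescaling one reaction can reroute
the predicted solution through an entirely different pathway, flip an
essentiality call, or change a predicted genetic interaction. FBA-style
objectives (max/min of a single flux) are immune, because rescaling the lone
objective column rescales the optimum without reordering candidate solutions.

The remedy implemented here is to cast objectives in *metabolite turnover*
space. The turnover of an intracellular metabolite $m$ is its total
production rate,
$$t_m(v) \;=\; \sum_{i\,:\,s_{mi} v_i > 0} s_{mi} v_i,$$
which equals the total consumption rate at steady state. Because the
coefficients enter the definition, $t_m$ is invariant under rescaling:
coefficients grow by $\theta$ exactly as the flux shrinks by $1/\theta$.

## The simulators

* `fba()` — maximize/minimize one flux (growth by convention).
* `minimize_total_flux()` — parsimony in flux space, $\min \sum_i |v_i|$
  (representation-*dependent*; kept as a case study and for comparison).
* `minimize_total_turnover()` — parsimony in turnover space,
  $\min \sum_m t_m$ (representation-independent).
* `lmoma()` / `qmoma()` — Manhattan / squared-Euclidean minimization of
  metabolic adjustment relative to a reference flux distribution.
* `norm_lmoma()` — adjustment of reference-normalized fluxes (fold changes).
* `optimize_metabolite_turnover()` — max/min $t_m$ of one metabolite (ATP
  yield style objectives; with a single-reaction biomass pseudo-metabolite it
  reproduces the FBA growth optimum).
* `mimbl()` — the turnover-space adjustment method, two sequential linear
  programs:
  1. minimize the Manhattan distance between mutant and reference turnovers,
     $D^\* = \min \sum_m |t_m - t_m^{\mathrm{ref}}|$;
  2. among flux distributions whose turnover distance stays within
     $D^\*(1+\texttt{rtol})+\texttt{atol}$, minimize the normalized flux
     distance $\sum_i |v_i - v_i^{\mathrm{ref}}|\,/\,\max(|v_i^{\mathrm{ref}}|,
     \texttt{floor}/h_i)$, which pins the solution to the reference among
     turnover-equivalent alternatives.

On the bundled four-metabolite toy network (`build_toy_model()`: uptake
pinned to one unit, a direct conversion carried by the reference, a parallel
direct route, and a three-step detour), deleting the reference route makes
lMoMA's optimum $\min(1 + 1/\theta,\, 4)$ as a function of the parallel
route's scaling $\theta$, with an abrupt pathway switch at $\theta = 1/3$;
qMoMA shifts its route mix continuously with crossover at $\theta =
1/\sqrt3$; MiMBl's distance is identically zero with the same predicted
turnovers at every $\theta$.

## Normalization floor in turnover units

Normalized flux distances divide each deviation by the reference flux; zero
or tiny reference fluxes need a floor. A flat flux floor is itself
representation-dependent (whether $|v^{\mathrm{ref}}_i|$ is above or below
the floor changes with $\theta_i$), which would leak representation
sensitivity back into MiMBl's second step. The floor is therefore expressed
in turnover units: reaction $i$ is floored at the flux magnitude
$\texttt{floor}/h_i$ at which it converts `floor` units of material, where
$h_i$ is its largest absolute stoichiometric coefficient. Every term of the
objective is then invariant, and for unit-coefficient reactions the floor
reduces to the familiar flat flux floor (default `floor = 1` in the model's
flux units, mmol/gDW/h by convention).

## Exactness and determinism of the two-step optimization

Three numerical choices make `mimbl()` return a well-defined, reproducible,
representation-independent answer rather than an arbitrary vertex of a
degenerate program:

* **Direction enumeration.** Absolute values are linearized by variable
  splitting, and turnover inside the LPs is the production-side sum over
  split components. That linearization is exact only when no reversible
  reaction carries simultaneous forward and backward flux; otherwise the LP
  can "fake" production with futile two-way flux and report a turnover
  distance no net flux attains. Both steps are therefore solved once per
  forward/backward direction pattern of the genuinely reversible reactions
  (up to `direction_cap = 8` of them, i.e. at most 256 small LPs), and the
  best pattern wins; the reported distance is attained by the reported net
  flux. Networks with more reversible reactions fall back to the plain
  relaxation, which is recorded in the result's `step_log`.
* **Conversion-unit solving.** The step LPs are posed in conversion units
  $u_i = h_i v_i$ (deviation variables likewise, and rows whose right-hand
  side is a flux are rescaled the same way). In these units the assembled
  program is numerically identical for every stoichiometric representation
  of the same network, so equivalent representations cannot even in
  principle be solved differently.
* **Deterministic pivoting.** The simplex breaks entering-variable ties by
  lowest column index within a $10^{-9}$ band of the strongest violation
  (and leaving-variable ties by lowest basic index), so identical programs
  follow identical pivot paths even through exact degeneracy. Together with
  the previous point this makes the *full optimal flux vector* — not merely
  the objective value — invariant in practice to machine precision, even
  when the second step has tied alternative optima.

An optional third LP (`tertiary = TRUE`) minimizes total conversion
$\sum_i h_i |v_i|$ at the locked step-1/step-2 optima, a pFBA-style
parsimony refinement in representation-independent units.

## The linear-programming layer

No linear-programming package is available in this installation's R library
(the two candidates that ship LP routines fail on the degenerate zero
right-hand-side equality systems that steady-state constraints produce), so
the package carries its own dense two-phase bounded-variable revised simplex
(`lp_solve_std()`): Dantzig pricing with an automatic switch to Bland's rule
after a run of degenerate pivots, a bounded-variable ratio test with bound
flips, explicit basis-inverse updates with periodic refactorization, and
explicit `infeasible`/`unbounded`/`iteration_limit` statuses. It is
validated in the test suite against an independent reference LP solver on
randomized degenerate problems of the shapes the simulators generate. qMoMA
is the one quadratic program and is solved with the `quadprog` package.

## Perturbations and interaction screens

`knockout()` supports standard gene-centered GPR evaluation (a reaction is
off only when its boolean gene rule fails; `and` = complex subunits, `or` =
isoenzymes) and a reaction-centered isoenzyme mode in which any deleted
member gene silences the reaction — useful for probing interactions that
isoenzyme redundancy hides from the gene-centered view. Deleted genes
missing from every rule warn (screen gene lists routinely include
non-metabolic genes); unknown genes mentioned in rules count as present.

`interaction_screen()` computes single- and double-mutant growths under a
chosen simulator, caching singles, and scores each pair with the
multiplicative epistasis model $\varepsilon = f_{ab} - f_a f_b$ on fitnesses
clipped at zero ($f$ = mutant growth / wild-type growth). Calls use a
symmetric cutoff, default $|\varepsilon| > 0.013$ (an alternative published
operating point is $0.13$; the cutoff is a plain argument).
`sensitivity_precision_curve()` evaluates predictions against an observed
interaction table, which defines the truth universe; precision with zero
predictions is reported `NA`, never silently 0 or 1. Under FBA the double
mutant can never out-grow the better single mutant — the structural reason
FBA under-calls positive interactions, checked as a property in the tests.
`network_distance()` measures gene-gene separation as the shortest path
between reaction sets in a reaction-adjacency graph, where metabolites above
a reaction-degree cutoff (default: the 95th percentile of the degree
distribution) are treated as currency metabolites and do not connect
reactions.

## Variability and alternative optima

`fva()` computes per-reaction flux ranges with the objective locked: FBA
growth at its optimum, the lMoMA distance, or MiMBl's turnover distance at
$D^\*$. The `unique` flag implements the ratio criterion
$\min(|v_{\min}|,|v_{\max}|)/\max(|v_{\min}|,|v_{\max}|) > 0.99$ with an
exactly zero range counted unique. `enumerate_alternative_optima()` collects
flux distributions attaining the FBA optimum with pairwise-distinct
active-reaction patterns ($|v| > 10^{-6}$) by probing the optimum-locked
polytope with seeded random secondary objectives; no integer-programming
backend exists in this installation, so the randomized probe is the sole
mechanism, which is exhaustive on small networks (on the toy problem it
recovers all three route patterns) but offers no completeness guarantee on
large ones.

## The synthetic-model generator

`generate_random_model()` emulates the situation the adjustment methods face
in practice: a connected conversion network with one capped uptake and one
sink (the objective), a known steady-state reference built by superposing
`parallel_paths = 3` random source-to-sink routes, alternative routes for
rerouting after deletions, reversible side reactions, non-unit
stoichiometry, and single-gene rules with occasional isoenzyme (`or`)
partners. Two deliberate idealizations keep the property suites sharp.
Route weights are continuous (uniform on 0.5–2), so rerouting costs are
generic and objective ties are coincidences of network symmetry rather than
of integer arithmetic. Conversion reactions carry the same coefficient
(1 or 2) on both sides, which rules out flux-amplifying cycles and keeps FBA
bounded without curated bounds. Real reconstructions violate both
idealizations — they have mass-changing reactions with curated bounds,
multi-substrate reactions, compartments, and currency-metabolite hubs — so
passing properties on these fixtures demonstrates correctness of the
algorithms, not predictive performance on any organism. Default sizes
(8 metabolites, 14 reactions) keep a 200-trial invariance screen within
seconds on one CPU; the test suite runs trials at exactly these sizes.

## Degenerate inputs and edge policies

Infeasible perturbations report status `"infeasible"` (screens convert that
to growth 0); unbounded objectives report `"unbounded"`. Fixed fluxes
(`fixed =`) override bounds as equality pins, so "all exchanges shut" is
expressible even on models with forced uptake. Reactions listing a
metabolite on both sides are net-collapsed at construction, making
production/consumption classification well defined. Total-flux minimization
sums *all* reactions, exchanges included, so pinned exchange fluxes
contribute their magnitude; a `reactions =` argument restricts the sum when
an intracellular-only parsimony is wanted. The toy network pins its uptake
at the reference rate (bounds `[1, 1]`), the convention under which the
adjustment distances above hold; with a relaxable uptake, shutting the
network down entirely (distance 3) would undercut the detour route and the
pathway-switch illustration would be about shutdown, not rerouting.

## Known limitations

* Genome-scale reconstructions are supported through the SBML/TSV readers
  but none ships with the package, and the dense simplex is sized for
  networks of tens to a few hundred reactions, not thousands.
* Above `direction_cap` reversible reactions MiMBl uses the LP relaxation,
  whose reported distance can undercut the best attainable net-turnover
  distance on networks where two-way flux can mimic production; `fva()`
  turnover locks always use the relaxation.
* The SBML dialect is the classic Level-2 constraint-based one
  (`boundaryCondition`, kineticLaw bound parameters, `GENE_ASSOCIATION`
  notes); Level-3 `fbc` documents are not parsed.
* Epistasis scoring is the multiplicative form only; no statistical
  significance machinery is attached to interaction calls or to network
  distance distributions.
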