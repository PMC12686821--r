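---
title: "Designing growth-coupled production strategies for adaptive laboratory evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing growth-coupled production strategies for adaptive laboratory evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evolvexga)
```

## The design problem

Adaptive laboratory evolution (ALE) improves a trait only when that trait
covaries with fitness. Heterologous production usually does not: product
synthesis drains precursors, redox power and energy from growth, so serial
passaging selects *against* producers. The way out is to re-engineer the
metabolic network and the growth medium so that flux through the production
route (or through the native reactions supplying it) becomes *flux-coupled*
to growth — then any mutation that raises growth rate also raises the
coupled flux, and ALE does the strain optimization.

This package searches for such designs in a genome-scale metabolic model
(GEM). A design is a pair of small sets: up to $K$ reaction knockouts
(achievable by gene deletions) and up to $E$ components of the chemical
environment (nutrients whose uptake is opened). The search is a genetic
algorithm; the fitness of a design is a worst-case flux-coupling score
solved as a linear or mixed-integer linear program on the constrained model.

## The coupling score

Let $S$ be the stoichiometric matrix and $v$ the flux vector with bounds
$v_{lb} \le v \le v_{ub}$. A design view fixes $v_{inh} = 0$ for each
knockout $inh \in I$ and forces uptake ($v_n \le -1$, uptake being negative
flux by the usual exchange convention) for each selected nutrient
$n \in N$. Growth is pinned to an arbitrary constant $a$, so all fluxes are
expressed per unit growth and the score has units of mmol/gCDW — no *in
vivo* uptake rates are needed.

Scoring is a two-stage optimization.

**Stage 1 — maximal-yield regime.** Minimize the absolute total uptake over
the selected environment, $r_{uptake} = \sum_{n \in N}(-v_n)$, subject to
$S v = 0$, $v_\mu = a$, the view's constraints and the bounds. The optimum
$r_{uptake,max}$ identifies the most nutrient-efficient way to grow at rate
$a$. An optional cap (75 mmol/gCDW in restricted searches) declares a design
infeasible when even the minimum uptake exceeds it, filtering out designs
that could only couple production by absurdly wasteful feeding.

**Stage 2 — worst-case coupling.** With total uptake pinned to
$r_{uptake,max}$ (up to a $10^{-6}$ relative slack guarding against solver
noise), solve

$$\min \; \sum_{u \in H} v_{|u|} \;-\; \sum_{d \in L} v_{|d|}$$

over the same polytope, where $H$ and $L$ are the up- and down-regulation
target sets and $v_{|u|}, v_{|d|}$ are auxiliary variables pinned to the
targets' absolute fluxes. The optimum is the guaranteed (minimum) absolute
flux through the up-targets minus the largest absolute flux the
down-targets could still carry: the worst case over all optimal-yield flux
states. A positive score certifies that the targets *must* run whenever the
cell grows at maximal yield — exactly the covariance ALE needs.

Absolute values are linearized exactly. For an up-target,
$v_u - v_{|u|} \le 0$ and $-v_u - v_{|u|} \le 0$ bound $v_{|u|}$ from
below, and minimization makes it tight. For a down-target the same pair
bounds from below while a big-$M$ pair with a binary $d_{|d|}$
($v_{|d|} \le v_d + M d_{|d|}$, $v_{|d|} \le M(1-d_{|d|}) - v_d$) bounds
from above, so $v_{|d|} = |v_d|$ at *every* feasible point, not only at the
optimum. The binary is only needed for reversible down-targets; with none,
the whole problem is an LP. $M$ defaults to twice the bound magnitude,
$v_{|t|}$ upper bounds to $\max(|v_{lb,t}|, |v_{ub,t}|)$.

Design choices worth flagging, since the formulation leaves them open:

- The stage-2 uptake constraint is implemented as
  $\sum_{n}(-v_n) \le r_{uptake,max}$, pinning scoring to the maximal-yield
  regime. Read literally as "$\ge$ the minimum", the constraint would be
  vacuous (every feasible point satisfies it) and the score would collapse
  to the unconstrained worst case.
- The uptake selector spans only the selected environment components, not
  base exchanges (oxygen, water, ions, phosphate, sulfate): those stay open
  in every design and are not "nutrient utilization" in the sense the cap
  is meant to limit.
- An infeasible design scores $-\infty$ rather than raising an error, so
  the GA ranks it last and continues.
- Whether the forced-uptake magnitude in $v_n \le -1$ should scale with $a$
  is undetermined; the constraint is applied literally with magnitude 1 for
  any $a$.

Conventional settings: $a = 10$ with bounds $\pm 1000$ when the environment
is fixed and only knockouts are searched; $a = 1$ with bounds $\pm 20000$
when environment and knockouts are searched jointly.

## The genetic algorithm

A chromosome is a fixed-cardinality pair: exactly $K$ knockouts (default 4)
from the pruned candidate list and exactly $E$ environment components
(default 3). In serialized form each candidate position carries a binary
value with 0 marking an active knockout or selected component. Each
generation:

1. every chromosome is scored (memoized — a design is solved at most once
   per run),
2. the `elite_count` best (default 10; ties broken by score then
   lexicographic serialization, for reproducibility) pass unchanged,
3. the rest are produced by choosing two parents uniformly at random,
   crossover, then mutation.

Crossover acts per segment with probability 0.8: the child's segment is a
uniform size-$K$ (or size-$E$) subset of the union of the parents'
segments. This is the smallest operator that recombines parents while
preserving cardinality exactly — naive bit-level single-point crossover
would not. Mutation, also per segment with probability 0.8, swaps one
active element for a uniformly chosen inactive candidate. Population size
defaults to 50. All randomness flows from one seed; a run is bit-identical
when repeated.

On every search space small enough to enumerate (up to $10^4$ designs) the
package's `exhaustive_search()` provides the ground truth; the test suite
requires the GA to recover it.

## Search-space pruning

Knockout candidates are all reactions *except*: growth-essential reactions
(single-deletion FBA drops growth below $10^{-6}$ of the wild-type maximum
— an LP noise floor, since no biological cutoff is prescribed),
production-essential reactions (same sweep with the product exchange as
objective), blocked reactions (flux variability min and max within
$10^{-9}$ of zero), reactions without gene annotation (not deletable),
transport/exchange/diffusion pseudo-reactions, and user-supplied extra
exclusions (e.g. lipid metabolism). Each excluded reaction is recorded with
the first rule that removed it.

Essentiality and blockedness are screened in a single superset environment
with *all* candidate exchanges open simultaneously, as a tractable proxy
for "any nutritional environment": with uptake-monotone feasible regions, a
reaction blocked under the superset is blocked in every sub-environment.
Diffusion reactions cannot be recognized from stoichiometry and must be
tagged in the model file; transport reactions are auto-tagged when a
reaction moves the same metabolite species between compartments with no
other chemistry.

## Native up-regulation targets (ROOM variant)

When a heterologous route cannot be coupled directly, the targets become
the native reactions that must carry more flux when the cellular objective
shifts from growth to production. These are found with a ROOM-type MILP:
minimize the number of reactions whose flux leaves the window
$[w_j - \delta|w_j| - \varepsilon,\; w_j + \delta|w_j| + \varepsilon]$
around a wild-type reference $w$, subject to steady state, bounds, and the
production constraint $v_{prod} \ge 0.99 \cdot v_{prod}^{max}$ (the
maximum theoretical production, computed with growth unconstrained apart
from nonnegativity). Defaults: $\delta = 0.5$, $\varepsilon = 10^{-5}$.
Reactions whose production-state flux *magnitude* exceeds the window are
the up-regulated set fed to the coupling search.

Two constructions are deliberate choices rather than consequences of the
formulation:

- **The reference state** is the parsimonious growth-maximal flux
  distribution (maximize growth, then minimize total absolute flux). ROOM
  needs one reference vector; plain FBA optima are degenerate, and the
  parsimonious secondary objective removes that arbitrariness
  deterministically. The reference mode is recorded in run metadata and
  swappable.
- **Up-regulation is judged on absolute flux** against
  $|w_j|(1 + \delta) + \varepsilon$, so a reversible reaction growing in
  magnitude in the negative direction counts as up-regulated — consistent
  with the coupling score, which is also absolute. (Judging $|v|$ against
  the signed upper threshold $w_j + \delta|w_j| + \varepsilon$ would be
  vacuous for negative references.)

A limit worth knowing: $\delta$ scales the window with $|w|$, so raising
$\delta$ alone never frees a reaction whose reference flux is zero — its
window stays $\pm\varepsilon$. Production targets have zero reference flux
by construction and therefore always count as changes unless
$\varepsilon$ is widened too.

## Numerical core

No LP/MILP solver library ships with this package's dependencies, so the
optimization layer is self-contained: a bounded-variable two-phase primal
simplex (dense basis re-factorization each iteration, Dantzig pricing with
a Bland's-rule fallback after long degenerate runs, feasibility and
optimality tolerances $10^{-9}$) and a depth-first branch-and-bound over it
for the binaries (integrality tolerance $10^{-6}$, most-fractional
branching, incumbent pruning). Problem sizes in scope — toy networks up to
~30 reactions, a handful to a few tens of binaries — are far inside the
comfortable range for a dense simplex; the absolute-value identity
$v_{|d|} = |v_d|$ is asserted after every scoring solve as a self-check.

The independent oracle path used in tests deliberately avoids this
machinery's formulation: the score is recomputed single-stage by
enumerating target-flux sign patterns (absolute values are linear within
each orthant) on a shifted nonnegative-variable encoding, solved with
`pracma`'s textbook simplex where it converges. That simplex is numerically
fragile on degenerate bases, so a non-converged run falls back to the
package simplex on the *same shifted encoding* — solver independence holds
wherever `pracma` converges, formulation independence everywhere, and a
solver failure is never misread as infeasibility.

## What the synthetic toys do and do not show

The bundled generators (`make_branch_toy()`, `make_fivepath_toy()`,
`make_random_toy()`) produce small, connected, growth-feasible networks:
a substrate-to-biomass backbone, random side reactions with stoichiometric
coefficients in $\{-2,-1,1,2\}$ and mixed reversibility, and extra
nutrient/drain exchanges. Coefficients are kept small-integer so the
enumeration oracles stay exact; generation retries with perturbed seeds
until growth is feasible and is deterministic per seed.

These toys exercise every code path — bypass-induced uncoupling, futile
cycles that down-targets exploit, essentiality, blocked dead ends,
infeasible designs — but they do not emulate genome-scale features:
thousands of reactions, compartmentalization, cofactor balancing across
many carriers, degenerate alternate optima at scale, or biomass equations
with dozens of precursors. Passing tests certify the algorithms and their
implementations, not predictions about any real organism; runs on a real
GEM (e.g. a consensus yeast reconstruction with a heterologous pathway
added from a TSV definition) use exactly the same code path via
`read_sbml_model()` but inherit all the usual caveats of constraint-based
modeling.

Problem sizes used by the test suite and the acceptance script were chosen
to keep the whole battery at desk scale: 100 and 60 seeded random networks
of 8–14 reactions for oracle agreement, an 84-design space for GA recovery
(20 and 10 seeded runs), ROOM enumeration up to $2^{12}$ indicator
patterns, and the five-reaction analytic toy for exact values.

## Known limitations

- Reaction-level knockouts only; gene–protein–reaction logic is out of
  scope (a knockout list must be mapped to genes by hand).
- One optimal vertex is reported per solve; alternate optima are not
  sampled (the worst-case construction makes the score itself
  degeneracy-robust, but per-target fluxes and uptakes may be one of
  several optima).
- No thermodynamic or enzyme-capacity constraints; couplings that rely on
  kinetically implausible futile cycles are reported as found (the
  reversible-bypass toy in the test suite shows one deliberately).
- The dense simplex is sized for the bundled analyses; genome-scale FVA
  sweeps would want a sparse factorized solver behind the same interface.
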