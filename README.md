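# evolvexga

Genome-scale-metabolic-model–guided design of **growth-coupled production
strategies for adaptive laboratory evolution (ALE)**.

Heterologous production rarely benefits a cell: it drains precursors, redox
power and energy, so serial-passage evolution selects against producers.
`evolvexga` searches for small combinations of **reaction knockouts** and
**chemical-environment components** under which selected fluxes — a
heterologous pathway, or the native reactions supplying it — become
*flux-coupled* to growth. Once coupled, every growth-improving mutation also
improves the coupled flux, and ALE becomes a strain-optimization tool.

The package is aimed at computational strain designers working with
constraint-based models: it reads SBML Level 3 (fbc) or a simple tabular
format, and everything downstream (FBA/FVA/pFBA, the scoring MILP, the
genetic algorithm, ROOM) runs on a self-contained bounded-variable simplex
and branch-and-bound core.

## The score

For a design — knockout set $I$, environment set $N$ — the model view fixes
$v_{inh}=0$ ($inh \in I$), forces uptake $v_n \le -1$ ($n \in N$; uptake is
negative flux), and pins growth to a constant $a$. Scoring is two-stage:

1. **Minimal total uptake**: $r_{uptake,max} = \min \sum_{n \in N} (-v_n)$
   subject to $Sv = 0$, $v_\mu = a$, bounds — the maximal-yield regime. An
   optional cap (75 mmol/gCDW) rejects designs that only grow by wasteful
   feeding.
2. **Worst-case coupling**: with total uptake pinned to that minimum,
   $$\min \sum_{u \in H} v_{|u|} - \sum_{d \in L} v_{|d|},$$
   where $v_{|t|}$ equals the absolute flux of target $t$ (exact big-M
   linearization; binaries only for reversible down-targets, so the problem
   is an LP whenever the down set is irreversible or empty).

The optimum is the guaranteed flux through the up-targets minus the largest
flux the down-targets could still carry, in mmol/gCDW (flux per unit
growth). A positive score certifies the up-targets *must* run whenever the
cell grows at maximal yield.

The search is a fixed-cardinality genetic algorithm (default: 4 knockouts,
3 environment components, population 50, elitism 10, 80 % crossover and
mutation per segment), with candidates pruned by essentiality, blockedness,
gene annotation and pseudo-reaction category. A modified ROOM (δ = 0.5,
ε = 1e-5, production ≥ 99 % of the theoretical maximum) identifies native
up-regulation targets when a pathway cannot be coupled directly. The
methods vignette (`vignettes/growth-coupled-design.Rmd`) derives all of
this in detail.

## Worked example

The bundled branch toy has an uptake `EX_A`, a two-step route `R1` (A→B),
`R2` (B→C), a one-step bypass `R3` (A→C) and a biomass drain `GROWTH`.
Flux through `R1` is uncoupled from growth — until the bypass is removed:

```r
library(evolvexga)
env  <- make_branch_env_space()
view <- apply_constraints(make_branch_toy(), knockouts = "R3",
                          environment = "A", env_space = env)
evolvex_score(view, target_set(up = "R1"), scoring_config(a = 1))
#> evolvex_score: 1 mmol/gCDW ( LP )
#>   minimal total uptake: 1 mmol/gCDW
#>   per-target |flux|: R1=1
#>   uptake: EX_A=1
```

Score 1 at `a = 1`: per unit of growth, one unit of flux is *guaranteed*
through `R1` (without the knockout the score is 0; with `a = 10` it scales
to 10). The GA finds that knockout by itself on the five-candidate variant
of the toy:

```r
toy  <- make_fivepath_toy()
cand <- build_candidate_space(toy, env)   # prunes to the five internals
run  <- run_ga(toy, target_set(up = "R1"), cand, scoring_config(a = 1),
               ga_config(population_size = 10, elite_count = 3,
                         generations = 10, K = 1, E = 1, seed = 1))
run
#> ga_run: 10 generations, 5 designs evaluated
#>   best score: 1 mmol/gCDW
#>   knockouts: R3
#>   environment: EX_A
```

When a pathway cannot be coupled directly, the ROOM variant proposes native
targets — here, adding a production pathway `P`/`EX_Prod` to the branch toy
and demanding 99 % of maximal production identifies the pathway itself as
the minimal up-regulated set:

```r
aug <- add_pathway(make_branch_toy(), make_branch_pathway())
w   <- wild_type_reference(aug)           # parsimonious growth optimum
room_min_change(aug, w)
#> room_result: 3 flux changes; production 9.9
#>   changed: GROWTH, P, EX_Prod
#>   upregulated: P, EX_Prod
```

A command-line wrapper with subcommands `prune`, `score`, `evolve`,
`native-targets` and `make-fixture` ships at `inst/cli/evolvexga`; every
run writes a manifest (config echo, seed, solver identity, version) next to
its outputs.

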