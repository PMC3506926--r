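# hetpath

Heterologous pathway design for nonnative metabolite production, by
iterative network expansion and flux balance analysis.

## The problem

Industrial hosts such as *Escherichia coli*, *Corynebacterium glutamicum*
and *Saccharomyces cerevisiae* are routinely engineered to make compounds
they cannot synthesize natively — diols, aromatic aldehydes, dicarboxylate
precursors, and the like. Choosing which foreign (heterologous) enzymatic
reactions to add is hard: the candidate set is the whole of known
metabolism, and a pathway that reaches the target on paper may still carry
zero flux once cofactor and redox balances are enforced. `hetpath` is for
metabolic engineers and systems biologists who want a desk-scale, fully
scriptable version of this screening workflow:

1. **Network expansion.** Starting from the host's native metabolite set
   `M0` and reaction set `R0`, iteratively admit candidate reactions from a
   reaction database. At iteration `i`, a reaction joins `Ri` when it is
   new to the network (by canonical stoichiometric signature) and one of
   its directions can fire from the metabolites accumulated so far while
   producing at least one compound not yet reachable; the newly produced
   compounds form `Mi`. All database reactions are treated as reversible,
   because curated reversibility is too sparse to trust at screening time.
   Iteration stops when nothing further connects.
2. **Backtrace.** For any connected target, recursively collect the
   producer reaction of the target and of every nonnative substrate it
   needs — a minimal-iteration heterologous reaction set sufficient to
   reach the target from `M0`.
3. **Flux balance analysis.** Add those reactions (and a demand column for
   the target) to the host's stoichiometric model and solve
   `max c'v  s.t.  S v = 0, lb ≤ v ≤ ub` on a glucose minimal medium.
   A target is *producible* when its maximum demand flux is positive, and
   *growth-coupled* when, after maximizing biomass and re-maximizing the
   target at the fixed biomass optimum (the lexicographic resolution of
   degenerate growth optima), its molar yield on glucose still clears a
   threshold (default 1%).
4. **Host comparison.** Chi-square contingency tests per functional
   category flag where hosts differ in what they can produce.

## A worked example

The package ships self-contained fixture generators for the published
worked examples, each a micro-host plus the printed candidate reactions:

```r
library(hetpath)

fx <- table2_fixture("pentanedione_cglut")   # host lacking methylglyoxal
ns <- native_sets(fx$host)
ex <- expand_network(ns$M0, ns$R0, fx$db)
pw <- backtrace(ex, fx$target)
pw
#> <hp_pathway> target X_pentane_2_4_dione: 2 heterologous reaction(s), connected at iteration 2
#>   reaction_id direction iteration
#> 1     RT2_MGS   forward         1
#> 2    RT2_PTD1   reverse         2

fm <- build_flux_model(fx$host, pw, fx$db, fx$medium, fx$target)
bc <- biomass_coupled_production(fm)
c(biomass = bc$biomass_opt, target_at_optimum = bc$target_flux)
#>           biomass target_at_optimum
#>                 4                 8
```

Reading: reaching pentane-2,4-dione in this host needs two added
reactions — methylglyoxal synthase fired forward, then the dioxygenase
fired in reverse — and under the micro-aerobic glucose medium the pathway
still carries 8 mmol/gDW/h at the growth optimum of 4 (it evolves oxygen,
which the oxygen-limited host happily consumes), i.e. the target is
growth-coupled with an 80% molar yield on glucose. `screen_targets()` runs
this end-to-end for every connectable compound and `category_enrichment()`
compares hosts; `inst/cli/hetpath` exposes the same pipeline as a shell
command.

## Acceptance script

`scripts/acceptance.R` rebuilds the six worked-example fixtures from
scratch, runs expansion and backtrace on each, and writes the resulting
heterologous reaction counts as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
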