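---
title: "hetpath: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hetpath: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetpath)
```

`hetpath` screens heterologous pathways: minimal sets of foreign enzymatic
reactions that let an industrial host produce a metabolite absent from its
native metabolism, together with a flux-balance assessment of whether the
production can actually carry flux — and whether it survives growth
maximization. This vignette records the model, its assumptions, the
tunable parameters, and the design decisions taken where the problem was
genuinely open, in the spirit of a methods section.

## 1. The expansion model

The host contributes a native compound set `M0` (KEGG compound identifiers,
collapsed over compartments) and a native reaction set `R0` (canonical
stoichiometric signatures). A candidate database — parsed from a
KEGG-ligand-style TSV — is then admitted in rounds:

* at round `i`, a candidate fires in a direction when its substrates on
  that side are reachable, and it is *productive* when it also yields at
  least one unreachable compound;
* productive candidates whose signature is not yet in the network join
  `Ri`; their new products form `Mi`;
* iteration continues until closure (no further compound connectable).

Three modeling commitments deserve explanation.

**All reactions are reversible.** Curated reversibility is sparse and
unreliable across the reaction databases this tool targets; a wrong
irreversibility call silently deletes pathways. We therefore try both
directions of every candidate and leave plausibility judgments (e.g. on
decarboxylations) to downstream curation. Host reactions, by contrast,
keep their model bounds for flux analysis.

**Firing rule.** The default `all_substrates` rule requires every
substrate of the firing direction to be reachable — the stoichiometrically
meaningful reading, and the one that reproduces every worked example the
package ships. The permissive `any_substrate` variant (one reachable
substrate suffices) is retained as a documented option; it provably
connects a superset of compounds and never later, a property the test
suite checks against an independently coded breadth-first oracle.

**Closure semantics.** Once admitted, a reaction stays in the expanded
network, so a direction that becomes enabled only in a later round can
still fire and connect further compounds (the reaction id joins `Ri` only
once). The alternative — consuming a reaction at admission — sounds
equivalent but is not: an early one-direction firing would block the later
reverse firing, and the superset property of `any_substrate` would fail.
Property-based testing surfaced exactly this, which is why the semantics
are spelled out here.

**Determinism.** When several reactions first produce a compound in the
same round, the producer recorded for backtracing is the lexicographically
smallest reaction id, forward direction before reverse. Backtraces are
therefore reproducible; they are minimal in connection iteration but *not*
guaranteed minimum-cardinality over all conceivable reaction subsets (that
would be a set-cover problem; enumeration of alternatives is out of
scope).

Signature canonicalization nets out compounds appearing on both sides,
merges repeated terms, and normalizes orientation, so that permuting terms
or swapping sides never changes a signature while any stoichiometric
change does. Equations with symbolic polymer coefficients ("n", "(n+1)")
have no defined stoichiometric column for flux analysis; they are excluded
from the candidate set and recorded in a skip report rather than silently
dropped.

## 2. The flux model

`build_flux_model()` assembles `S v = 0` from the host reactions, the
backtraced heterologous reactions, and a demand column exporting the
target. Heterologous reactions are placed in the cytosol — the host models
give no inter-compartment rule for foreign enzymes, and compartment
transport limits are a known caveat of this model class — with the
conventional symmetric bound of ±1000 mmol/gDW/h. Nonnative compounds get
fresh matrix rows.

Parameters that matter, with defaults:

| parameter | default | unit | rationale |
|---|---|---|---|
| carbon source | glucose (C00031) | — | sole carbon source |
| carbon uptake bound | 10 | mmol/gDW/h | conventional glucose uptake in genome-scale work |
| oxygen uptake bound | 2 | mmol/gDW/h | "micro-aerobic": small but nonzero; 0 gives anaerobic |
| free exchanges | CO2, H2O, sulfate, NH3, H+ | — | freely transported externals; protons added for practicality |
| heterologous bound | ±1000 | mmol/gDW/h | standard GEM convention |
| yield threshold | 1 | % (mol/mol) | cutoff for calling a target "produced" |

The literature this workflow follows states the micro-aerobic condition
but not its numbers; the oxygen and glucose bounds above are chosen once
as field-conventional values and are fully configurable. Absolute
genome-scale producibility percentages are consequently not reproducible
and are not claimed.

**Yield** is mol target per mol carbon source, ×100, measured against the
*realized* uptake flux at the optimum (uptake is the negative exchange
flux). A carbon-mol basis would need elemental formulas, which the
reaction-table format does not carry.

**Lexicographic optimization.** Growth optima of flux models are routinely
degenerate. Producibility under growth is therefore evaluated in two
stages: maximize biomass, then maximize the target demand with the biomass
flux fixed at its optimum. The fix uses a tiny *absolute* tolerance
(1e-9): a relative slack (say 1e-6 of a biomass of 10) would let the
solver trade 1e-5 units of growth for 1e-5 units of target, which is
enough to blur the distinction the two-stage scheme exists to draw — the
strict-competition toy below must report exactly zero. The contract that
stage-2 biomass equals the stage-1 optimum is still verified at relative
1e-6.

**Tolerances.** LP pivot/feasibility 1e-9; zero-flux tolerance for
producibility 1e-6; every optimal solution is checked to satisfy
`max |S v| ≤ 1e-6`.

**The solver.** No LP package is assumed: flux models at fixture scale
(tens of rows and columns) are solved by a built-in dense two-phase primal
simplex with Bland's rule for both entering and leaving variables, which
guarantees termination on degenerate bases. On every small random LP the
suite cross-checks it against an exhaustive vertex-enumeration oracle to
1e-8. This solver is deliberately simple and is not intended for
genome-scale matrices; swapping in an industrial solver behind
`solve_lp()` is the obvious extension.

## 3. What the fixtures emulate — and what they do not

The worked-example generators (`table2_fixture()`) rebuild published
pathway examples as *micro-hosts*: the native metabolites each pathway
requires, riding on a shared glucose → pyruvate → biomass backbone with
NAD(H) cycling and oxygen-limited respiration, plus the printed candidate
equations (names resolved through a bundled compound table; compounds
without a well-established KEGG identifier get deterministic synthetic ids
in a reserved `X_` namespace). Case-specific natives are fed by 1:1
pyruvate supply lumps — except non-carbon species such as orthophosphate,
which get exchanges instead, precisely because a supply lump would act as
a phantom carbon source. Cofactor pairs (NAD+/NADH, NADP+/NADPH,
FAD/FADH2, ATP/AMP) are ordinary compounds with explicit cycling
reactions; no special-casing, since the growth-coupling mechanisms of
interest (oxygen evolution, NADH reoxidation) depend on them being modeled
plainly.

These micro-hosts are *not* mass- or element-balanced chemistry: a supply
lump turns one pyruvate into one glycerone phosphate. A green test on
them establishes that the algorithms — expansion, backtrace, lexicographic
FBA, yield accounting — behave exactly as specified on networks whose
answers are known by hand; it does not establish anything about a real
genome-scale reconstruction, reachable-set sizes, or real yields. The
analytic toys (`analytic_fba_toys()`) play the same role for the solver:
a linear chain (yield 100%), a 2:1 branch (50%), a strict
biomass-competition case (target 0 at the growth optimum) and an
oxygen-limited NADH-reoxidation case (target 6 at a growth optimum of 4).

Random expansion instances are seeded hypergraphs whose layer assignments
are computed by a separately coded naive breadth-first oracle and frozen
as expected values; determinism is part of the contract
(`random_instance(n, m, seed)` is a pure function of its arguments).

## 4. Degenerate inputs and tie-breaks

* Equations that cancel completely (`A <=> A`) are unusable and land in
  the skip report.
* Duplicate stoichiometric signatures in a database collapse to the
  lexicographically smallest reaction id, keeping the union of EC, gene
  and organism annotations, so heterologous additions are never counted
  twice.
* Minimum-Km annotation ties are broken alphabetically by organism;
  wildcard EC numbers ("1.3.99.-") match by prefix on the defined digits.
* Targets already native to the host backtrace to an empty pathway;
  unconnected targets are an error for `backtrace()` and a distinguished
  status for `connection_iteration()`.
* Enrichment categories with an all-zero row or column margin have no
  defined chi-square expectation and are excluded (and logged in the
  result's `excluded` attribute). The contingency structure is hosts ×
  produced/not per category by default; the per-host one-vs-rest 2×2
  variant is labelled in the output. No multiple-testing correction is
  applied by default, matching the raw `P < 0.001` convention of this
  analysis style; Bonferroni is a flag.

## 5. Known limitations

* The expansion is reachability, not stoichiometric feasibility: a
  connected target can still be non-producible once cofactor balance is
  enforced — that separation is the point of the FBA stage, but it means
  iteration counts alone should never be read as feasibility.
* One deterministic pathway per target; alternative routes of equal depth
  are not enumerated.
* The built-in simplex is exact enough at fixture scale but is not a
  genome-scale solver.
* Compartment handling is deliberately coarse (collapse for expansion,
  cytosol for additions); organisms where compartment transport dominates
  production capacity need a finer model.
* SBML import is not provided; the two-section TSV dialect is the
  reference format and is designed to be hand-writable.
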