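---
title: "Methods: multi-goal design screening over constraint-based models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-goal design screening over constraint-based models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxscape)
```

`fluxscape` screens metabolic engineering designs — combinations of a
medium composition and a genotype of up to two gene deletions — over a
constraint-based metabolic model, then analyzes the resulting population
of phenotypes for dominant phenotypic classes, multi-goal optima and
perturbation sensitivity. This vignette documents the model, the
numerical choices, the defaults and their rationale, and what the bundled
synthetic fixtures do and do not establish about real genome-scale
screens.

## The constraint-based model and its assumptions

The metabolic state of a design is the solution of the flux balance
analysis (FBA) linear program

$$\max_x f^\top x \quad \text{s.t.} \quad A x = 0,\; \alpha_i \le x_i \le \beta_i,$$

where $A$ is the $m \times n$ stoichiometric matrix and $f$ selects the
biomass reaction. The steady-state assumption ($Ax = 0$) means no
internal metabolite accumulates; concentration dynamics and dilution are
out of scope. Thermodynamic irreversibility enters only through
$\alpha_i \ge 0$ on irreversible reactions. The medium is imposed on
exchange reactions: uptake is a negative exchange flux, so a nutrient in
the medium opens its exchange lower bound to $-\text{max\_uptake}$ and
every other *catalog* nutrient is closed at 0. Exchanges that are not
medium-controlled (secreted products, freely exchanged CO2) keep their
model bounds; this matters because carboxylating pathways legitimately
consume environmental CO2 without it being a purchased nutrient. A gene
deletion zeroes both bounds of every reaction whose gene–protein–reaction
rule evaluates false, with AND meaning an enzyme complex (all subunits
required) and OR isozymes (any suffices). No non-growth-associated
maintenance flux is added by the engine; if a model encodes one as a
bound, it is honored as-is.

### Linear programming

Flux polytopes are solved by the package's own two-phase bounded-variable
primal simplex (`R/lp.R`): nonbasic variables rest on a finite bound,
phase 1 drives artificial variables out of the basis, pricing is Dantzig
with a Bland anti-cycling fallback after $10(n+m)$ iterations. Bounds
must be finite (models conventionally cap at $\pm 1000$ mmol/gDW/hr);
infinite bounds are replaced by $10^6$ and a solution resting on that cap
is reported `unbounded`. Tolerances: $10^{-9}$ on reduced costs,
$10^{-10}$ on pivots, $10^{-7}$ on phase-1 feasibility; post-hoc mass
balance is checked at $10^{-6}$. The solver is validated in the test
suite against brute-force vertex enumeration on random bounded polytopes
and on the analytic fixtures.

### Alternate optima

The growth-optimal vertex is degenerate in realistic networks, and
secretion-derived traits (purity, product rates) differ between optimal
vertices. By default a second LP fixes biomass at its optimum and
minimizes total absolute flux (`pfba = TRUE`), which selects a
reproducible, parsimonious flux state; `pfba = FALSE` returns the raw
simplex vertex for comparison with solvers that report their own
tie-break. Viability uses $\varepsilon = 10^{-6}\,\text{hr}^{-1}$ on the
growth objective; the threshold is configurable because "viable growth"
has no canonical numeric definition.

## Engineering traits

Each viable design yields a 36-trait vector: for each of the six target
products — acetate, D-lactate, hydrogen, ethanol, formate, succinate —
the production rate (mmol/gDW/hr), the purity (titer ratio: target
secretion over total secretion across the byproduct set), the carbon
yield (secreted carbon atoms over consumed carbon atoms) and the revenue
rate; plus twelve global traits (biomass production rate, biomass carbon
yield, total carbon yield, total carbon change, total economic cost rate,
total intake price, price change for all and for target compounds, profit
rate, expression consistency, total secretion rate, number of secreted
products). The registry is config-driven (`metric_registry()`), so an
alternative trait list can be substituted without touching the screen.

Choices that the trait definitions force:

* **Byproduct set.** Water, protons and biomass are never byproducts;
  CO2 is excluded by default (config flag) because the interesting
  denominators are the organic fermentation products. Purities over the
  byproduct set sum to 1 whenever anything is secreted; a design that
  secretes nothing reports purity 0 with a `zero_secretion` flag rather
  than 0/0.
* **Economic cost.** The cost of a consumed nutrient is
  `unit price ($/g) × MW (g/mol) × uptake (mmol/gDW/hr) / 1000`, i.e.
  $/hr/gDW; the total cost is the sum over consumed medium nutrients. A
  nutrient without a price makes the design's economic traits
  *unavailable* (`NA` with `economics_available = FALSE`), never zero —
  downstream economic analyses run on the priced subset only. Non-catalog
  consumed species (atmospheric CO2) are environmental, not purchased.
* **Price-change traits.** Computed as value of secreted minus value of
  consumed compounds per unit time, over all priced compounds and over
  the six targets respectively; profit is revenue minus cost, an exact
  accounting identity that the tests assert.
* **Purity of rates at the optimum.** All traits are pure functions of
  the stored flux solution, so phase-2 analyses re-read the phenotype
  matrix; nothing is ever re-solved.

### Expression consistency

The consistency score maps an expression profile onto reactions (AND =
min over complex members, OR = max over isozymes), penalizes each
below-cutoff reaction by $c_i = \max(0, \text{cutoff} - e_i)$, and solves
$\min \sum_i c_i |x_i|$ subject to steady state, the design bounds, and
biomass at least a functionality fraction (default 0.9) of its maximum.
The raw inconsistency $I$ is unbounded, so it is normalized to
$s = 1 - I/I_{\text{ref}}$, clipped to $[0,1]$, where $I_{\text{ref}}$
penalizes *every* reaction at the full cutoff weight under the same
functionality requirement — the worst-informed flux state that still
grows. The cutoff defaults to the profile's stated cutoff (fixtures use
0.5); both the normalization and the cutoff are documented config
choices, since a bounded consistency score admits more than one
normalization and expression data cannot arbitrate between them at toy
scale.

## Meta-phenotypes

Trait matrices are transformed to row-wise z-scores
$(y_i - \bar y)/\sigma$ (population $\sigma$; constant rows map to zero
and are flagged), then clustered with k-means using 10 random restarts
and up to 100 Lloyd iterations, keeping the restart minimizing the
within-cluster square error $E = \tfrac1n \sum_i \sum_{x \in C_i}
\lVert x - m_i \rVert^2$. Empty-cluster events trigger a fresh restart.
The number of clusters is chosen by the gap statistic against $B = 50$
uniform reference samples drawn over the per-feature range, with the
one-standard-error rule (smallest $k$ with
$\text{gap}(k) \ge \text{gap}(k{+}1) - s_{k+1}$) as default and the
global gap maximum behind a switch — the selection rule is genuinely
ambiguous in the literature, so both are exposed and the gap table is
attached to the result for inspection. Cluster heterogeneity is each
cluster's SSE normalized by the largest cluster SSE of the same fit, so
the loosest cluster scores exactly 1. Clustering defaults to the
*economic subset* (designs with fully priced media), mirroring how
economic analyses must be restricted; z-scoring is done jointly across
whatever rows are clustered. Trait–trait structure is summarized as a
Pearson correlation map with rows and columns ordered by average-linkage
hierarchical clustering on the $1 - |r|$ distance; zero-variance traits
are dropped and reported.

## Pareto analysis

On an enumerated finite design set the exact nondominated filter is both
cheaper and strictly more reliable than a genetic algorithm, so it is the
default: a design is kept iff no other design is at least as good in all
goals and better in one. The NSGA-II selector exists for very large point
sets: real-coded chromosomes over design indices, nondominated sorting,
crowding distance, binary tournament, simulated binary crossover
(distribution index 10, probability 0.85) and polynomial mutation (index
20, probability 0.05), population 100, 500 generations; the protocol's
fractional seed 0.6 is mapped to the integer seed `round(0.6 × 10^6)`
because fractional seeds are backend-specific. The initial population is
seeded with each goal's single-objective argmax, and every returned
design is membership-validated against the exact dominance check, so
NSGA-II output is always a subset of the true frontier.

Tradeoffs are least-squares slopes of one goal against another over
frontier segments. Breakpoints may be supplied (published frontiers often
pick them by inspection); otherwise a single automatic breakpoint is
chosen to maximize the residual improvement over one line, and the output
is labeled as automatic. Scalarized selection min-max normalizes each
goal over the candidate set before weighting — weights across units
($/hr vs mmol/gDW/hr) are meaningless otherwise — negates minimized
goals (a negative weight in a goal list is accepted as shorthand for
minimization), and breaks ties by design-key order, logged.

## Transition networks

For each perturbation type — carbon, electron acceptor, nitrogen,
phosphorus, sulfur source, single (SGD) and double (DGD) gene deletion —
every unordered pair of designs differing in exactly one component of
that type (all else fixed) is evaluated once; the pair increments the
typed edge between the two designs' clusters, with nonviable designs
mapped to node 0. Pair semantics for the genetic types: SGD pairs are
single-gene edits among genotypes with at most one deletion (wild type ↔
single, single ↔ single substitution); DGD pairs are single-gene edits
touching a double-deletion genotype (double ↔ double substitution,
single ↔ double addition). Unordered counting was chosen (each ordered
variant would double all counts and change no relative frequency).
Relative frequency normalizes each edge by its type's total pair count,
so edge weights are comparable within a type; cross-type comparison goes
through the perturbation influence summary (fraction of a type's pairs
that change cluster, normalized across types to sum to 1). Edges below
1% relative frequency are filtered for rendering, and the nonviable node
is kept in all counts but dropped on GraphML export, because it would
dwarf every viable node.

## Synthetic fixtures: what they emulate

`make_toy_model()` generates the study conditions for all offline
testing: a ~30-reaction carbon-balanced network with NADH and ATP
bookkeeping, so byproduct secretion is growth-coupled the way it is in
real fermentation — glycolysis produces pyruvate, NADH and ATP; anaerobic
growth must re-oxidize NADH through the ethanol or (CO2-consuming)
succinate branches and cover ATP demand through an acetate+formate
overflow reaction; respiration converts NADH to ATP aerobically. The
deliberate consequences, chosen once as the package's study conditions:

* wild-type anaerobic designs secrete an ethanol/succinate/overflow mix,
  ADH-deficient genotypes become succinate producers, and a
  melibiose-like disaccharide buys a higher carbon uptake at a purity
  cost (its hydrolysis branch co-releases acetate) — so the succinate
  rate-vs-purity frontier genuinely slopes downward;
* maximum theoretical yields are closed-form (per mole glucose: acetate,
  formate, hydrogen and D-lactate 2; ethanol and succinate 1,
  NADH-limited), giving exact oracles for `theoretical_extreme()`;
* glycerol is unpriced (exercising the missing-price path) and
  anaerobically unusable (its catabolism is too reduced), urea is a
  carbon-containing nitrogen source (exercising the catalog-overrides-
  element-rule path), and several deletions are conditionally lethal, so
  screens have a nontrivial nonviable fraction.

Default uptake bounds (glucose 10, disaccharide 8, glycerol 10, oxygen
20, others 100/50 mmol/gDW/hr) and prices are fixtures chosen to be
realistic in magnitude; they are inputs, not estimates. The default
screen (3 carbon × 2 EA × 2 N × 1 P × 1 S media × 121 genotypes = 1,452
designs) runs in about a minute; tests use smaller slices of the same
space.

What passing on fixtures does **not** show: genome-scale behavior
(thousands of reactions, alternate-optima degeneracy at much larger
scale, viable fractions near 10%), absolute trait magnitudes of real
organisms, or scientific validity of any particular price table.
Genome-scale models load through the same interfaces
(`load_model()` for the community JSON dialect and SBML/fbc), but runs
at the published scale — hundreds of millions of conditions — require
cluster resources and are outside the test envelope; the pipeline's
two-phase design (screen once, analyze many times) is what makes them
feasible.

## Known limitations

* The LP core is dense; genome-scale models solve but a sparse
  factorized simplex or an external solver would be preferable for
  million-design screens.
* Triple and higher-order deletions, regulatory (up/down-regulation)
  perturbations, flux variability analysis and thermodynamic constraints
  are out of scope.
* The bounded expression-consistency normalization is one of several
  defensible choices; scores are comparable within a run, not across
  normalizations.
* Condition totals reported for published genome-scale screens depend on
  catalog details (which nutrients per category, which genes) that are
  inputs here; `count_designs()` exposes the wild-type and anaerobic
  toggles so any published total can be reconciled against a known
  catalog.
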