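# fluxscape

Multi-goal metabolic engineering design over constraint-based metabolic
models.

Strain and medium design rarely optimizes a single quantity: a practical
fermentation design balances productivity, yield, purity and raw-material
cost, and those goals conflict. `fluxscape` explores that landscape
exhaustively. It enumerates every *design* — one nutrient per category
(carbon, electron acceptor, nitrogen, phosphorus, sulfur source) crossed
with every genotype of up to two gene deletions — solves a flux balance
analysis (FBA) problem for each, and turns the surviving (viable-growth)
designs into a table of engineering traits that downstream analyses query
without ever re-solving a linear program. It is written for systems- and
metabolic-engineering researchers who want a desk-scale, fully scriptable
version of cluster-scale design screens.

## The model

Each design is evaluated at steady state. With stoichiometric matrix
**A** (m metabolites × n reactions) and flux vector x,

```
max  f'x   subject to   A x = 0,   α_i ≤ x_i ≤ β_i
```

where f selects the biomass reaction Σ_i d_i z_i → biomass. The medium
enters through exchange-reaction lower bounds (uptake is a negative
exchange flux; a nutrient absent from the medium has α = 0), and a gene
deletion sets α = β = 0 for every reaction whose gene–protein–reaction
rule evaluates false (AND = enzyme complex, OR = isozymes). Because the
optimal vertex is degenerate in general, a second LP fixes the optimal
biomass and minimizes Σ|x_i|, making secretion-derived traits
reproducible (switchable via `pfba = FALSE`).

From each viable solution a 36-trait vector is computed: per product
(acetate, D-lactate, hydrogen, ethanol, formate, succinate) the production
rate (mmol/gDW/hr), purity (titer ratio: target secretion over total
byproduct secretion), carbon yield (fraction of consumed carbon atoms),
and revenue rate; plus global traits — biomass production rate, biomass
and total carbon yields, total carbon change, economic cost rate
(`unit price ($/g) × MW (g/mol) × uptake (mmol/gDW/hr) / 1000`), intake
price, price-change and profit rates, an expression-consistency (GIMME)
score, and aggregate secretion traits. Trait vectors are then z-scored and
clustered into *meta-phenotypes* (k-means, 10 seeds, ≤100 iterations, k
chosen by the gap statistic), screened for Pareto-optimal designs under
arbitrary goal combinations (exact nondominated filter, or NSGA-II for
very large sets), summarized as piecewise-linear tradeoff slopes, and
connected into a perturbation-typed meta-phenotype transition network
(edge `t_ij` counts single-component perturbations of a given type — C,
EA, N, P, S source, single or double gene deletion — that move a design
between clusters i and j).

A synthetic fixture generator (`make_toy_model()`) builds a small
carbon-balanced network with redox and energy bookkeeping whose maximum
theoretical yields are closed-form, so the entire pipeline is testable
offline; published genome-scale models in the community JSON dialect or
SBML (fbc) load through the same `load_model()` interface.

## Worked example

```r
library(fluxscape)

toy <- make_toy_model()
designs <- enumerate_designs(toy$catalog, central_genes(toy$model),
                             max_deletions = 1, ea_includes_none = TRUE)
nrow(designs)
#> [1] 192

ph <- screen_designs(designs, toy$model, toy$catalog, toy$prices)
attr(ph, "screen_summary")$viable
#> [1] 142

fit <- cluster_phenotypes(ph, k = 4, rng_seed = 1)
glance(fit)
#> # A tibble: 1 x 4
#>       k     n     E largest_cluster_share
#>   <dbl> <int> <dbl>                 <dbl>
#> 1     4   116  10.7                 0.431

goals <- goal_spec(c("succinate_production_rate", "succinate_purity"))
front <- pareto_front(ph[ph$economics_available, ], goals)
unique(front$frontier[, goals$metric])
#> # A tibble: 2 x 2
#>   succinate_production_rate succinate_purity
#>                       <dbl>            <dbl>
#> 1                      7.27            0.667
#> 2                      8.73            0.414
```

The 192 designs are 12 media (3 carbon sources × aerobic/anaerobic × 2
nitrogen sources) × 16 genotypes (wild type + 15 single deletions); 142
grow. Of the viable designs, 116 have fully priced media and enter the
economic subset; k-means groups them into 4 meta-phenotypes with a
dominant cluster holding 43% of designs. The succinate frontier has two
distinct optima: the glucose-fed ADH-deficient strain produces
7.27 mmol succinate/gDW/hr at purity 0.67, while the disaccharide-fed one
reaches 8.73 at purity 0.41 (its feedstock co-releases acetate) — the
purity–rate tradeoff in miniature.

A thin command-line wrapper lives at `inst/cli/fluxscape.R`
(`fixtures`, `run`, `screen`, `pareto`, `network` subcommands).

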