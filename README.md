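# forestplots

Diversity partitioning, community classification and carbon-stock
accounting for nested forest plot surveys.

## What it is for

Island forest gradients — natural forest, exotic woodland, conifer
production forest — are surveyed with nested designs: islands > forest
types > 10 × 10 m plots > four 5 × 5 m subplots. `forestplots` gives
ecologists working with such data one tested toolchain for the complete
analysis:

* **Taxonomic diversity** — richness, Shannon *H* (nats), Pielou
  evenness per plot, and the **additive partition of γ diversity**
  across the hierarchy: α_k is the mean richness at level *k*,
  β_k = α_{k+1} − α_k, β_L = γ − α_L, so γ = α₁ + Σβ exactly.
* **Community classification** — Hellinger distance
  (d(i,j) = ‖√(x_i/x_i·) − √(x_j/x_j·)‖), UPGMA clustering with
  cophenetic-correlation model selection, silhouette and Mantel
  cluster-number diagnostics, NMDS (Kruskal stress-1 with monotone
  regression), PERMANOVA with sequential sums of squares and free
  label permutations, and Dufrêne–Legendre IndVal
  (IndVal = 100·A·B, specificity × fidelity) with permutation tests.
* **Structural diversity** — branch-wise basal area
  (BA = Σ (d/100)²·π/4), stand density, BA-share Shannon indices,
  height summaries, all behind the DBH ≥ 2.5 cm retention rule.
* **Carbon stocks** (Mg C ha⁻¹) — allometric above-ground biomass via a
  pluggable equation registry, below-ground biomass from a root:shoot
  ratio, 0.48/0.51 broadleaf/conifer carbon fractions, litter carbon
  from dry mass × concentration, and soil organic carbon via the Van
  Bemmelen factor (C = 0.58 × OM) scaled by bulk density and measured
  sampling depth.
* **Group statistics** — two-way island × type ANOVA, Tukey HSD and
  compact letter displays behind every summary table.
* A **seeded synthetic survey generator** reproducing the 3 × 3 × 10
  design with realistic dominance structure, and `run_pipeline()`
  chaining everything into a reproducible, manifest-tracked run.

## Worked example

```r
library(forestplots)

# identities on stated partition means
partition_from_means(alpha = c(10.2, 13.9, 59.0), gamma = 108.0)
#> Additive diversity partition (3 levels)
#>   alpha: alpha_1=10.200  alpha_2=13.900  alpha_3=59.000
#>   beta:  beta_1=3.700  beta_2=45.100  beta_3=49.000
#>   gamma: 108.000
#>   percent of gamma: alpha_1=9.4%  beta_1=3.4%  beta_2=41.8%  beta_3=45.4%

# a full synthetic survey: 90 plots, 3 islands x 3 forest types
ds <- generate_survey(survey_config(seed = 1))
pc <- aggregate_to_plots(ds$cover, ds$design)

d  <- hellinger_distance(pc)
choose_k(upgma(d), d, k_max = 8)$k
#> [1] 3

g <- ds$design[!duplicated(ds$design$plot_id), c("forest_type", "island")]
permanova(d, g, n_perm = 999, seed = 1)
#> PERMANOVA (999 free permutations)
#>         term df     SS      MS pseudo_F      R2     p
#>  forest_type  2 40.505 20.2524   76.297 0.63178 0.001
#>       island  2  1.044  0.5222    1.967 0.01629 0.047
#>     Residual 85 22.563  0.2654       NA 0.35193    NA
#>        Total 89 64.112      NA       NA 1.00000    NA
```

The three community groups recovered by the dendrogram cut correspond
exactly to the three forest types, and forest type explains ~63 % of
compositional variance against ~2 % for island — the qualitative
signature the generator encodes. Carbon chains are exact unit
conversions: `litter_carbon(500, 400)` is 2.0 Mg ha⁻¹ and
`soil_carbon(100, 800, 0.10, carbon_parameters(root_shoot_ratio = 0.25))`
is 46.4 Mg ha⁻¹.

A thin CLI (`inst/cli/forestplots`) exposes `simulate`, `diversity`,
`partition`, `cluster`, `permanova`, `indval`, `structure`, `carbon` and
`run` subcommands over the same functions.

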