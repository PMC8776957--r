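---
title: "Methods: diversity partitioning, community classification and carbon stocks in nested forest surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity partitioning, community classification and carbon stocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestplots)
```

## The study system and the survey design

`forestplots` analyses vegetation surveys laid out as a nested hierarchy:
islands contain forest types, forest types contain plots, and each
10 × 10 m plot is divided into four 5 × 5 m subplots. The default design
is 3 islands × 3 forest types × 10 plots = 90 plots (360 subplots). The
three forest types carry distinct ecological identities: natural forest
(NF), species-rich and dominated by several endemic broadleaves; exotic
woodland (EW), dominated by a single invasive broadleaf; and production
forest (PF), a conifer plantation that is close to a monoculture but
stores the most carbon per tree.

Field data enter as long-format tables: subplot × taxon cover records,
per-tree branch diameters (DBH, cm) and heights (m), per-plot leaf-litter
samples (dry mass, carbon concentration) and soil samples (bulk density,
organic matter, depth). The package validates these on load
(`read_survey()`), runs every analysis stage, and writes plain CSV plus a
JSON manifest (`run_pipeline()`).

## The synthetic survey generator

Because no plot-level field data are distributed, the package ships a
seeded generator (`generate_survey()`) whose defaults *are* the study
conditions every downstream method assumes.

**Composition.** A taxon occupies a subplot with probability
$\operatorname{logit}^{-1}\!\big(\operatorname{logit}(p_0) + \tau\,s_T +
\iota\,s_I\big)$, where $p_0$ is the baseline occupancy (0.09), $s_T$ is
+1 in the taxon's home forest type and −1 elsewhere (±2 for dominants),
and $s_I$ is a fixed standard-normal taxon × island score. The effect
magnitudes default to $\tau = 1.75$ (forest type) and $\iota = 0.4$
(island), encoding the expectation that forest type structures
composition far more strongly than island. Cover conditional on presence
is log-normal on a percent scale (truncated at 100), with the dominants'
location raised by $1.25\,\tau$ in their home type; the per-type `sdlog`
(`dominance`) concentrates cover in fewer species in PF than in NF.
Cover is continuous rather than an ordinal scale: field protocols that
estimate cover visually do not fix a scale, and continuous values avoid
committing to any particular ordinal convention.

Setting $\tau = \iota = 0$ removes all group structure: plots become
exchangeable, which is what the type-I-error checks rely on.

**Trees, litter, soil.** Stem counts are Poisson with per-type means
(NF 33, EW 44, PF 21 per 100 m² plot, i.e. densities of the order of
2 000–4 500 ha⁻¹); branch DBH is log-normal, truncated below the 2.5 cm
measurement threshold, with PF much thicker (median ≈ 30 cm) than NF/EW
(≈ 9–10 cm); heights are normal with means 4.8 m (NF), 8.8 m (EW) and
22.7 m (PF), reproducing the low-canopy-natural / tall-plantation
ordering. Litter dry mass is log-normal around per-type means (350–780
g m⁻²) at ≈ 400 g C kg⁻¹; soil organic matter is log-normal around
per-island means (80–245 g kg⁻¹), bulk density ≈ 800 kg m⁻³, and the
sampled soil depth is uniform on 0.05–0.10 m — the depth window actually
used for stock scaling in this kind of survey.

**Seeding.** One root seed drives deterministic per-component sub-streams
(pool, occupancy, abundance, trees, litter, soil, NMDS, PERMANOVA,
IndVal), so adding a component never shifts another's draws, and equal
seed + config is bit-identical.

**What the generator does not emulate.** Spatial autocorrelation between
neighbouring plots, covariance between tree size and soil fertility,
observer error in cover estimation, and rare-species accumulation
beyond the fixed 108-taxon pool. Tests passing on synthetic surveys
demonstrate the correctness and calibration of the *methods*, not claims
about any particular real archipelago.

## Diversity indices and additive partitioning

Richness is the count of taxa with positive abundance; Shannon diversity
is $H = -\sum p_i \ln p_i$ (natural logarithm — the convention of the R
ecosystem this package interoperates with; stated in the output
metadata); evenness is Pielou's $J = H / \ln S$, defined as 0 when
$S = 1$ so the value always exists.

The additive partition decomposes total richness over the nested
hierarchy: $\alpha_k$ is the unweighted mean richness of level-$k$
groups (each group's richness computed on its pooled abundances),
$\beta_k = \alpha_{k+1} - \alpha_k$, $\beta_L = \gamma - \alpha_L$, so
$\gamma = \alpha_1 + \sum_k \beta_k$ *exactly* — this identity is
asserted to 10⁻⁹ in the tests. Means are unweighted because the design
is balanced; a size-weighted switch exists for user-supplied unbalanced
surveys. The default hierarchy is plot < island × type cell < forest
type < total; it is configuration, not hard-coded, because which level
counts as "level 1" is a survey-design decision (subplot-level
partitions are equally valid and the identities hold under either
reading). `partition_from_means()` applies the same identities to
externally stated level means, for checking published partition tables.

```{r partition}
partition_from_means(alpha = c(10.2, 13.9, 59.0), gamma = 108.0)
```

## Community classification

All community statistics operate on plot-level composition, defined as
the **sum** of the plot's four subplot covers (pooling before analysis is
the only aggregation that keeps richness consistent with the partition).

* **Hellinger distance** — Euclidean distance between rows transformed to
  $\sqrt{x_{ij}/x_{i\cdot}}$; bounded by $\sqrt 2$ and metric, which the
  tests verify on sampled triples.
* **UPGMA** — implemented directly from the agglomeration schedule with
  the unweighted-average update
  $d(k, i\!\cup\! j) = (n_i d_{ki} + n_j d_{kj})/(n_i+n_j)$; ties break
  to the earliest pair in index order. Merge heights are monotone and
  the induced cophenetic distances ultrametric.
* **Cophenetic correlation** — Pearson correlation between original and
  cophenetic distance vectors; the model-selection score across the
  distance × linkage candidate grid (`select_clustering()`), with ties
  resolved by candidate order. Constant distance vectors return `NA`
  rather than an error.
* **Cluster number** — the dendrogram is cut at each $k$; mean
  silhouette width selects $k$ (ties to the smaller $k$), and the Mantel
  correlation between the distance vector and the same/different-cluster
  indicator is reported as a diagnostic only, because no principled rule
  combines the two indices into one criterion.
* **NMDS** — direct minimisation of Kruskal stress-1 with monotone
  regression (primary tie treatment, PAVA via `stats::isoreg`) inside a
  quasi-Newton loop with an analytic gradient; 20 seeded random starts
  by default, best stress kept, and the returned stress never exceeds
  its own start's. Non-convergence is flagged, never thrown.
* **PERMANOVA** — Gower-centred inner-product partition of squared
  distances with sequential (entry-order) sums of squares, factor order
  (forest type, island) by default; free permutation of unit labels and
  the add-one estimator $p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})$,
  $n_{perm} = 999$ by default. The implementation is verified against an
  independent one (`vegan::adonis2`) and against exhaustive enumeration
  at $n = 4$.
* **IndVal** — single-group Dufrêne–Legendre form:
  $A_{tg}$ (specificity) is the share of the taxon's across-group mean
  abundances concentrated in $g$ — a within-species comparison that
  makes the statistic invariant to rescaling any one taxon —
  and $B_{tg}$ (fidelity) its occupancy in $g$;
  $\mathrm{IndVal} = 100\,A\,B$. The permutation statistic is each
  taxon's maximum-group IndVal; species with IndVal ≥ 70 % and
  $p < 0.05$ are flagged as characteristic. No multiplicity correction
  by default (per-species significance is the reporting convention);
  Holm is available behind a switch.

## Structural diversity

A tree is retained iff its *largest* branch DBH reaches 2.5 cm — the
measurement threshold read as an inclusion rule for multi-stemmed
individuals; once retained, *all* branches contribute
$\mathrm{BA} = \sum_b (d_b/100)^2 \pi/4$. Per-plot outputs: density
(trees ha⁻¹), basal area both per plot and per hectare (the two are
deliberately separate columns, since published tables are often
ambiguous about which is meant), the number of taxa contributing BA, the
Shannon/evenness indices on BA shares, and height mean/sd/max.

## Carbon accounting

Three pools, all in Mg C ha⁻¹:

* **Trees.** AGB (kg, dry) from an allometric registry: per-taxon
  entries with a closed set of forms (power law in D, power law in D²H,
  log-linear in ln D and ln H, linear in BA, linear in declared
  predictors including branch count), falling back to leaf-type generic
  entries. Multi-branch trees feed single-diameter forms through the
  quadratic-mean equivalent diameter $\sqrt{\sum d_b^2}$, which
  preserves total basal area. BGB is `root_shoot_ratio` × AGB; the ratio
  is mandatory configuration (the customary source is IPCC 2006 Table
  4.4, temperate oceanic class, ≈ 0.25, which the default pipeline
  uses). Carbon is 0.48 × biomass for broadleaves and 0.51 for conifers,
  applied to AGB + BGB by default: building total biomass first and
  converting once is the internally consistent reading of the standard
  protocol, and the AGB-only variant remains available behind
  `fraction_scope = "agb_only"` for sensitivity runs. The shipped
  registry (`inst/extdata/allometry_synthetic.yml`) is explicitly
  synthetic — plausible magnitudes for demonstration, not literature
  coefficients — and the engine is agnostic to the values.
* **Litter.** $C = \text{mass}\,(\mathrm{g\,m^{-2}}) \times
  \text{conc}\,(\mathrm{g\,C\,kg^{-1}}) \times 10^{-5}$.
* **Soil.** $C = \mathrm{OM} \times 10^{-3} \times 0.58 \times
  \mathrm{BD} \times \text{depth} \times 10$, with OM in g kg⁻¹, BD in
  kg m⁻³, depth in m. 0.58 is the Van Bemmelen factor (OM = 1.724 C).
  The *measured per-site depth* is used, not a nominal 30 cm: the stock
  is scaled over the depth actually sampled (0.05–0.10 m window).

Missing litter or soil samples yield `NA`, never a silent zero; per-plot
tree totals equal their per-taxon breakdowns to 10⁻⁹.

## Group comparisons

Every summary table is backed by the same machinery: two-way fixed
crossed ANOVA (classical sums of squares when balanced, Type II
otherwise — Type II needs no interaction-ordering assumption and reduces
to the classical decomposition when balanced), Tukey HSD on the
studentized range with pooled residual variance, and a compact letter
display from an insertion algorithm: start with one set holding all
groups, split every set containing a significantly different pair, then
absorb subsets. The letters satisfy *exactly* "share a letter ⇔ not
significantly different" (non-transitive patterns are expressed through
letter multiplicity); minimal letter count is not guaranteed. Letters
for the 9 island × type cells come from treating the cells as 9 groups;
main-effect comparisons are a separate output, since either comparison
family is defensible. Normality (Shapiro) and homogeneity
(Brown–Forsythe) diagnostics are attached but never gate computation.

## Numerical and testing choices

* Permutation p-values use the add-one estimator and can never fall
  below $1/(n_{perm}+1)$.
* Null-calibration simulations use 12-plot single-island surveys (3
  types × 4 plots): with only 2 plots per group the number of distinct
  label partitions (and hence the permutation resolution) is too coarse
  for any test to reject at $\alpha = 0.05$, so 4 plots per group is the
  smallest design in which calibration is observable. 500 simulations ×
  199 permutations give the rejection-rate check a Monte-Carlo standard
  error under 0.01.
* Property tests on generated surveys use 1-island, 2-plots-per-cell
  configurations with pools of ~20–40 taxa; the qualitative-recovery
  checks use the full default 90-plot design, and the variance-share
  comparison across 20 seeds uses 5 plots per cell. These sizes keep the
  whole suite within tens of seconds while leaving every assertion at
  full strength.
* NMDS initialises from seeded random configurations scaled to the mean
  input dissimilarity; coincident points are guarded with a 10⁻¹²
  distance floor in the gradient.
* Degenerate inputs have defined behaviour throughout: all-zero rows are
  errors in the Hellinger transform, empty plots yield zero diversity
  with a warning, constant distance vectors yield `NA` cophenetic/Mantel
  correlations, single-observation groups are excluded from Tukey with a
  warning.

## Known limitations

* Plots are treated as independent replicates; there is no mixed-model
  treatment of plots within islands.
* The distance registry is deliberately small (Hellinger, Bray–Curtis,
  Euclidean); no model-based or fuzzy clustering.
* No rarefaction or richness estimators; richness is observed richness.
* IndVal is the single-group form; site-group-combination variants are
  out of scope.
* Allometric coefficients are configuration; the package never refits
  them and ships only synthetic examples.
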