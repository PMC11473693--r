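# shadowdist

Species distribution models (SDMs) predict *where* a species can occur but
not *why* each place is suitable or unsuitable — and in human-dominated
landscapes the "why" matters: a species may be absent from a river reach
either because the reach lies outside its abiotic niche, or because the
niche is fine but barriers, channelization or urbanisation push suitability
down. `shadowdist` separates these two explanations. It is aimed at
macroecologists and conservation planners working with presence–absence
SDMs (the motivating system is riverine fish under multiple coincident
threats), and at anyone who needs observation-level, per-variable
explanations of SDM predictions.

## The method

For each species a class-balanced ("down-sampled") random forest is fitted
to presence–absence data: every tree trains on a bootstrap containing the
minority-class count of *both* classes, so the vote fraction
f(x<sub>i</sub>) is an index of relative occurrence ("environmental
suitability") rather than a prevalence-driven probability. Each site's
prediction is then decomposed into additive Shapley contributions
φ<sub>ij</sub> per environmental variable j, estimated with the
Štrumbelj–Kononenko Monte-Carlo permutation estimator and adjusted so that
efficiency holds exactly:

  f(x<sub>i</sub>) = ŷ + Σ<sub>j</sub> φ<sub>ij</sub>,

where ŷ is the mean prediction over a background sample. Variables are
partitioned into a natural abiotic set N (discharge, slope, temperature,
flow velocity, distance to lake) and an anthropogenic threat set A
(urbanisation, morphological modification, floodplain loss, wetland loss,
connectivity loss). From the attribution matrix:

* **Expected distribution** E: sites with Σ<sub>j∈N</sub> φ<sub>ij</sub> > 0
  — the footprint of the naturally realised abiotic niche, ignoring threats.
* **Binary shadow distribution**: sites in E where a chosen threat subset
  contributes negatively (Σ<sub>j∈A'</sub> φ<sub>ij</sub> < 0).
* **Quantitative shadow distribution**: the ratio
  clamp(y<sub>i</sub> / ŷ<sub>i</sub><sup>alleviated</sup>, 0, 1) of
  observed to threat-alleviated suitability inside E, where the alleviated
  expectation replaces each threat's contribution under a scenario:
  `q95_positive` (best case: the species-level 95th percentile of that
  threat's positive contributions), `mean_positive` (harmed sites recover
  to the mean positive contribution) or `zero_negative` (negative
  contributions merely zeroed).

A Shapley-free cross-check re-predicts suitability after setting threat
columns to their improved quantile (99th or 1st depending on the direction
of benefit). Multi-species results aggregate to per-site community
summaries (mean/min/SD shadow ratio, negative-threat counts) with sparse
sites masked. A seeded synthetic riverscape generator — dendritic network,
correlated longitudinal gradients, spatially autocorrelated threat fields
with a configurable elevation confound, barrier-driven connectivity, and
virtual species with *known* per-variable contributions — makes the whole
chain testable end to end.

## Worked example

```r
library(shadowdist)

# 1. a seeded riverscape with a virtual species whose truth is known
net <- generate_network(500, branching_prob = 0.3, seed = 1)
env <- generate_environment(net, seed = 2)
sp  <- response_spec(
  natural = list(discharge   = list(shape = "gaussian", mu = 0.5, sd = 1, height = 3),
                 temperature = list(shape = "linear", slope = 1.5),
                 velocity    = list(shape = "linear", slope = 1)),
  threats = list(urbanisation = list(shape = "linear", slope = -2),
                 connectivity = list(shape = "linear", slope = 1)),
  intercept = -0.8)
vs  <- generate_virtual_species(env, sp, seed = 3)
occ <- occurrence_table(vs, species = "spirlin_like")

# 2. class-balanced random forest + spatially blocked evaluation
model <- fit_downsampled_rf(env, occ, ntree = 500, seed = 4)
folds <- spatial_block_folds(net, block_size = 5000, k = 5, seed = 5)
evaluate_blocked_cv(env, occ, folds, ntree = 500, seed = 6)
#> Spatially blocked cross-validation ( 5 folds )
#> Pooled: AUC 0.855 | TSS 0.489 | MCC 0.515 | Brier 0.145

# 3. per-site, per-variable Shapley attribution
shap <- shap_table(model, env, n_reps = 200, seed = 7)
head(global_summaries(shap, env), 4)
#>      variable mean_abs_phi rho_raw_phi
#> 1   elevation   0.01459145  -0.5761881
#> 2   discharge   0.02070000   0.5004139
#> 3       slope   0.02408853   0.7255262
#> 4 temperature   0.01830145   0.6004128

# 4. expected and shadow distribution
quantitative_shadow(shap,
  natural_set = c("discharge", "slope", "temperature", "velocity", "distance_to_lake"),
  threat_set  = c("urbanisation", "morphological_modification", "floodplain",
                  "wetland", "connectivity"),
  scenario = "q95_positive")
#> Shadow distribution (scenario: q95_positive )
#> Sites: 500 | expected distribution: 297 (59%)
#> Mean observed/expected suitability in E: 0.843 / 1.141 | mean ratio: 0.741
```

Reading the output: out-of-fold AUC 0.855 says the blocked model carries
real transferable signal; `rho_raw_phi` gives each variable's overall
response direction (positive for the gradients the species prefers,
negative for harmful threats); 59% of sites fall inside the abiotic niche;
and inside that niche the observed suitability averages 74% of what the
best-case threat-alleviation scenario would allow — the remaining 26% is
the species' shadow distribution.

A command-line wrapper over the same functions ships in
`inst/cli/shadowdist.R` with subcommands `simulate`, `preprocess`, `fit`,
`cv`, `explain`, `shadow`, `community` and `report`
(`Rscript inst/cli/shadowdist.R --help`).

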