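---
title: "Shadow distributions: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shadow distributions: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shadowdist)
```

## The problem

A presence–absence species distribution model collapses many coincident
environmental gradients into one suitability score per site. In riverscapes
this is particularly unsatisfying: natural gradients (discharge,
temperature, slope, velocity, distance to a lake) and anthropogenic threats
(urbanisation, channel modification, floodplain and wetland loss, barrier-
driven connectivity loss) run along the same dendritic network, so a low
score never says *which* factor is limiting, nor whether the limitation is
natural or human-made. `shadowdist` answers that question at the
observation level: every prediction is split into additive per-variable
contributions, and those contributions are partitioned into the natural
niche signal and the threat signal.

## Model and attribution

**Occurrence model.** A down-sampled random forest: each of `ntree` trees
is grown on a within-class bootstrap of size equal to the minority class
for *both* classes, so strongly imbalanced data do not push the forest
towards the majority class. Predictions are vote fractions in [0, 1] and
are interpreted as relative suitability, not calibrated probability of
occurrence; no probability calibration is attempted, and no hyperparameter
tuning is done beyond the conventional defaults (`ntree = 1000`,
`mtry = floor(sqrt(p))`), because random-forest SDMs are known to be
insensitive to tuning and a fixed recipe keeps the attribution target
stable.

**Attribution.** Shapley values with an interventional value function:
the worth of a coalition S at instance x is the mean prediction over
background rows with the variables in S set to x. `shapley_exact()`
enumerates all 2^p coalitions (capped at p = 12) and is the test oracle;
`shapley_mc()` is the production estimator — per repetition it draws one
variable permutation and one background row, walks the permutation
flipping variables from background to instance values, and credits each
variable with the prediction change at its own flip. One permutation
serves all p variables (the prefix rule), which reuses p + 1 model calls
per repetition and reduces variance relative to independent per-variable
draws.

Because a finite Monte-Carlo run does not satisfy efficiency exactly, the
residual r = (f(x) − ŷ) − Σφ is spread equally over the p variables.
Equal spreading preserves symmetry (exchangeable variables stay
exchangeable) at the cost of leaking |r|/p into dummy variables; since
|r| is of the order of one Monte-Carlo standard error, the leak is within
estimation noise, and the package's dummy-axiom test checks exactly that.
After adjustment, ŷ + Σφ reproduces the model prediction to better than
1e−9 at every site (floating-point only), which downstream shadow algebra
relies on.

The baseline ŷ is the mean prediction over the background set; the
background defaults to the full table being explained, subsampled
(seeded) to 1000 rows when larger. Each explained site draws from its own
random sub-stream keyed to the site's rank among the table's ids, so the
attribution table is invariant to the order in which sites are processed
and can be chunked freely.

**Estimator settings.** `n_reps = 10000` per site is the production
default; the Monte-Carlo standard error shrinks as 1/sqrt(n_reps) (a
property test verifies the rate), so a few hundred repetitions already
fix the *sign* and rough magnitude of contributions, which is what the
shadow partition consumes. Tests and the acceptance script therefore use
150–250 repetitions on subsamples of a few hundred sites; the reported
checks (sign recovery, rank correlations, set membership) are robust at
that precision, while exact per-site magnitudes at publication quality
warrant the full default.

## The shadow partition

With N the natural set and A the threat set:

* **Expected distribution**: E_i ⇔ Σ_{j∈N} φ_ij > 0, strictly. A sum of
  exactly zero provides no positive natural support, so ties fall outside;
  this matters only for degenerate hand-built tables, as continuous
  attributions are almost never exactly zero.
* **Threat alleviation**: the expected suitability is
  ŷ + Σ_{j∉A} φ_ij + Σ_{j∈A} s_j(i). Variables outside both N and A (the
  generator's `elevation`, for instance, which serves as a confounder
  rather than a niche axis) keep their own attribution: the expectation
  differs from the observation only through threat alleviation, which also
  makes "no negative threat contribution ⇒ expectation = observation" an
  identity under the `zero_negative` scenario.
* **Scenarios.** `zero_negative` sets s_j = max(φ_ij, 0);
  `mean_positive` lets harmed sites recover to the species-level mean of
  that threat's positive contributions; `q95_positive` — the headline,
  best-case scenario — replaces *every* site's threat contribution with
  the species-level 95th percentile of its positive contributions (the
  95th rather than the maximum, to be robust to spuriously large
  values). Replacement quantities are computed over all sites, not just
  E-sites. A threat with no positive contribution anywhere gets
  replacement 0, with a message.
* **Quantitative shadow**: ratio_i = clamp(y_i / expected_i, 0, 1) inside
  E, where y_i = ŷ + Σ_j φ_ij. The clamp is applied to the final ratio
  only. Under full q95 replacement a site whose own positive threat
  contribution exceeds the 95th percentile has expected < observed; the
  clamp maps such sites to exactly 1. The same mechanism means the
  per-site ordering "expected(mean_positive) ≤ expected(q95_positive)"
  holds wherever positive contributions sit below their 95th percentile —
  i.e. at all but roughly the top few percent of sites — whereas
  "expected(zero_negative) ≤ expected(mean_positive)" is a strict
  identity at every site. This is an inherent property of a best-case
  scenario defined by a quantile: an alternative design (replacing only
  negative contributions) would restore per-site monotonicity but would no
  longer represent "every site at its near-optimal condition", and would
  make the clamp vacuous; the package deliberately keeps the quantile
  semantics.
* **Degenerate expectations.** expected_i ≤ 0 is possible when a non-N
  context variable is strongly negative at an E-site; the ratio is then
  reported as `NA` (with a message) rather than clamped, since a
  non-positive expectation has no meaningful "fraction retained".

**The Shapley-free cross-check.** `feature_adjustment_expected()` sets
each threat column to its improved state — the 99th percentile of observed
values when high is good (connectivity), the 1st percentile when low is
good (urbanisation, channel modification) — and simply re-predicts. The
rank correlation between the resulting observed/expected ratio and the
scenario-based ratio is the package's main external-consistency check; on
synthetic species it is strongly positive (roughly 0.3–0.8 depending on
the species and estimator precision).

## Evaluation

Spatially blocked 5-fold cross-validation: square tiles (default edge
10 km, the typical autocorrelation scale of riverscape covariates) are
shuffled and dealt round-robin to folds, so spatially proximate sites
never straddle a train/test split. Binary metrics are computed at the
threshold that maximizes TSS on the *training* predictions of each
iteration (ties towards the lowest threshold); AUC and the Brier score are
threshold-free. Ten metrics are reported (AUC, sensitivity, specificity,
TSS, MCC, Cohen's kappa, accuracy, F1, Brier, threshold). Folds whose
training portion lacks a class are skipped with a warning; pooled rows
combine out-of-fold predictions, with binary metrics built from the
per-fold thresholded predictions.

## Preprocessing

* **Collinearity audit**: pairwise Spearman correlations (average ranks on
  ties), summarised by the median and 95th percentile of off-diagonal
  absolute values; constant columns are excluded as undefined rather than
  zero-filled, because a zero would understate the summaries.
* **Residualization**: threats that track natural gradients for incidental
  reasons are replaced by their residuals from a penalized additive model
  on the confounders (cubic regression splines, basis size 10 per
  confounder, smoothness by GCV — standard additive-model defaults, since
  only the residual behaviour is identifiable). Confounders that are
  constant or nearly so are dropped with a warning; the residualized flag
  is recorded in the table's metadata.
* **Variable selection**: a shadow-feature competition. Each run appends a
  permuted copy of every active variable, fits the down-sampled forest
  with permutation importance (Z-score-scaled), and scores a hit when a
  real variable beats the best shadow. Two-sided binomial tests at
  `alpha = 0.01` with Bonferroni correction promote or demote variables;
  rejected variables leave the competition; `max_runs = 100`. With a
  single run no decision can reach significance, so everything remains
  tentative — by design, not by accident.

## The synthetic riverscape

The generator emulates the features of real river monitoring data that the
method must cope with: a dendritic network grown by seeded upstream
attachment (binary confluences, meandering planar coordinates in meters,
strictly increasing elevation with channels steepening at altitude);
discharge growing with drainage area; temperature falling with elevation
(lapse 0.0065 °C/m, noise 0.4 °C); velocity rising with slope; spatially
autocorrelated threat fields built by Gaussian-kernel smoothing of white
noise (default range 10 km, matching the blocked-CV scale); and
connectivity decaying with the number of random barriers on the path to
the outlet. Threat fields are first projected orthogonal to elevation (on
both the raw and the rank scale) and then remixed with it at a
configurable weight, so the elevation confound is an exact dial: weight 0
yields essentially zero realized rank correlation in the sample, not just
in expectation, and weight w yields rank correlation ≈ w. Virtual species
evaluate linear, Gaussian or threshold responses on z-scored variables;
contributions are centered over sites (grand means fold into the
intercept), suitability is the inverse logit of their sum, and presences
are Bernoulli draws. Because the per-variable contributions are stored,
`ground_truth_shadow()` can apply the same expected/shadow algebra to the
truth (on the log-odds scale, mapped through the inverse logit) and serve
as a recovery target.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: biased and spatially clumped survey
effort, imperfect detection, species interactions, temporal non-
stationarity of threats, measurement error in the covariates, and
hydrological realism (the connectivity index is a stand-in for a
colonisation-probability model, not a calibrated one). Recovery results on
virtual species bound what the estimator can do when its assumptions hold;
they do not certify causal threat attribution in the field, and correlated
covariates still blur attributions even after residualization.

## Numerical conventions and problem sizes

All randomness flows from explicit integer seeds; sub-streams use fixed
offsets per component, so changing one component's noise leaves the others
untouched. Efficiency is enforced to machine precision; algebra fixtures
are asserted at 1e−12; quantile type 7 (R's default) is used everywhere a
quantile appears. The test suite runs riverscapes of 300–1000 sites with
150–250 Monte-Carlo repetitions on subsamples of 250–300 sites, 20-seed
replicate loops for recovery claims, and forests of 60–500 trees — sizes
chosen so the full suite completes in a few minutes on a laptop while
leaving every claim statistically comfortable; the acceptance script uses
an 800-site riverscape, three virtual species, 500-tree forests and 150
repetitions over 400 explained sites for the same reason. Community
summaries mask sites with too few species inside their expected
distributions (default: more than two required) and exclude masked sites
from association statistics; species outside E at a site are excluded
from that site's ratio statistics, never imputed, and both E-only and
all-species suitability means are emitted because either convention is
defensible.

## Known limitations

Attribution quality is bounded by model quality: a forest with weak
blocked-CV skill yields attributions (and hence shadow estimates) that
mostly reflect noise, and the package deliberately reports CV skill next
to every downstream product. Shapley values on correlated covariates split
credit between proxies; the audit/residualization step reduces but cannot
eliminate this. The best-case scenario is a hypothetical, not a
restoration forecast; and binary presence–absence undersells continuous
population responses, so suitability losses are, if anything,
underestimated.
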