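---
title: "Maximum-entropy habitat suitability modelling with sdmax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-entropy habitat suitability modelling with sdmax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmax)
```

## The model

`sdmax` estimates habitat suitability from presence-only records and
gridded environmental covariates. The core is a maximum-entropy
(Gibbs) density over landscape cells: with features $f(x)$ derived from
the environmental variables at cell $x$, the model is

$$ q_\lambda(x) = \frac{\exp(\lambda \cdot f(x))}{Z(\lambda)}, \qquad
   Z(\lambda) = \sum_{x \in \text{background}} \exp(\lambda \cdot f(x)), $$

fitted by minimizing the L1-regularized negative mean presence
log-likelihood

$$ J(\lambda) = -\frac{1}{m}\sum_{i=1}^{m} \lambda \cdot f(x_i)
   + \log Z(\lambda) + \sum_j \beta_j |\lambda_j| . $$

This is the standard presence/background formulation: there are no true
absences, so the model contrasts the $m$ presence cells with a
background sample of the landscape (presence cells included, the usual
convention). The objective is convex; any stationary point is the global
optimum.

Features come in five classes, all computed on variables scaled to
$[0,1]$ by their background minimum and maximum:

* **L** (linear) — the scaled value;
* **Q** (quadratic) — its square, giving unimodal responses;
* **P** (product) — all pairwise products, giving interactions;
* **T** (threshold) — step indicators $1\{v > k\}$ at 10 equally spaced
  knots per variable;
* **H** (hinge) — forward ramps $\max(0, (v-k)/(1-k))$ and reverse ramps
  $\max(0, (k-v)/k)$ at 10 knots each per variable.

The per-feature penalty is $\beta_j = \mathrm{rm} \cdot
\beta_{\text{class}}(m) \cdot s_j$, where $s_j$ is the feature's
background standard deviation, `rm` is the global regularization
multiplier, and $\beta_{\text{class}}$ interpolates
$\{10 \mapsto 1.0,\; 30 \mapsto 0.6,\; 100 \mapsto 0.5\}$ on the
presence count for linear/quadratic/product features, with constants 1.0
(threshold) and 0.5 (hinge). The table is a package default and is
configurable through the `beta_class` argument of `maxent_fit()`; knot
counts are likewise arguments. Knot placement is fixed and equally
spaced rather than data-driven, which bounds the design width at desk
scale.

Two output scales are available from `maxent_predict()`: `raw`, the
density $q_\lambda$ itself (sums to 1 over the training background), and
`cloglog`, $1 - \exp(-e^{H} q_\lambda(x))$ with $H$ the entropy of the
fitted density. The cloglog scale is the conventional 0–1 suitability
surface; under the null (uniform) model it equals $1 - e^{-1} \approx
0.632$ everywhere, a closed form the tests assert. During projection to
other scenarios, variables outside the training range are **clamped** to
it rather than extrapolated.

```{r tiny-fit}
fx <- make_toy_fixture()
occ <- thin_per_cell(fx$occ, fx$stack$layers[[1]])
bg <- background_sample(fx$stack$layers[[1]])
fit <- maxent_fit(build_features(fx$stack, occ, bg, "LQ"), rm = 1)
fit
```

## Model and variable selection

Candidate models form a grid over the regularization multiplier and the
feature combination (`candidate_grid()`), each scored by the
small-sample AIC: scores are renormalized to sum to 1 over all valid
cells, the log-likelihood is summed at presence cells, $k$ counts
nonzero weights ($|\lambda_j| > 10^{-8}$), and

$$ \mathrm{AICc} = 2k - 2\ell + \frac{2k(k+1)}{n-k-1}, $$

undefined (candidate flagged invalid) when $n \le k+1$. The best
candidate has $\Delta\mathrm{AICc} = 0$; ties break by smaller $k$, then
smaller rm, then lexicographic feature combination. The published design
this mirrors spans 40 multiplier values in $[0.1, 40]$ by 29 feature
combinations (1160 candidates); since only the count and range of the
multiplier grid are stated, the package default `default_rm_grid()` uses
40 log-spaced values, and the combination list defaults to all 31
non-empty subsets of $\{L,Q,P,T,H\}$ with duplicates removed — both
configurable.

Variable selection runs in two stages (`collinearity_filter()`): drop
variables with percent contribution $\le 0$, then scan variable pairs in
descending $|r|$ (Pearson correlation at the occurrence cells) and, for
each pair with $|r| > 0.85$ where both members survive, drop the
lower-contribution member. Processing pairs in descending $|r|$ resolves
transitive chains deterministically; contribution ties keep the
alphabetically first variable. The result never contains a retained pair
above the threshold — a property the tests assert on a thousand random
instances. Because the correlation is evaluated at occurrence cells
only, range restriction can pull a pair that is strongly correlated
across the landscape below the threshold at the presences; this mirrors
the published procedure, which computed the coefficients at the
occurrence records.

Percent contribution itself is **permutation importance**: the drop in
training gain when one variable's raw values are permuted jointly across
presence and background rows (all derived features recomputed), averaged
over 5 seeded permutations, truncated at zero and normalized to 100.
The original software reports a solver-path-dependent accounting that is
not reproducible with a batch convex solver; permutation importance is
the standard order-independent substitute and is documented as such.
Jackknife importance (`jackknife_gain()`) refits with only / without
each variable and reports the training gains.

## Thresholding, zoning and areas

The continuous surface is binarized at the score maximizing sensitivity
plus specificity (`max_sss_threshold()`), with the background standing
in as pseudo-absence for specificity — the presence-only setting has no
negative class. Candidate thresholds are exactly the observed score
values, so a brute-force scan reproduces the result with no resolution
parameter; ties take the smallest threshold. Four classes follow:
unsuitable $[0, P)$, poor $[P, 0.33)$, moderate $[0.33, 0.66)$ and most
suitable $[0.66, 1]$. If $P \ge 0.33$ the poor class is structurally
empty and a message says so.

Cell areas use spherical geometry on the authalic radius
$R = 6371.0088$ km: a cell in latitude band $[\varphi_s, \varphi_n]$ has
area $R^2 \Delta\lambda (\sin\varphi_n - \sin\varphi_s)$, constant
within a row. Area reports give per-class areas in $10^4$ km², shares of
the total suitable area, and percent changes against a baseline report;
printed-style values round half-away-from-zero to 2 decimals with a
trailing zero dropped, matching the convention of the published tables
the worked examples reproduce.

```{r areas}
cur <- report_from_areas(poor = 103.13, moderate = 51.96, most = 22.27)
cur
```

## Change analytics

For each future scenario against current, `overlay_change()` classifies
every cell as stable (suitable in both), expand (future only), shrink
(current only) or never; the conservation identities
stable + shrink = current-suitable and stable + expand = future-suitable
hold exactly by construction. `change_proportions()` reports stable and
shrink relative to the current suitable area and expand relative to the
future suitable area (the conventional denominators).
`class_transition()` gives the full 4×4 area matrix whose marginals are
the two maps' class areas.

The centroid of the most suitable class is the **area-weighted** mean of
cell-center coordinates — published workflows typically say only
"centroid", and area weighting is standard zonal-centroid practice;
suitability weighting would be an alternative and the target class is an
argument.
Displacements between successive centroids use the haversine distance on
the same sphere (the projection used by the original GIS workflow is
unstated, so distances are validated against this package's own oracle
and an independent geodesic library, not against the published
kilometre figures, which are not reproducible from the published
2-decimal coordinates) and the initial great-circle bearing, mapped to
8 compass sectors of 45°.

One ambiguity the package resolves explicitly: whether the
suitability threshold is re-estimated per future scenario or reused from
the current climate is unstated in the source procedure. The pipeline
default estimates $P$ once on the current scenario and reuses it, which
keeps class definitions comparable across scenarios; `run_config()`
accepts a fixed numeric threshold instead.

## The synthetic study system

Because the original occurrence compilation and climate downloads are
not redistributable, the package generates study systems with known
truth. `make_env_stack()` builds each layer as Gaussian white noise
smoothed by an isotropic Gaussian kernel (reflection boundary) to a
stated autocorrelation length, standardized over valid cells. Requested
cross-layer correlations are achieved *exactly*: the smoothed fields are
empirically orthogonalized (QR) before mixing with the Cholesky factor
of the target correlation matrix — plain mixing would inherit the
residual sample correlation that smoothing leaves between independent
fields (roughly $\pm 0.1$ on a 50×50 grid at autocorrelation length 5).
A non-positive-definite target is an error. Optional deterministic
spatial trends per layer support constructions where the niche must move
in a known compass direction.

The generating niche is linear
($s(x) = \sum_v w_v\, v(x)$ on the log-density scale) or unimodal
($g(v) = -(v - \text{opt})^2$); `true_suitability()` returns the
normalized density, `sample_occurrences()` draws presence cells from it
with replacement and places records at cell centers so thinning and
extraction are exactly reproducible. Future stacks add stated offsets to
named layers ("warming"), leaving geometry and the nodata mask intact.

The default conditions (`default_truth()`) mirror the real study at desk
scale: a 100×100 grid, 8 layers with two collinear pairs at $r = 0.9$
(above the 0.85 filter threshold), one strong linear driver (weight 3 on
env1) plus two weak ones (0.8 on env2 — deliberately also the collinear
partner of env1 — and 0.5 on env5), and 123 presences after per-cell
thinning. With these weights the presence/background contrast is strong
enough that replicated test AUC lands in the 0.9–1.0 "excellent" band,
comparable to the published evaluation; the weak effects give the
variable-selection stage something real to arbitrate.

What the generator does **not** emulate: actual bioclimatic variable
semantics (bio1–bio19), soil or human-footprint layers, spatially biased
sampling effort, and observation error in coordinates. Passing tests
therefore demonstrate that the machinery recovers known structure under
clean conditions, not that any particular real-world map is correct.

```{r synthetic, eval = FALSE}
d <- default_truth()
stack <- make_env_stack(d$n_layers, d$template, d$truth, seed = 1)
occ <- sample_presences_thinned(true_suitability(stack, d$truth),
                                d$template, d$n_presences, seed = 2)
cfg <- run_config(fc = "LQ", rm = 0.5, seed = 3)
bundle <- run_pipeline(cfg, list(current = stack), occ)
```

## Numerical choices

* **Solver**: proximal gradient descent (soft-threshold steps) with
  backtracking line search and step growth; monotone in the objective by
  construction. Convergence at relative objective change $< 10^{-6}$,
  cap 5000 iterations; hitting the cap is an error carrying the
  objective trace. $\lambda$ starts at 0. On instances small enough to
  enumerate, the objective matches an independent smooth reformulation
  ($\lambda = a - b$, $a, b \ge 0$) solved by L-BFGS-B to $10^{-4}$.
* **Background**: all valid cells when at most 10,000, otherwise a
  seeded uniform sample of 10,000.
* **Degenerate inputs**: variables constant over the background are
  excluded from the expansion with a warning; features constant over the
  background are pinned at $\lambda_j = 0$; an all-identical score
  vector makes the threshold degenerate (returned with a warning);
  zero-variance variables at occurrences get $r = 0$ in the Pearson
  matrix, flagged.
* **Tie-breaks**: thinning keeps the first record per cell in input
  order (the original duplicate-resolution rule is undocumented);
  maxSSS ties take the smallest threshold; selection ties break by
  $k$, then rm, then feature combination; point-in-cell assignment uses
  half-open intervals $[w, e) \times [s, n)$ so the tiling is exact.
* **Determinism**: every stochastic step (background sampling,
  replicate splits, permutations, synthetic fields) takes a seed, and
  child seeds are derived from one master seed; the pipeline is a pure
  function of (config, inputs, seed), which the tests assert via
  byte-identical manifests.

## Problem sizes and limitations

The test suite and the reproduction script run the synthetic system at
100×100 cells with 123 presences and a 10,000-cell background, 10
evaluation replicates, and oracle comparisons on instances up to a few
hundred scores or 20 background cells — sizes chosen so every check runs
in seconds while remaining structurally faithful to the study design.

Known limitations: no categorical variables; no cumulative output or
novel-climate (MESS-style) diagnostics; no projected-CRS area
computation (areas are spherical); hinge/threshold knots are fixed
rather than data-driven; and the percent-contribution accounting is
permutation-based rather than path-based, as discussed above.
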