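---
title: "Methods: mobility-network disruption and socioeconomic segregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mobility-network disruption and socioeconomic segregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the tunable parameters, and the numerical
and design choices behind `mobflow`. The package quantifies how a mobility
restriction disrupts a territory-level human-mobility network and asks whether
the most and least disrupted territories differ systematically in their
pre-existing socioeconomic structure.

## The mobility network and its efficiency

Raw inputs are origin–destination records: counts of people moving between
map tiles in 8-hour bins. Tiles are mapped to territorial units — local labour
markets (LLMs), sub-regional areas in which people live and work — and records
are aggregated over consecutive, non-overlapping 14-day windows (half-open:
window $k$ covers $[\mathrm{start}+14k,\ \mathrm{start}+14(k+1))$ days). Each
window yields a weighted undirected network: nodes are LLMs, an edge weight
$w_{ij}$ is the total number of travellers between $i$ and $j$ in the window
(both directions summed), and within-LLM flows are discarded. The node set is
held fixed across windows so per-window quantities are comparable; a node with
no flow is an isolate with zero centralities.

Because many travellers make two places "close", distances for the efficiency
measure are the reciprocals $d^{(1)}_{ij} = 1/w_{ij}$ and $d_{ij}$ is the
shortest-path distance over those edge lengths ($d_{ij}=+\infty$, contributing
$1/d_{ij}=0$, for disconnected pairs). The global efficiency and each node's
contribution to it are

$$E_{glob} = \frac{1}{n(n-1)}\sum_{i \ne j} \frac{1}{d_{ij}}, \qquad
  e_i = \frac{1}{n-1}\sum_{j \ne i} \frac{1}{d_{ij}},$$

so $\mathrm{mean}_i(e_i) = E_{glob}$ holds as an algebraic identity (asserted
in the tests). Normalization divides by the efficiency of an ideal complete
graph in which every pair sits at the smallest observed distance
$w_{\min} = 1/\max_{ij} w_{ij}$, giving $E_{norm} = E_{glob}\,w_{\min} \in
[0,1]$ and $e^{norm}_i = e_i\,w_{\min}$, with $E_{norm}=1$ exactly for an
equal-weight complete graph. $w_{\min}$ is recomputed per window, so the
normalized quantity measures topology relative to the window's strongest
link; this is deliberate, and both raw and normalized variants are stored so
either can drive the downstream indicators (`efficiency_variant` in
`run_config()`, default `"norm"`; ranks across territories within a window,
and hence the extracted classes, are identical under the two variants because
$w_{\min}$ is a common factor).

Shortest paths are computed by Dijkstra's algorithm (via `igraph`); the tests
validate the results against an independent exhaustive path-enumeration
oracle on small graphs to $10^{-12}$ relative error. An edgeless window is a
degenerate case reported as zero efficiency with a warning rather than an
error, since a disruption analysis must tolerate an empty window.

## Disruption indicators and affectedness classes

For each territory, the disruption trajectory is the relative variation of
nodal efficiency against a pre-disruption baseline window $t_0$:
$\Delta e_i^t = (e_{i,t} - e_{i,t_0})/e_{i,t_0}$. Values are kept as raw
ratios internally and multiplied by 100 only for display. Territories with
zero baseline efficiency cannot be normalized and are masked out (logged,
never imputed).

Two scalar indicators summarize the two phases, each the mean of
$\Delta e$ over the first two windows of its phase: the *lockdown* indicator
over windows $t_L, t_L+1$ and the *recovery* indicator over $t_R, t_R+1$. On
the default grid anchored at 2020-02-24 the lockdown begins in window 1
(9/3–22/3) and is lifted in window 5 (4/5–17/5), so `t_L = 1`, `t_R = 5`.
The *most* and *least* affected classes are the bottom and top $K\%$ of an
indicator's distribution (sizes `round(K/100 * N)`), the remainder is "rest";
ties are broken deterministically by (value, territory id) so runs are
reproducible. Class trajectories are summarized by cross-sectional means with
a normal-approximation 95% band (`mean ± 1.96 SE`); a bootstrap band was
considered and rejected as the default because the cross-sections are large
(dozens of territories) and the band is descriptive, not inferential.

## The synthetic scenario generator

The real inputs (proprietary social-network mobility flows; municipal income
and registry tables) cannot be redistributed, so the generator produces
statistically analogous stand-ins; it is first-class, tested code, and its
defaults *are* the study conditions of the package's validation suite:

* **Geography.** 200 LLMs uniformly on a $100\times100$ planar grid, each
  owning 1–3 abstract tiles and 2–5 municipalities; five contiguous
  macroarea strips along the south–north axis; 20 provinces as contiguous
  blocks of territories. A municipality belongs to its block's province with
  probability 0.6 and to a neighbouring province otherwise — labour markets
  genuinely straddle administrative boundaries, which is what makes the
  province-to-LLM bridging step non-trivial (and keeps the regression's
  area-by-sector interaction columns from being collinear).
* **Baseline flows.** A gravity rule
  $B_{ij} = s\,p_i p_j / d_{ij}^{\gamma}$ with $\gamma = 2$, scale $s = 5$,
  populations lognormal around 30k; rounded to integers. Window $w$'s
  directed flow out of a territory of class $c$ is
  $\mathrm{round}(B_{ij}\, m_c(w)\, \varepsilon)$ with multiplicative
  lognormal noise $\varepsilon$ (mean 1, $\sigma$ = `noise_sd` = 0.05,
  chosen multiplicative for nonnegativity). Flows below the privacy floor
  (default 10, mirroring the suppression of small flows in privacy-preserving
  mobility data; applied at the window level before the bin split) are
  dropped. The window flow is then split exactly over 42 eight-hour bins
  (largest-remainder scheme), so aggregation has real work to do and
  noise-free identities hold exactly.
* **Recovery shapes.** The class multipliers $m_c(w)$ (with $m_c(0)=1$) are
  free parameters of the generator, not estimates of any real curve: the
  least affected class dips to 0.85 and is back at 1 by window 5 (V shape),
  the most affected class drops to 0.45 and climbs slowly to 0.90 (U shape),
  the rest sits midway. The 0.40 multiplier gap in the lockdown windows is
  the separation the indicator analysis is designed to detect.
* **Covariates.** Configured effect sizes (`covariate_effects`, defaults:
  income per capita $+1.5$ SD, inequality $-1.0$ SD, least minus most, in
  within-class SD units) are realized *exactly*: a latent development factor
  $g$ carries part of the shift and a direct class term pins the remainder.
  The latent factor also loads on density (0.7), the sectoral employment mix
  (tilting richer territories towards remote-intensive sectors), and
  province-level productivity (0.5 on revenue per employee), emulating the
  strong covariance between income and economic structure that real
  territorial data display. Classes are assigned along the south–north axis
  with near-contiguous bands, and the strength of that spatial clustering is
  itself proportional to the configured income effect: in a null
  configuration (all effects 0) classes are assigned completely at random.
  This last rule matters for validity: with spatially banded classes and
  province-level covariates, a classifier can memorize *which provinces*
  belong to which class (the features act as a province fingerprint) and
  reach perfect discrimination even when no socioeconomic signal exists.
* **Income tables.** Municipal mean incomes vary around the LLM target with
  declarant-weighted mean exactly equal to the target, and municipal medians
  are mean/$g_i$ with one inequality ratio $g_i$ per LLM, so the assembled
  LLM-level income per capita and mean/median ratio equal their generative
  targets up to integer rounding — which is what makes the configured effect
  sizes verifiable to Monte-Carlo precision.

What the generator does **not** emulate: differential-privacy noise
mechanisms, epidemic dynamics, real tile geometry, the real sector
classification (sectors are abstract labels), or seasonal/weekday structure
within windows (bins are uniform). Passing tests therefore show that the
pipeline recovers structure *of the kind the generator encodes* — monotone
class-wise flow suppression with class-correlated covariates — not that it
would recover the parameters of any particular real dataset.

## Segregation analyses

All analyses run on the standardized feature table (38 features per
territory: income per capita, mean/median inequality, population density,
revenue-concentration HHI, essential- and remote-worker shares, and
per-sector employees and revenue per employee for 16 sectors; macroarea is
carried as a categorical column). Standardization is fitted once on the full
territory set and shared by clustering, classification and regression.

* **Hierarchical clustering purity.** Cosine distance, average linkage
  (configurable to euclidean/complete/Ward), tree built once on the
  most/least subset; purity — majority-label counting per cluster — is
  evaluated at every cut of the same tree, hence non-decreasing in the number
  of clusters. A tied cluster contributes its tied count once (any majority
  choice gives the same count). Zero feature vectors have no cosine direction
  and raise an error naming the observation.
* **Classification.** Logistic regression, random forest, k-nearest
  neighbours and a support-vector machine with ecosystem-default
  hyperparameters, under stratified shuffle-split cross-validation (10
  splits, 20% test, at least two test observations per class); the report is
  the per-fold macro-averaged AUROC mean ± SD (fold mean, not a pooled
  estimate).
* **Group tests.** Per feature, a Kruskal–Wallis omnibus test over
  most/least/rest followed by Conover–Iman pairwise comparisons with
  Bonferroni correction ($p_{adj} = \min(1, 3\,p_{raw})$). Post-hocs are
  computed unconditionally and reported next to the omnibus p, but the
  decision rule gates on the omnibus. The omnibus p-value uses a permutation
  reference distribution by default (999 seeded label permutations): several
  features are province-level and hence duplicated across the territories of
  a province, which makes the $\chi^2$ approximation of the tie-corrected
  statistic anticonservative; the permutation reference is valid under any
  duplication pattern and bounds the p-value below at $1/(B+1)$. The
  $\chi^2$ reference remains available (`omnibus = "asymptotic"`). The
  Conover statistic is implemented from the rank identities (its denominator
  is the within-group mean square of the pooled ranks) and cross-checked in
  the tests against LSD t tests on ranks computed through `aov`.

## Quantile regression

The design has 59 columns: an intercept; the six aggregate covariates; 16
employee columns; 16 revenue-per-employee columns; four macroarea dummies
against the north-west reference area; and 16 interactions between those
dummies and the revenue per employee of four designated sectors. Covariates
enter standardized; the response is standardized by default (configurable),
and the regression is fitted at $\tau \in \{0.1, 0.2, 0.3, 0.7, 0.8, 0.9\}$
with an OLS reference on the same design.

The estimator minimizes the check (pinball) loss. The solver is iteratively
reweighted least squares with an annealed smoothing floor on $|r|$
($10^{-3}$ down to $10^{-11}$), followed on small designs ($p \le 6$) by an
exact vertex polish: a basic optimum interpolates $p$ observations, so the
$p$-subsets of the smallest-residual observations are solved exactly and the
best loss kept. Correctness is defined by the attained loss and verified
against a brute-force subset-enumeration oracle; in flat-optimum regions the
solver's solution is reported and tests compare losses, not coefficients.
Reported standard errors are asymptotic (iid-error sparsity with the
Hall–Sheather bandwidth) by default; heteroskedasticity-robust errors come
from a wild bootstrap with Rademacher (sign-symmetric two-point) weights —
the weight law is a documented choice, as is re-estimating each $\tau$
independently per replication. Bootstrap refits use a warm-started,
iteration-capped IWLS (three annealing stages of at most 15 iterations);
replicate SEs match fully converged refits to a few percent, a deliberate
accuracy/runtime trade-off. Replications that fail to produce finite
coefficients are dropped and counted; more than 5% failures is an error.
Information criteria use an asymmetric-Laplace working likelihood and are
labelled "working-likelihood IC" accordingly. The package's validation uses
200 bootstrap replications (scaled down from the conventional 1000) and a
study size of 495 territories.

## Problem sizes and reproducibility

The validation suite runs the full pipeline at the default study size
(200 territories, 16 windows, 42 bins per window) over 20 seeds for class
recovery; segregation checks use 5 signal seeds, 10 null seeds for
chance-level classification and 50 null seeds for Type-I control; parameter
recovery uses 20 seeds at 495 territories with a 200-replication bootstrap.
Unit tests use smaller scenarios (20–150 territories, 6 bins per window).
These sizes are the package's chosen validation conditions; every stochastic
step takes an explicit seed, and rerunning any seeded analysis reproduces it
bit for bit.

## Known limitations

* Undirected networks only; directionality of flows is summed away.
* The normalized efficiency's per-window $w_{\min}$ makes *levels* of
  $E_{norm}$ non-comparable across windows when the strongest link itself
  changes; the disruption indicators are within-territory ratios and class
  extraction depends only on within-window ranks, which are normalization
  invariant.
* The asymptotic quantile-regression SEs assume iid errors; use the wild
  bootstrap when heteroskedasticity matters.
* Purity under cosine/average linkage is sensitive to clumpy,
  province-blocked feature geometry; the alternative distances/linkages are
  exposed for robustness checks.
* The generator's recovery-curve magnitudes are free parameters; nothing in
  the package estimates them from data.
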