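# mobflow

Analysis of human-mobility network disruption and its socioeconomic
correlates at the level of territorial units (local labour markets, LLMs).

When a mobility restriction hits, territories do not suffer equally: some
rebound quickly (a V-shaped recovery), others stay depressed for months
(U-shaped). `mobflow` implements the full analysis chain that measures this
from raw origin–destination flow records and relates it to pre-existing
socioeconomic structure:

1. **Networks** — aggregate tile-level OD records over non-overlapping
   14-day windows into weighted undirected networks over LLMs.
2. **Efficiency** — with reciprocal-flow distances $d^{(1)}_{ij}=1/w_{ij}$
   and shortest-path $d_{ij}$,
   $E_{glob} = \frac{1}{n(n-1)}\sum_{i\ne j} 1/d_{ij}$ and the nodal
   contribution $e_i = \frac{1}{n-1}\sum_{j\ne i} 1/d_{ij}$
   (so $\mathrm{mean}_i\, e_i = E_{glob}$), normalized by the window's
   smallest distance: $E_{norm} = E_{glob}\, w_{\min} \in [0,1]$.
3. **Disruption indicators** — per-territory relative variation
   $\Delta e_i^t = (e_{i,t}-e_{i,t_0})/e_{i,t_0}$ against the pre-lockdown
   baseline, summarized by the *lockdown* indicator
   $(\Delta e_i^{t_L}+\Delta e_i^{t_L+1})/2$ and the *recovery* indicator
   $(\Delta e_i^{t_R}+\Delta e_i^{t_R+1})/2$; the *most*/*least* affected
   classes are the bottom/top K% of an indicator's distribution.
4. **Segregation tests** — hierarchical-clustering purity (cosine distance,
   average linkage), cross-validated classification (logistic, random
   forest, kNN, SVM; stratified shuffle split, macro AUROC), and per-feature
   Kruskal–Wallis tests with Conover post-hocs and Bonferroni correction,
   over a 38-feature socioeconomic table (income per capita, mean/median
   inequality, density, revenue-concentration HHI, essential/remote worker
   shares, and per-sector employees and revenue per employee).
5. **Quantile regression** — the indicators regressed on the standardized
   features with macroarea dummies and macroarea-by-sector interactions at
   $\tau \in \{0.1,0.2,0.3,0.7,0.8,0.9\}$, an OLS reference, and
   heteroskedasticity-robust wild-bootstrap standard errors. The check-loss
   solver (IWLS with exact vertex polish) is built in and verified against a
   brute-force oracle.

The real inputs of such studies (proprietary social-network mobility flows,
municipal tax and firm-registry tables) are not redistributable, so the
package ships a seeded synthetic-scenario generator (`generate_scenario()`)
that emulates their statistical structure — two latent territory classes
with V/U-shaped recovery multipliers on a gravity-model flow network, and
class-correlated covariates with exactly realized effect sizes. See the
methods vignette (`vignettes/mobility-disruption-methods.Rmd`) for the
models, parameter meanings and design choices.

## Worked example

```r
library(mobflow)

cfg      <- scenario_config(seed = 42)     # defaults: 200 LLMs, 16 windows
scenario <- generate_scenario(cfg)
grid     <- window_grid()                  # 16 x 14-day windows from 2020-02-24
networks <- build_networks(scenario$od_records, grid, scenario$tile_map)
eff      <- efficiency_series(networks)
head(eff$global[, c("window", "E_glob", "E_norm", "n_edges")], 3)
#>    window   E_glob      E_norm n_edges
#> 1:      0 79.01812 0.001067192    2877
#> 2:      1 49.69097 0.001425853    2004
#> 3:      2 49.72496 0.001387725    1999
```

Global efficiency collapses by ~37% in the first lockdown window (window 1)
and a third of the edges disappear. Per-territory indicators and classes:

```r
series     <- relative_variation(eff$nodal)          # normalized nodal e
indicators <- compute_indicators(series, t_L = 1, t_R = 5)
classes    <- extract_classes(indicators, K = 30, indicator_col = "lockdown")
table(classes$label)
#> least  most  rest
#>    60    60    80

curves <- class_recovery_curves(series, classes)
curves[label != "rest" & window %in% c(1, 5, 15),
       c("label", "window", "mean", "ci_low", "ci_high")]
#>     label window        mean      ci_low       ci_high
#> 1:  least      1  0.66661716  0.65045869  0.6827756
#> 2:  least      5  0.45658625  0.44432854  0.4688440
#> 3:  least     15 -0.00828038 -0.01272606 -0.0038347
#> 4:   most      1  0.08882922  0.06986287  0.1077956
#> 5:   most      5  0.02464273  0.01022254  0.0390629
#> 6:   most     15 -0.07821925 -0.08364930 -0.0727892
```

(Normalized $\Delta e$ is measured relative to each window's strongest link,
so class *levels* can shift with $w_{\min}$; the gap between the two curves —
here about 0.58 at lockdown and still 0.07 at the last window — and the
class ranking are what carry the disruption signal, and both are invariant
to the normalization.)

```r
features <- assemble_features(scenario)
std      <- standardize_features(features)
classify_classes(std$std, classes, classifiers = "random_forest", seed = 42)
#> <cv_report> 10 stratified shuffle splits (20% test)
#>   random_forest  macro AUROC 1.000 +/- 0.000
hierarchical_purity(std$std, classes)
#> <purity_curve> cosine distance, average linkage; purity(2) = 1.000, purity(50) = 1.000
```

On this synthetic scenario the extracted classes are perfectly separable
from their pre-existing socioeconomic features: the most affected
territories are the poorer, more unequal ones by construction, and the
classifier and the unsupervised clustering both find exactly that split.
Finally, the quantile regression:

```r
des <- build_design(std$std, indicators, indicator_col = "lockdown")
fit <- fit_quantile(des)           # 59 columns, tau = .1 .2 .3 .7 .8 .9
fit <- wild_bootstrap_se(fit, n_reps = 200, seed = 42)
tidy_quantile_fit(fit)             # term / tau / estimate / se / p
```

`run_pipeline(run_config(scenario = cfg), "out/")` runs all stages at once
and writes every intermediate table as CSV plus a `manifest.json`; a thin
CLI wrapper lives at `inst/scripts/mobflow`.

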