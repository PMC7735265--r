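# altishift

Effort-balanced estimation of elevational range shifts from two-period
resurvey data.

## What this is for

Repeating a historical biodiversity survey is one of the few ways to
measure century-scale range change, but historical and modern campaigns
never sample a mountain gradient with the same intensity at the same
elevations. A raw comparison of a species' mean elevation of occurrence
between periods then mostly measures *where the collectors went*.
`altishift` is aimed at quantitative ecologists working with such
two-period, elevation-tagged occurrence data — the motivating system is a
plant–bumblebee visitation community on a montane gradient — and provides:

* **Bin-stratified balanced resampling** of per-species mean-elevation
  shifts: records are stratified into 200 m elevation classes; within each
  class the better-sampled period is subsampled without replacement down to
  the other period's count; species means are computed on the balanced
  subset; the procedure is repeated (B = 1000) and averaged. Community-level
  significance uses a one-sample t-test (or Wilcoxon signed-rank when a
  Shapiro–Wilk test rejects normality of the shifts).
* **Interaction-weighted linkage**: each pollinator's shift is regressed on
  the visitation-frequency-weighted mean shift of the plants it visits,
  \(\sum_p w_p s_p / \sum_p w_p\), with 1:1-line residuals and a
  leave-one-out influence diagnostic.
* **Rarefied and extrapolated species richness** (Hill number 0):
  \(S(m) = S_{obs} - \sum_i \binom{n-x_i}{m}/\binom{n}{m}\) for
  interpolation, Chao1-based extrapolation via
  \(\hat f_0 = \frac{n-1}{n} f_1^2/(2 f_2)\), and multinomial-bootstrap
  confidence bands.
* **Climate and land-use context**: decadal aggregation and paired t-tests
  of gridded temperatures, the warming trend, conversion of warming into an
  equivalent uphill displacement of isotherms via the lapse rate
  (\(d_i = \Delta T_i / |b|\)), per-species occupied-climate-range
  Kruskal–Wallis tests, and elevation-zone land-use χ² tests.
* A **synthetic resurvey generator** with known ground truth (truncated
  normal niches, exact per-bin effort profiles, bee×plant preference
  matrices, affine climate grids, multinomial land-use grids) so every
  stage is testable without undeposited historical data.

## A worked example

The packaged demonstration scenario mirrors the structure of a
century-scale resurvey: 12 bee and 15 plant species shared between
periods, plants shifting further than their visitors, a −0.0049 °C/m
August lapse with 2.1 °C of warming.

```r
library(altishift)
demo <- demo_scenario(seed = 1)
occ  <- generate_resurvey(demo$scenario)

bees <- occ[occ$group == "bee", ]
est  <- estimate_shifts(bees, demo$binning, n_replicates = 1000, seed = 1)
head(est[c("taxon", "n_hist", "n_mod", "mean_hist", "mean_mod",
           "shift_m", "replicate_sd")], 4)
#>         taxon n_hist n_mod mean_hist mean_mod shift_m replicate_sd
#> 1 Bombus sp01     60    60      1415     1511   95.26        13.76
#> 2 Bombus sp02     60    60      1504     1541   37.40        13.80
#> 3 Bombus sp03     60    60      1561     1685  124.51        13.46
#> 4 Bombus sp04     60    60      1616     1703   86.73        14.09

overall_shift_test(est)
#> Overall shift test (n = 12 species)
#>   one-sample t: t = 7.25, df = 11, p = 1.64e-05
#>   mean shift = 82.2 m, 95% CI [57.2, 107.1] m
#>   Shapiro-Wilk normality p = 0.601
```

Each row is one species: `mean_hist`/`mean_mod` are its resampled mean
elevations per period (metres a.s.l.), `shift_m` the average
modern-minus-historical difference over 1000 balanced replicates, and
`replicate_sd` the spread of that difference across replicates. The
community test says the 12 species moved uphill by 82 m on average and
that a mean shift of zero is untenable (t = 7.25, df = 11). Note the
estimates are conservative for species at the community's range edges —
elevation classes occupied in only one period carry no evidence (see the
methods vignette).

Linking bees to their food plants and converting the warming into metres:

```r
w      <- interaction_weights(occ)
plants <- estimate_shifts(occ[occ$group == "plant", ], demo$binning,
                          n_replicates = 1000, seed = 1)
shift_regression(est, w, plants)
#> Bee shift ~ weighted plant shift (n = 12)
#>   slope = 1.06, intercept = -70.9, R^2 = 0.039, p = 0.539

cells <- generate_climate(demo$climate)
equivalent_elevation(cells, "mean")[c("displacement_mean_m",
                                      "displacement_sd_m")]
#> $displacement_mean_m
#> [1] 425.3222
#> $displacement_sd_m
#> [1] 86.19904
```

The historical mean August temperature is now found ~425 m higher on this
grid. The full chain — harmonization, shifts for both groups, linkage,
climate, land use, stratified rarefaction — runs from a YAML config via
`run_pipeline()`, writing one table per stage plus a seed-stamped summary;
reruns are byte-identical.

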