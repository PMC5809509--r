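# elevdisp

Abundance-weighted community phylogenetics for plot surveys along
elevational gradients.

Ecologists surveying woody-plant (or other sessile-organism) communities
along mountain transects routinely ask whether assemblages are
phylogenetically or functionally *clustered* (consistent with
environmental filtering) or *overdispersed* (consistent with competitive
exclusion), how that structure changes with elevation, and which
environmental axes — regional area, climate, habitat heterogeneity —
best explain it. `elevdisp` implements that whole workflow as composable
tibble-first R functions: dispersion metrics with a permutation null
model, an alpha/beta/gamma decomposition over elevational bands,
phylogenetic-signal statistics, a functional-trait dendrogram, and the
regression / Mantel / variation-partitioning layer on top. A synthetic
data generator produces phylogenies, traits, environments and
communities with the survey's statistical structure, so the pipeline is
fully testable without field data.

## The statistics at the core

Within an assemblage with relative abundances $f_i$ and pairwise
cophenetic distances $d_{ij}$ (on the phylogeny or on the trait
dendrogram):

$$\mathrm{MPD} = \frac{\sum_{i<j} f_i f_j d_{ij}}{\sum_{i<j} f_i f_j},
\qquad
\mathrm{NRI} = \frac{-\left(\mathrm{MPD}_{obs} -
\overline{\mathrm{MPD}}_{null}\right)}{\mathrm{sd}\!\left(\mathrm{MPD}_{null}\right)}$$

Between assemblages, $D_{pw}$ averages the two directed
abundance-weighted mean cross-community distances (with full abundance
weighting it reduces to the bilinear form $f^\top D\, g$), standardized
the same way into S.E.S. $D_{pw}$. The null model shuffles species names
across the tips of the tree/dendrogram (1000 times by default), holding
the community matrix fixed; positive values mean clustering, negative
overdispersion. Per band: alpha = mean plot NRI, beta = mean pairwise
S.E.S. $D_{pw}$ among plots (and between pooled band pairs),
gamma = NRI of the pooled band. Phylogenetic signal is quantified with
Blomberg's K (PIC-variance randomization test) and Pagel's lambda
(profile ML with an LR test). The gradient layer provides
linear/quadratic OLS with AIC choice, simple OLS screens, forward
stepwise regression, Mantel tests, MRM and three-set variation
partitioning.

## A worked example

Simulate an environmental-filtering scenario (60 species, 10 bands of
100 m, 5 plots per band) and run the full analysis:

```r
library(elevdisp)

cfg <- scenario_config("filtering", n_species = 60, n_bands = 10,
                       plots_per_band = 5, individuals_per_plot = 80,
                       lambda_sim = 0.8, seed = 42)
run <- run_full(cfg, n_null = 199, n_perm = 999, seed = 1)

run$signal
#> # A tibble: 5 × 7
#>   trait                K   p_K K_stars lambda  p_lambda lambda_stars
#>   <chr>            <dbl> <dbl> <chr>    <dbl>     <dbl> <chr>
#> 1 height_m        0.157  0.008 "**"     0.615 0.000297  "***"
#> 2 leaf_length_cm  0.120  0.048 "*"      0.601 0.0000455 "***"
#> 3 leaf_width_cm   0.0819 0.126 ""       0.406 0.00256   "**"
#> 4 flowering_month 0.0378 0.547 ""       0.337 0.105     ""
#> 5 seed_mass_mg    0.203  0.001 "**"     0.732 0.0000786 "***"
```

Traits carry significant but sub-Brownian signal (K well below 1,
lambda between 0.34 and 0.73) — the regime in which phylogenetic
dispersion approximates functional dispersion only roughly. The band
components show the filtering signature, clustering (NRI > 0) across
most of the gradient:

```r
dplyr::filter(run$band_components, facet == "phylogenetic") |>
  dplyr::select(band, alpha, beta_within, gamma)
#> # A tibble: 10 × 4
#>     band  alpha beta_within  gamma
#>  1   200  1.32        1.47   1.37
#>  2   300  1.40        1.43   1.39
#>  3   400  1.48        1.56   1.57
#>  4   500  1.39        1.44   1.61
#>  5   600  1.21        1.32   1.19
#>  6   700  1.06        1.22   1.25
#>  7   800  0.757       0.811  0.918
#>  8   900  0.789       0.888  0.931
#>  9  1000  0.203       0.201  0.130
#> 10  1100 -0.333      -0.395 -0.500
```

Between-band functional dispersion decays with elevational separation
(simple Mantel, 999 permutations):

```r
dplyr::filter(run$mantel, distance == "dist_ele")
#> # A tibble: 2 × 7
#>   facet        distance      r p_value stars     n n_perm
#> 1 phylogenetic dist_ele -0.102   0.624 ""       10    999
#> 2 functional   dist_ele -0.552   0.001 "**"     10    999
```

`run$elevation_fits`, `run$ols_screen`, `run$stepwise` and
`run$varpart` hold the AIC-chosen elevation models, per-predictor
screens, stepwise equations and variance fractions;
`plot_band_components(run$band_components)` and
`plot_distance_decay(run$band_beta)` draw the standard figures, and
`write_report_bundle(run, "out/")` writes everything as CSV plus the
dendrogram as newick.

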