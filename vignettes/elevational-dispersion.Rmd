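---
title: "Phylogenetic and functional dispersion along elevational gradients: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic and functional dispersion along elevational gradients: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elevdisp)
```

`elevdisp` implements an abundance-weighted community-phylogenetics
workflow for woody-plant (or any sessile-organism) survey data arranged
as plots along elevational transects: dispersion metrics with a
permutation null model, their decomposition into alpha, beta and gamma
components over elevational bands, phylogenetic-signal statistics for
the traits, a functional-trait dendrogram, and a regression/Mantel layer
relating the components to environment. This vignette records the models
implemented, the conventions chosen where the methodology leaves
freedom, what the synthetic-data generator does and does not emulate,
and the package's known limitations.

## Dispersion metrics and the null model

Within one assemblage, the abundance-weighted mean pairwise distance is

$$\mathrm{MPD} \;=\; \frac{\sum_{i<j} f_i f_j\, d_{ij}}{\sum_{i<j} f_i f_j},$$

over distinct species pairs, with $f_i$ the relative abundances and
$d_{ij}$ the cophenetic distance on the phylogeny or on the trait
dendrogram. Note the normalization over *distinct* pairs: some software
averages over ordered pairs including conspecific ($d = 0$) ones, which
rescales the observed value by $1 - \sum_i f_i^2$; both the observed
metric and its null draws use the same convention here, so the
standardized effect sizes are unaffected by that choice.

Between two assemblages $k_1, k_2$, the dissimilarity $D_{pw}$ averages
the two directed abundance-weighted sums
$\sum_i f_i \bar d_{ik_2}$ and $\sum_j f_j \bar d_{jk_1}$, where
$\bar d_{ik_2}$ is the mean distance from species $i$ of $k_1$ to the
species of $k_2$. The inner mean's weighting is not fixed by the
formula's prose, so both variants ship: with the default
(`inner_weighted = TRUE`) the inner mean uses the other assemblage's
relative abundances, and the two directed sums coincide, giving the
bilinear form $D_{pw} = f^\top D g$; with `inner_weighted = FALSE` the
inner mean is unweighted and the two directed sums are averaged. The
default was chosen because it makes the metric fully
abundance-weighted, consistent with its use alongside abundance-weighted
MPD, and reduces to a single quadratic form that the null machinery can
evaluate for thousands of permutations at once.

The null model shuffles species names across the tips of the tree (or
dendrogram), leaving the community matrix untouched, so occupancy,
abundance and spatial structure are all conserved. Standardized effect
sizes are sign-flipped,

$$\mathrm{NRI} = \frac{-(\mathrm{MPD}_{obs} -
\overline{\mathrm{MPD}}_{null})}{\mathrm{sd}(\mathrm{MPD}_{null})},$$

so positive values mean clustering and negative values overdispersion;
the between-assemblage analogue (S.E.S. $D_{pw}$) is standardized the
same way. Defaults are 1000 null replicates for dispersion metrics and
10000 permutations for Mantel tests; both are arguments everywhere.

Conventions where the method is silent:

* **Pool.** Tips are shuffled over the full species pool of the supplied
  (pruned) tree — constant across bands — not per-band pools.
* **Degenerate nulls** (zero null SD, e.g. a star phylogeny): the effect
  size is reported as 0 with a `degenerate` flag and an `NA` p-value,
  and flagged values are excluded from band-level averages, so summaries
  stay computable.
* **p-values** are two-sided rank probabilities
  $2\min(r, n+1-r)/(n+1)$, with $r$ the observed value's rank among
  observed plus null (midranks for ties).
* **Monospecific plots** (MPD undefined) are skipped with a warning and
  a count in the band table.
* **Seeds.** One master seed; every per-plot, per-pair and
  per-replicate task derives its own sub-seed with `derive_seed()`
  (a Lehmer-style mix), so results do not depend on execution order.

The alpha component of a band is the mean NRI of its plots; the
within-band beta component is the mean S.E.S. $D_{pw}$ over unordered
plot pairs; the gamma component is the NRI of the band's pooled-and-
summed assemblage; between-band beta is S.E.S. $D_{pw}$ on pooled band
pairs. Bands are lower-closed, upper-open elevation intervals of
configurable width (default 100 m), since real band definitions vary by
study.

## Trait space

Traits (canonically: maximum height in m, leaf length and width in cm,
flowering onset month, seed mass in mg) must be strictly positive; they
are log-transformed and standardized to unit SD. PCA is run on the
standardized matrix (covariance PCA of standardized columns equals
correlation PCA of the raw logs); the number of retained components
defaults to the smallest number explaining 94.8 % of variance and can
be pinned (e.g. to 4). Signs are fixed by making the largest-magnitude
loading of each component positive. Euclidean distance on the retained
scores feeds UPGMA.

UPGMA is implemented with size-weighted average linkage; each merge sits
at *half* the between-cluster average distance, so tip-to-tip dendrogram
distance equals the cluster-average distance and the result is
ultrametric. Ties in the minimum distance are broken by merging the pair
whose smallest member labels sort first lexicographically — an arbitrary
but reproducible convention that makes the dendrogram byte-identical
across runs. Missing trait values are an error: no imputation is
attempted, because imputation policy belongs to data preparation, not to
the dendrogram.

## Phylogenetic signal

Blomberg's K is the ratio of the observed
$\mathrm{MSE}_0/\mathrm{MSE}$ (tip variance around the GLS ancestral
mean over the phylogenetically corrected variance) to its Brownian
expectation $(\mathrm{tr}\,C - n/(\mathbf 1^\top C^{-1}\mathbf 1))/(n-1)$;
K = 1 under Brownian motion. Significance uses the statistic's standard
randomization: trait values are shuffled across tips 999 times and the
variance of phylogenetically independent contrasts is compared with the
observed (one-sided, low variance = signal), observed configuration
included in the count.

Pagel's lambda multiplies the off-diagonal (shared-history) entries of
the Brownian covariance by $\lambda$; the mean and rate are profiled out
in closed form and $\lambda$ is estimated by a grid scan plus bounded
Brent search, followed by a parabolic refinement step from a rounded
base point. The refinement exists for a numerical reason: golden-section
termination near a flat optimum is driven by floating-point noise, and
the refinement restores invariance of $\hat\lambda$ under affine
rescalings of the trait to below 1e-8. By default $\lambda$ is reported
on $[0, 1]$; the admissible upper bound (off-diagonals capped by the
diagonals) is available. The significance test is a likelihood-ratio
test against $\lambda = 0$ referred to $\chi^2_1$ — conservative at the
boundary; the 50:50 mixture correction and a test against
$\lambda = 1$ are available behind flags. Star trees make $\lambda$
unidentifiable and are flagged rather than fitted. Basal polytomies are
accepted (a star phylogeny simply yields a diagonal covariance).

## Gradient statistics

* **Elevation fits.** Linear and quadratic OLS on the centred
  predictor; AIC in the Gaussian profile form $n\ln(RSS/n) + 2k$ with
  $k$ = mean parameters + 1. Only AIC differences are interpreted. When
  the linear model fits to numerical precision
  ($RSS \le 10^{-10}\,TSS$) it is chosen outright — log-ratios of
  floating-point residuals are meaningless.
* **Stepwise.** Forward selection by smallest partial-F p-value with
  entry threshold 0.05. The criterion is a convention (the method name
  alone does not fix one); AIC-based stepping would also be defensible
  and the threshold is an argument.
* **Mantel.** Pearson correlation of lower triangles; the *response*
  matrix's labels are permuted; two-sided p with the observed
  configuration included in numerator and denominator; exhaustive
  enumeration for small label sets.
* **MRM.** OLS on lower-triangle vectors with label-permutation
  p-values on |t|; predictor sets with condition number above 1e8 are
  refused, naming the most collinear pair.
* **Variation partitioning.** The seven subset models of three
  predictor groups; unique fractions by difference from the full model,
  one combined (shared) fraction, and the residual. Negative shared
  fractions are reported as-is with a flag — they are a known,
  legitimate outcome of this decomposition.
* **Distances.** Between bands: absolute elevation difference (proxy of
  geographic distance), absolute difference in log regional area,
  Euclidean distance on the climate PC1, and Euclidean distance on the
  two heterogeneity PCs, from two separate PCAs of standardized climate
  and topographic-SD variables.

Conditional autoregressive (spatial) models are deliberately out of
scope; where a study would use them as a robustness check on the OLS
results, this package does not.

## The synthetic-data generator

The generator exists so that every stage of the pipeline is testable
without field data. It emulates the *structure* of a multi-transect
elevational survey, not any particular data set:

* **Phylogeny.** A forward birth–death simulation conditioned on first
  passage to the requested number of extant tips, with the present
  placed at the moment the next event would have occurred (so pendant
  edges are positive). Under pure birth the expected depth is
  $(1/b)\sum_{k=2}^{n} 1/k$, which the tests use as an analytic oracle.
  Extinct lineages are pruned; the tree is ultrametric.
* **Traits.** Two latent traits drawn from
  $\mathcal N(0, \sigma^2 C(\lambda_{sim}))$; five observable traits
  are exponentiated affine images of the latents plus log-scale noise
  (default SD $0.2\sqrt{\sigma^2}$, vanishing with the signal), so
  values are strictly positive and the trait PCA has known low-rank
  structure. The first latent trait is the assembly trait, which
  couples functional to phylogenetic dispersion without making them
  identical.
* **Environment.** Climate variables are monotone in elevation
  (temperature-like decreasing, precipitation-like increasing on the
  log scale) with noise expressed as a fraction (default 0.1) of each
  variable's elevational range; log regional area decreases with
  elevation; topographic-heterogeneity SDs follow a hump (or flat)
  profile. At zero noise the climate PC1 is exactly collinear with
  elevation — a useful identity for tests.
* **Communities.** Each plot draws a fixed number of individuals
  (default 100, the order of a 400-m² forest plot's stem count) from
  the pool. Regional abundances are lognormal (meanlog 0, sdlog 1),
  drawn once per simulation. Neutral: weights are the regional
  abundances. Filtering: weights are multiplied by a Gaussian kernel of
  width $\sigma_f$ around an optimum linear in elevation (default slope
  0.004 trait units per metre, spanning about two latent-trait SDs over
  a 1000-m gradient). Competition: sequential draws with rejection of
  candidates whose latent-trait distance to any resident *other*
  species is below $\delta$ (conspecific redraws are allowed — limiting
  similarity acts between species); after 100 failed retries the
  candidate is accepted and counted, with a warning if violations
  exceed 10 % of draws. The scale defaults (80 species, 10 bands of
  100 m, 10 plots per band) are a deliberately desk-sized version of a
  regional survey, chosen once for the study conditions.

What the generator does **not** emulate: spatially explicit dispersal,
demographic dynamics through time, intraspecific trait variation,
non-Gaussian trait evolution, or the megaphylogeny-binding step by
which real studies obtain their tree. Consequently, passing tests show
that the *statistical machinery* behaves as designed under its own
assumptions — they are not evidence about any particular forest.

One property of the generator matters for interpretation and is easy to
miss. All plots of one scenario share a single tree and a single
regional-abundance draw, so plot-level dispersion scores are strongly
correlated within a scenario: even under neutral assembly, the mean NRI
over hundreds of plots fluctuates by roughly ±1 across scenario
replicates. Two design consequences follow:

* **Null calibration** is checked on assemblages given independent
  abundance-preserving random relabelings (each plot keeps its
  abundance vector but draws fresh species identities). These are
  genuine draws from the null, so NRI over them must have mean ≈ 0 and
  SD ≈ 1 — which is what the calibration test asserts.
* **Mechanism direction** (filtering ⇒ clustering, limiting similarity
  ⇒ overdispersion) is asserted on the *functional* trait-dendrogram
  distance, where the direction is forced by construction because
  assembly filters or repels on the latent trait directly. On the
  phylogenetic facet the direction holds on average (the assembly trait
  is phylogenetically conserved) but a single Brownian realization on a
  single tree couples trait to phylogeny only statistically, so the
  phylogenetic means are reported rather than asserted.

## Problem sizes and runtime choices

The test suite and the acceptance script run on deliberately small
problems chosen as the package's own desk-scale study conditions:
null calibration on 200 plots with 999 nulls; K recovery on 500
fifty-tip Brownian simulations; $\lambda$ recovery on 100 replicates of
200 tips at each of $\lambda \in \{0.2, 0.5, 0.8\}$; mechanism and
distance-decay scenarios with 80 species, 10 bands and 6 plots per band
at 199 nulls; Mantel tests at 999–9999 permutations. The dispersion
null is evaluated as a batched bilinear form over all permutations at
once, which is what makes thousands of null replicates per assemblage
cheap.

## Known limitations

* AIC with a per-parameter penalty of 2 prefers the quadratic on truly
  linear data with asymptotic probability
  $P(\chi^2_1 > 2) \approx 0.16$ regardless of noise level or band
  count. Shape identification on linear data therefore plateaus around
  75–85 % accuracy; this is a property of AIC itself, not of the
  implementation, and is visible in the reported
  `aic_linear_correct_rate`.
* The LR test for $\lambda$ uses the plain $\chi^2_1$ reference and is
  conservative at the boundary (measured type-I rate ≈ 0.03 at nominal
  0.05); the mixture correction is available but off by default.
* NTI/MNTD-type (nearest-taxon) metrics, presence-only dispersion,
  alternative null models (independent/trial swap), partial Mantel
  tests and spatial autoregressive models are out of scope.
* Mantel and MRM inherit the usual caveats of distance-matrix
  inference (non-independence of pairs); permutation inference is used
  throughout, but effect sizes should be read comparatively, as in the
  report tables, not as absolute variance explained.
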