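---
title: "Densities in geographical and ecological space: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Densities in geographical and ecological space: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecodensity)
```

## The scientific problem

Point-count monitoring schemes estimate how many birds live where. Two
density notions answer different questions. **Geographical density** divides
a species' total count by the total physical area surveyed: it describes
abundance in space as a whole. **Ecological density** divides the same count
by the area of *habitat suitable for that species*, so it describes how
densely the species packs the space it can actually use. A habitat
specialist may look rare in geographical space simply because little of the
landscape is usable for it, while being very abundant inside its own
habitat. Separating the two densities is what lets specialization effects be
tested at all: `ecodensity` implements both, together with the
specialization index, trait reduction and the phylogenetically corrected
regressions that relate traits to densities.

## From counts to densities

A census consists of points of radius 100 m (area $\pi$ ha $= 3.14159$ ha,
`point_area_ha`), each visited twice in a breeding season and annotated with
the proportions of 12 biotope categories within the point radius. The 12
categories are aggregated to 7 analysis classes (the four open categories to
`open`, the two wetland ones to `water`, urban plus suburban to `urban`;
`aggregate_habitats()`). Because communities turn over within a season, the
per-point abundance of a species is the **maximum** of its two visit counts
(`collapse_visits()`); summing the visits would double-count territorial
birds.

Species habitat preferences are binary vectors over a separate, European
15-class habitat taxonomy, mapped onto the same 7 analysis classes
(`preference_to_aggregated`; the generic `woodland` class is carried to
mixed forest and `marine` to water, both remappable). The suitable area of
point $p$ for species $s$ is the point area times the summed proportions of
the aggregated classes containing at least one preferred source class.
Then, with $a_{sp}$ the per-point abundance,

$$D^{geo}_s = \frac{\sum_p a_{sp}}{N \cdot \pi\,\mathrm{ha}}, \qquad
  D^{eco}_s = \frac{\sum_p a_{sp}}{\sum_{p:\,a_{sp}>0} A^{suit}_{sp}}.$$

The ecological denominator uses **presence points only** by default; because
the defining phrase of the quantity is ambiguous about this, an
`all_points` mode is provided that sums suitable area over every surveyed
point. Under either mode $D^{eco} \ge D^{geo}$, since the denominator can
never exceed the total surveyed area. A presence at a point with zero mapped
suitable habitat is treated as evidence of suitability: the point
contributes its full area to the denominator and the species is flagged
(`zero_suitable_presence`) rather than silently dropped, which would break
the inequality and discard real individuals.

## Specialization

The species specialization index for a species occupying $h$ of $H$
possible classes is

$$\mathrm{SSI} = \sqrt{H/h - 1},$$

which is exactly the population coefficient of variation (divisor-$H$
standard deviation) of the binary occupancy vector — the sample-SD variant
does not satisfy this identity, so the population form is used. $H$ is the
width of the preference taxonomy (15 habitat, 9 diet classes), *not* the
number of classes seen in the census: specialization is a species attribute
and must stay independent of local habitat availability. The attainable
ranges are $0$–$3.742$ for habitat ($h = 15$ down to $1$) and $0$–$2.828$
for diet.

## Traits

Five morphological traits (body, wing, tail, bill, tarsus lengths;
sex-averaged before any transform) and four reproductive traits (clutch
size, broods per year, egg mass, life span) are each reduced to their first
principal component (`pca_reduce()`): the structural-size axis **ssPC** and
the slow–fast life-history axis **sfPC**. The PCA standardizes traits
first (correlation-matrix PCA). This is a deliberate choice: the blocks mix
millimetres, grams and years, and an unstandardized PCA would load almost
entirely on whichever trait has the largest numeric variance. PC1 is
sign-oriented so its loading on the first listed trait is positive; since a
PCA axis is only defined up to sign, no scientific conclusion may depend on
the orientation, and tests only assert magnitudes of correlations involving
PC scores. Body mass enters the models separately as its natural log (the
base is configurable; slopes scale by $1/\ln 10$ under log10), and nest
type is treatment-coded with ground nests as the reference level.

## Phylogenetic correction

Related species are not independent data points. Under Brownian trait
evolution the covariance of two tips is proportional to the shared
root-to-MRCA path length, giving the matrix $V$ (`brownian_vcv()`, with any
stored root edge added so pruning a tree commutes with subsetting $V$). The
regression model is then

$$y = X\beta + \varepsilon, \qquad \varepsilon \sim N(0, \sigma^2 V),$$

fit by whitening with the Cholesky factor of $V$ (`fit_pgls()`). $\sigma^2$
is profiled out, so $V$ may be supplied on any scale. Maximum likelihood is
the default estimator because the model-selection stage compares models with
different fixed effects, and REML likelihoods are not comparable across
fixed-effect structures; REML remains available for variance estimation.
The AIC counts $\sigma^2$ as a parameter ($k = p + 1$). Coefficient tests
in single fits use $t$ statistics on $n - p$ degrees of freedom with the
df-corrected variance.

When the analysis uses a sample of candidate trees, a 50% majority-rule
consensus is built first (`consensus_tree()`): clades present in strictly
more than half of the trees are retained (an exact 50/50 conflict collapses
to a polytomy) and each retained edge gets the mean of its lengths over the
trees containing that clade. The strict rule is available; the majority
rule with mean lengths is the default because it keeps branch-length
information that the strict consensus of a jittered sample would discard.
`dredge_over_trees()` repeats the whole model-selection analysis on every
tree in the sample and reports per-coefficient spread and sign agreement
with the consensus result, which is the appropriate check that conclusions
do not hinge on one phylogenetic hypothesis.

## Model selection and averaging

`dredge_pgls()` fits every subset of the full model's terms ($2^m$ models;
a factor block enters or leaves whole; the intercept always stays), ranks
them by AIC and breaks exact ties deterministically (fewer parameters, then
the lexicographic term string). Models within $\Delta\mathrm{AIC} < 2$ of
the best are retained and combined by **full model averaging**
(`select_and_average()`): with Akaike weights
$w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$ over the retained set,

$$\bar\beta_j = \sum_i w_i\,\beta_{ij}, \qquad
  \mathrm{SE}(\bar\beta_j) = \sum_i w_i
  \sqrt{\mathrm{SE}_{ij}^2 + (\beta_{ij} - \bar\beta_j)^2},$$

where $\beta_{ij} = 0$ (with zero SE) when term $j$ is absent from model
$i$. The adjusted SE replaces each $\mathrm{SE}_{ij}$ by
$\mathrm{SE}_{ij}\, t_{df_i,0.975} / z_{0.975}$, and averaged coefficients
are tested with standard-normal $z$ statistics. Full (zero-substitution)
averaging is the default because it shrinks weakly supported terms toward
zero and matches the conventional averaged-model table layout; conditional
averaging (over containing models only) is available via a flag. The full
models for the density responses contain nest type, one trait PC, habitat
SSI, diet SSI and breeding range. Body mass is excluded from the full
models because it correlates with both PCs, and ssPC and sfPC never share a
model (they are themselves strongly correlated); the pipeline records these
correlations in its run report so the exclusion is auditable per dataset.

## The synthetic study system

`sim_config()` / `simulate_dataset()` generate a complete, ground-truthed
study. Defaults describe one fixed set of study conditions:

* **Landscape** — 1000 points in transects of 20; each point's composition
  over the 7 classes is a symmetric Dirichlet draw (concentration 1;
  $\infty$ degenerates to the exact uniform mosaic). Real biotope mosaics
  are spatially autocorrelated; the generator's points are exchangeable, a
  deliberate simplification (see Limitations).
* **Niches** — habitat-niche breadths $h \in 1\ldots6$ of the 15 source
  classes with probabilities $(0.15, 0.30, 0.25, 0.15, 0.10, 0.05)$, which
  places the habitat SSI between 1.22 and 3.74 with median near 2 —
  the range real temperate-zone breeding avifaunas occupy. Diet breadths
  follow an analogous distribution over the 9 diet classes.
* **Intensity** — species $s$ has within-suitable-habitat intensity
  $\lambda_s = \lambda_0 \exp(\gamma\,\mathrm{SSI}_s + \varepsilon_s)$ with
  $\lambda_0 = 0.3$ individuals/ha, $\gamma = 0.2$, and $\varepsilon$ a
  Brownian species effect (rate 0.25 on the unit-height tree, i.e. tip SD
  0.5, roughly one order of magnitude of typical between-species spread).
  The log-linear link makes $\gamma = 0$ an exact null, and the Brownian
  species effect is what makes the Brownian GLS residual model appropriate
  for the generated data: abundance is phylogenetically conserved in real
  communities, and without this term species would be exchangeable given
  SSI and a phylogenetic regression would have nothing to correct.
* **Counts** — two independent Poisson visits with mean
  $\lambda_s \times A^{suit}_{sp}$, the suitable area computed by the same
  code the estimator uses.
* **Trees and traits** — a Yule tree rescaled to unit height; perturbed
  variants by lognormal branch jitter (SD 0.1) and optional NNI moves;
  traits by hand-rolled Brownian propagation along edges with shared latent
  size and pace axes plus small independent deviations, exponentiated to
  positive measurement scales (morphometric PC1 then carries ~95% of block
  variance, matching the near-collinearity of real bird morphometrics).

Because specialists with binary niches mechanically find *less* suitable
area, log geographical density under this generator is
$\gamma\,\mathrm{SSI} + \log f_s + \text{noise}$, where $f_s$ is the
species' expected suitable fraction; the availability term contributes a
systematic negative slope of roughly $-0.5$ per SSI unit at these breadth
settings. A flat geographical-density–SSI relationship therefore cannot
coexist with $\gamma = 0.2$ under general niches. The generator's
`single_biotope` niche model provides the clean null for geographical-space
calibration: all species prefer source classes within the open biotope
group, so SSI varies (through source-class breadth) while habitat
availability is identically distributed across specialization levels. The
package's calibration checks use that balanced design at $\gamma = 0$, and
the general design at $\gamma = 0.2$ for the ecological-space effect, which
ecological density recovers regardless of niche model since its denominator
already conditions on suitability.

All randomness flows from one seed through fixed per-stage substreams, so
every stage is independently reproducible and a repeated run is
byte-identical.

## Numerical choices and degenerate inputs

* $V$ is factorized by Cholesky; on failure a diagonal jitter of
  $10^{-10} \times \overline{\mathrm{diag}(V)}$ is tried once before
  erroring, so semi-definite matrices from polytomous consensus trees are
  accepted.
* Singular designs error and name the collinear columns; a noiseless
  response yields $\hat\sigma^2 = 0$ and infinite likelihood rather than a
  silent fallback.
* Species with zero total count have undefined ecological density and are
  excluded with a warning; a missing second visit is treated as a zero
  count with a warning.
* Dredging refuses more than 20 terms (over a million models) unless the
  guard is raised explicitly.

## What the tests do and do not show

The test suite verifies the estimator algebra against independent oracles
(whitening OLS via eigendecomposition, explicit path-traversal Brownian
covariances, an independently coded implementation of the averaging
formulas, `nlme::gls` for one Brownian-correlation fit), the generator's
distributional claims, and — on the synthetic system at 150 species and
1000 points — the headline qualitative contrast: the averaged habitat-SSI
coefficient on ecological density is positive in essentially all
replicates, while under the balanced-habitat null the geographical-density
coefficient has no preferred sign.

One calibration property fails by design of the system rather than of the
code, and is worth stating plainly. The census introduces Poisson sampling
noise into the density estimates, an *independent* (non-phylogenetic) error
component on top of the Brownian species effect. A pure-Brownian GLS fit to
such a Brownian-plus-independent mixture has inflated type-I error —
near-sibling tips are almost perfectly correlated under $V$, so the
whitening transform amplifies their contrasts, and independent noise then
dominates exactly those contrasts. At the default study conditions
(independent noise SD about 0.1 on log ecological density versus Brownian
tip SD 0.5) the single-predictor SSI test rejects a true null far above the
nominal 5%; calibration would require either implausibly large counts per
species or a residual structure (Pagel's $\lambda$, explicit
measurement-error modelling) that is outside this package's scope. The
same caveat applies to any pure-Brownian PGLS on ratio estimates from
finite censuses, including analyses of real monitoring data; the
significance levels of such fits should be read accordingly.

Passing tests on the synthetic system also do not certify behaviour on real
data with spatial autocorrelation between neighbouring points, observer
effects, or imperfect detection — all deliberately absent from the
generator, and the latter explicitly outside the estimators' scope.

## Problem sizes used in the checks

The distributional checks run at 150 species × 1000 points with 50
replicates for the model-averaged sign properties and 200 replicates for
the null-calibration measurement; oracle comparisons use 100 random small
instances each. A demo-scale run (25 species, 150 points) executes in
about a second:

```{r demo, eval = FALSE}
cfg <- run_config(sim = sim_config(n_points = 150, n_species = 25,
                                   n_trees = 4),
                  seed = 42, log_response = TRUE)
res <- run_ecodensity(cfg)
res$report$ssi_habitat_coefficient
#> geo_density_ssPC eco_density_ssPC
#>       -0.3878999        0.2920536
res$table2$eco_density_ssPC
```

The negative geographical-space coefficient is the availability confound
described above; the positive ecological-space coefficient is the
generator's specialization–intensity link, recovered.
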