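# ecodensity

Bird population densities in **geographical space** (individuals per
hectare of surveyed area) and in **ecological space** (individuals per
hectare of habitat suitable for the species), and the phylogenetically
corrected regressions that relate those densities to species traits.

The package is aimed at ornithologists and macroecologists working with
point-count monitoring data (fixed-radius points along transects, two
visits per breeding season, biotope composition recorded around each
point) together with species-level trait and habitat/diet preference
tables and a sample of candidate phylogenies.

## What it computes

* **Densities.** Per-point abundance is the maximum over the two visits.
  Geographical density divides total abundance by total surveyed area
  (points × π ha for a 100 m census radius). Ecological density divides it
  by the species' suitable-habitat area, derived from binary habitat
  preference vectors mapped onto the 7 aggregated biotope classes; by
  construction ecological ≥ geographical density.
* **Specialization.** The species specialization index
  `SSI = sqrt(H/h − 1)` for a species occupying `h` of `H` preference
  classes (15 habitat, 9 diet) — equivalently the population coefficient of
  variation of the binary occupancy vector. Habitat SSI ranges 0–3.742,
  diet SSI 0–2.828.
* **Traits.** Correlation-matrix PCAs reduce the morphological block to a
  structural-size score (ssPC) and the reproductive block to a slow–fast
  score (sfPC); body mass (natural log) stays a separate predictor.
* **Phylogenetic regressions.** Brownian-motion covariance matrices from
  rooted Newick trees, 50% majority-rule consensus trees with mean clade
  branch lengths, GLS fits `y = Xβ + ε, ε ~ N(0, σ²V)` by Cholesky
  whitening (ML or REML), all-subsets AIC dredging, ΔAIC < 2 selection,
  full model averaging with Akaike weights, and a robustness report over a
  whole tree sample.
* **Synthetic data.** A generator with known ground truth (Dirichlet
  mosaic landscapes, binary niches, Poisson censuses whose
  within-suitable-habitat intensity follows
  `λ0·exp(γ·SSI + Brownian species effect)`, Yule trees, Brownian traits)
  so the full pipeline is testable without field data.

## Worked example

A small synthetic study — 40 species, 300 points, 5 candidate trees —
analysed end to end on the log-density scale:

```r
library(ecodensity)
cfg <- run_config(sim = sim_config(n_points = 300, n_species = 40,
                                   n_trees = 5),
                  seed = 42, log_response = TRUE)
res <- run_ecodensity(cfg)

head(res$densities[c("species", "total_count", "geo_density", "eco_density")])
#>   species total_count geo_density eco_density
#> 1   sp001         210   0.2228169   1.2037231
#> 2   sp002         241   0.2557089   0.9364018
#> 3   sp003         261   0.2769296   1.3191916
#> ...
```

Ecological densities (per hectare of suitable habitat) sit well above
geographical ones, most for the habitat specialists. The single-predictor
suite contrasts the two spaces:

```r
subset(res$table1, predictor == "ssi_habitat")
#>       response   predictor        term estimate     se t_value p_value
#> 3  geo_density ssi_habitat (Intercept) -1.21796 0.4395 -2.7709  0.0086
#> 4  geo_density ssi_habitat ssi_habitat -0.00632 0.0729 -0.0866  0.9314
#> 9  eco_density ssi_habitat (Intercept)  0.10199 0.2977  0.3426  0.7338
#> 10 eco_density ssi_habitat ssi_habitat  0.09574 0.0494  1.9381  0.0601
```

Habitat specialization predicts density in ecological space (positive
slope) but not in geographical space — the pattern the estimator pair is
designed to expose. The dredged, ΔAIC < 2-averaged model for ecological
density:

```r
res$table2$eco_density_ssPC
#> Full model average over 1 model(s) with delta AIC < 2
#>             term   estimate        se    adj_se z_value   p_value
#> 1    (Intercept) -1.229e-01 2.089e-01 2.171e-01  0.5659 5.715e-01
#> 2    nest_typeGC -2.999e-01 2.981e-01 3.098e-01  0.9678 3.332e-01
#> 3     nest_typeH -1.213e-01 6.390e-02 6.641e-02  1.8266 6.776e-02
#> 4    nest_typeOA -9.724e-02 5.136e-02 5.338e-02  1.8219 6.848e-02
#> 5           ssPC -4.581e-02 1.969e-02 2.047e-02  2.2382 2.521e-02
#> 6    ssi_habitat  2.476e-01 4.424e-02 4.598e-02  5.3858 7.211e-08
#> 7       ssi_diet -4.560e-02 2.358e-02 2.451e-02  1.8607 6.279e-02
#> 8 breeding_range  2.780e-08 1.004e-08 1.044e-08  2.6640 7.722e-03
```

The averaged habitat-SSI coefficient (0.248, z = 5.4) recovers the
generator's specialization–intensity link (γ = 0.2); the run report
carries the headline coefficients for both spaces and the PCA variance
shares (here 95.9% for ssPC, 82.8% for sfPC):

```r
res$report$ssi_habitat_coefficient
#> geo_density_ssPC eco_density_ssPC
#>       -0.2050814        0.2476251
```

With `out_dir` set, the run writes `densities.csv`, `ssi.csv`,
`predictors.csv`, `table1.csv`, per-response dredge and averaged-model
tables, `consensus.nwk` and `report.json`. Field data are supplied via
`run_config(inputs = list(counts = ..., habitat = ..., prefs_habitat =
..., traits = ..., trees = ...))` with the same downstream behaviour.

See the vignette (`vignettes/ecodensity-methods.Rmd`) for the models,
their assumptions, the generator's design and its known limitations —
including why significance levels of pure-Brownian GLS fits to census
ratio estimates should be read with care.

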