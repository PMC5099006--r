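# firesync

Tools for reconstructing multi-century fire histories from crossdated
fire-scar records and testing how fire relates to climate variability and
to the human geography of a landscape.

`firesync` is aimed at fire ecologists and dendrochronologists working
with fire-scar networks — for example a coastal temperate rainforest
record of a few dozen plots where burning clusters near former
settlement sites and follows drought years. It covers the full analysis
chain:

* **FHX I/O** — read/write the Fire History Exchange plain-text format
  (`read_fhx()`, `write_fhx()`, `recorder_depth()`).
* **Composite chronology** — the two-tree fire-event rule, cohort
  verification of single-scar years, mean and point fire intervals,
  severity classing (`detect_fire_events()`,
  `verify_single_scar_events()`, `mean_fire_interval()`,
  `point_fire_interval()`).
* **Extreme climate events** — top-*k* phase years of reconstructed
  indices (PDSI, ENSO, PDO, AO) and rank-sum phase combinations
  (`select_extreme_years()`, `combine_phase_events()`).
* **Bivariate event analysis** — a one-directional, one-dimensional
  bivariate Ripley's K between fire years and climate-event years,

      K̂(t) = T/(n₁n₂) · Σ_f Σ_c w(f,t)⁻¹ · 1[0 ≤ f − c ≤ t],

  with Ripley-style edge correction and pointwise Monte Carlo envelopes
  (95%/99%, 1000 replicates) classifying each lag as synchronous,
  independent or asynchronous (`k_bivariate_1d()`, `bea_envelopes()`,
  `classify_synchrony()`, `randomization_sanity()`).
* **Frequency analysis** — G-tests of fire counts across climate phases
  against equal likelihood of burning in all years (`g_test()`,
  `build_contingency()`, `phase_combination_tests()`).
* **Spatial models** — Poisson GLMs of per-plot scar abundance and
  fire-event frequency with all-subsets AICc ranking, Akaike weights,
  evidence ratios, pseudo-R² and 95% confidence-set model averaging
  (`select_models()`, `model_average()`).
* **Synthetic data** — a calibrated generator of landscapes, AR(1)
  climate indices, ignition regimes and tree-level scar/cohort records
  with known ground truth (`synthetic_config()`,
  `simulate_fire_history()`), plus a one-call pipeline
  (`run_fire_history()`).

## Worked example

Simulate a record whose generating regime concentrates fire near former
habitation sites and after dry (negative-PDSI) years, then run the three
main analyses:

```r
library(firesync)

sim <- simulate_fire_history(synthetic_config(seed = 1))
chron <- detect_fire_events(sim$collection, min_trees = 2)
chron <- verify_single_scar_events(sim$collection, chron, sim$establishment)

sim$collection
#> FHX collection 'synthetic study area': 90 series, 74 scars, span 1225-2000
nrow(chron$events); mean_fire_interval(chron); point_fire_interval(sim$collection)
#> 16 events, MFI 33.2 yr, PFI 87.9 yr
```

Sixteen composite fire events survive the two-tree rule plus cohort
verification; on average one burns every 33 years somewhere in the study
area, while any single tree records fire only about every 88 years.

```r
pdsi_dry <- select_extreme_years(sim$climate$PDSI, "-", k = 50,
                                 period = common_period(sim$climate$PDSI,
                                                        end = 1893))
bea_envelopes(chron$events$year, pdsi_dry$event_years,
              domain = c(1300, 1893), t_max = 40, n_reps = 1000, seed = 42)
#> Bivariate event analysis: 16 fires vs 50 climate events on 1300-1893
#>   lags 0-40, 1000 Monte Carlo reps (uniform null), envelopes 95%, 99%
#>   synchronous at lags 0-40 years prior
```

The 50 driest years cluster in the windows before fire years far more
than the uniform null allows — the planted lag-1 drought forcing is
recovered as synchrony (dry years are autocorrelated, so the cumulative
K stays above the envelope across the lag range).

```r
sel <- select_models(sim$plots, "scar_abundance")
head(sel$table[, c("model", "K", "pseudo_R2", "dAICc", "weight", "ER")], 3)
#>                                                    model K pseudo_R2 dAICc weight   ER
#> 1                    dist_habitation_m + vegetation_type 5     0.448  0.00  0.232 1.00
#> 2 dist_habitation_m + dist_shoreline_m + vegetation_type 6     0.467  1.71  0.099 2.35
#> 3           dist_habitation_m + aspect + vegetation_type 6     0.461  2.16  0.079 2.95

model_average(sel)[1:2, ]
#>                term  estimate importance
#> 1       (Intercept)  1.971153      1.000
#> 2 dist_habitation_m -0.001538      1.000
```

Distance to the nearest habitation site appears in every confidence-set
model (relative importance 1.0) with a negative averaged coefficient
(−0.0015 per metre on the log scale, versus a generating value of
−0.002): scar abundance declines away from settlements, and AICc
selection ranks that predictor first — the spatial signature of
anthropogenic burning.

`run_fire_history(synthetic_config(seed = 1), out_dir = "out")` runs all
of the above plus the G-tests and writes CSVs and a reproducibility
manifest.

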