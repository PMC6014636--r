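# antestiarisk

Temperature-driven infestation risk mapping for the antestia bug
(*Antestiopsis thunbergii*), a pentatomid pest of Arabica coffee in the
east African highlands. Unusually for a coffee pest, antestia bug densities
*increase* with elevation: on the Mt. Kilimanjaro transect (1000-1700 m
asl) farm counts rise toward the cool top of the gradient, and the bug's
thermal biology -- development between 14.6 and 32.9 degrees C, population
growth only within about 19-25 degrees C -- marks it as a cool-adapted
tropical insect. This package provides the full analysis pipeline that
links those two observations and projects them under a warmer climate, for
entomologists and pest-risk modellers working with stage-structured
thermal data.

## What it computes

**Life tables.** Each immature stage carries a development-rate and a
mortality response, adults a fecundity and a senescence response. At
constant temperature `T` the package computes the six classical
parameters: gross and net reproductive rates (`GRR`, `R0`), mean
generation time (`T`), doubling time (`Dt`), intrinsic rate of increase
(`rm = ln(R0)/T`) and finite rate (`lambda = exp(rm)`).

**Annual risk indices** from a 365-day series of daily minima and maxima:

- `ERI = 1 - lethal_days/365` -- establishment risk; a lethal day is one
  on which at least one immature stage suffers total (100%) mortality,
  judged from the reconstructed hourly temperature cycle;
- `GI = sum_d 1/T_d` -- generations per year, accumulated day by day;
- `AI = sum_d log10(lambda_d)` -- activity; `10^AI` is the potential
  annual multiplication factor (AI = 4 means 10,000-fold).

**Spatial layer.** Station indices are interpolated over a DEM with a
thin-plate spline plus a linear elevation covariate (exact interpolation
at smoothing 0), written as plain-text rasters, sampled at points, and
compared current-vs-future with paired Wilcoxon signed-rank tests on 20
random points per 100-m elevation band.

**Survey layer.** Overdispersion-corrected Poisson regression (iterative
Pearson-dispersion weighting) of farm totals on elevation and season, with
single-step adjusted pairwise season contrasts, and predicted
bugs-per-tree density maps.

**Synthetic world.** Generators for the DEM, the nine-logger temperature
set (calibrated to the packaged logger summary table), the future-scenario
deltas and the 24-farm survey, so the whole pipeline runs and is tested
offline.

## Worked example

```r
library(antestiarisk)

models <- default_species_params()
check_species_constraints(models)
#>     development_limits        rm_window_19_25     mortality_89_at_30
#>                   TRUE                   TRUE                   TRUE
#>    generations_2.6_4.4 survival_optimum_22_24
#>                   TRUE                   TRUE

life_table_at(models, 22)
#> <life_table_params> GRR=11.182 R0=9.423 T=95.0 d Dt=29.3 d rm=0.0236 lambda=1.0239

dem      <- gen_transect_dem(seed = 1)
stations <- gen_station_temperatures(dem, seed = 1)
idx      <- indices_at_stations(stations, models)
idx[order(idx$elevation_m), c("station_id", "elevation_m", "eri", "gi", "ai")]
#>  station_id elevation_m   eri   gi   ai
#>          S1        1000 0.734 3.95 4.08
#>          S2        1088 0.770 3.87 3.97
#>          S3        1175 0.805 3.78 3.53
#>          S4        1263 0.833 3.67 3.29
#>          S5        1350 0.855 3.55 2.85
#>          S6        1437 0.882 3.42 2.48
#>          S7        1525 0.901 3.27 2.04
#>          S8        1612 0.921 3.10 1.57
#>          S9        1700 0.932 2.93 1.16
```

The three indices tell different stories along the gradient. ERI (the
fraction of the year every immature stage can survive) *rises* with
elevation -- hot afternoons at the transect bottom are lethal to nymphs --
and is the only index whose spatial pattern matches the observed field
counts. GI and AI *fall* with elevation because development is faster and
growth larger at the warmer bottom. An AI of 4.08 at the bottom station
means a potential multiplication of `growth_factor(4.08)` of about
12,000-fold per year if temperature were the only limit; natural enemies
(egg parasitism commonly 40-95%) keep realised densities far below it.

The survey side, on the cool-dry-season counts of the same synthetic
world:

```r
farms <- gen_farm_counts(dem, seed = 1)
fit_overdispersed_poisson(farms[farms$season == "cool_dry_2014", ],
                          count ~ elevation_m)
#> <dispersed_glm_fit> count ~ elevation_m | chi2 = 20.647, df = 22, dispersion = 2.727
#>          term  estimate        se      z         p
#> 1 (Intercept) -3.787441 1.3906417 -2.724 6.459e-03
#> 2 elevation_m  0.003936 0.0009534  4.129 3.649e-05
```

Counts increase significantly with elevation (z = 4.1): the regression
recovers the generating slope (0.0038 per m) well within one standard
error, with the standard errors already inflated for the overdispersion
(2.7) of the counts.

End-to-end runs (fixtures, maps, band tests, manifests) are available from
R via `make_fixtures()` / `run_all()` or from the shell via the installed
CLI:

```sh
Rscript inst/cli/antestia-risk make-fixtures --outdir study --seed 1
Rscript inst/cli/antestia-risk run-all --config study/config.yml
```

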