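# lurkit

Land use regression (LUR) modelling of fine particulate matter (PM2.5)
on a planar raster grid, with a seeded synthetic-study generator so the
whole pipeline is testable without external data.

LUR is the workhorse of exposure assessment where monitoring networks
are sparse: monthly monitor concentrations are regressed on GIS-derived
predictors, and the fitted equation

```
Y = β0 + β1·X1 + β2·X2 + … + βn·Xn
```

is then evaluated at every 50 m grid cell to map the pollutant surface.
The predictors `X` are circular-buffer summaries (summed land-use class
area in hectares and mean NDVI within radii of 250–5000 m), distances
to the nearest airport/road features, station meteorology interpolated
by inverse distance weighting, season indicators, and optionally
co-pollutants. Model development is *supervised* stepwise selection:
candidates are pre-screened by Spearman correlation against a-priori
effect directions, ranked by R², and admitted only while every
coefficient keeps p < 0.1, VIF < 3 and its expected sign. The chosen
model is validated by 10-fold cross-validation and turned into monthly,
yearly and pooled prediction maps with air-quality-guideline exceedance
summaries.

The package is organised as an analysis workflow: every computation
lives in the package (`R/`, compiled focal kernels in `src/`), and the
numbered drivers under `analysis/` run the study end to end, writing
tables and rasters to `results/`.

## Worked example

Simulate a 5 × 5 km study (17 monitors, 30 months, 40 candidate
predictors, a known 4-term ground truth with noise calibrated to a true
R² of 0.8), develop the model, and cross-validate it:

```r
library(lurkit)

study <- simulate_lur_study(7, grid = grid_spec(0, 0, 50, 100, 100),
                            n_months = 30)
study$design
#> <lur_design> 510 station-month rows, 40 candidate predictors
#>   candidates by class: distance=2, land_use=24, meteorology=4, ndvi=8, season=2

model <- supervised_stepwise(study$design)
model
#> <lur_model> 4 terms, n=510, R2=0.809, adj R2=0.808, RMSE=3.95
#>   intercept -78.006; gates: p < 0.1, VIF < 3
#>                name      beta   p_value   vif partial_r2
#> 1       Temperature   5.88933 1.364e-97 1.179     0.5815
#> 2 Residential_1000m   0.05266 1.154e-26 1.310     0.2026
#> 3  RelativeHumidity  -0.78500 6.888e-59 1.321     0.4049
#> 4        NDVI_1500m -76.07700 1.542e-26 1.600     0.2017

cv <- kfold_cv(study$design, model, k = 10, seed = 7)
sprintf("pooled 10-fold CV: R2 = %.3f, RMSE = %.2f ug/m3", cv$r2, cv$rmse)
#> "pooled 10-fold CV: R2 = 0.805, RMSE = 3.98 ug/m3"

study$truth$coefficients
#>       Temperature  RelativeHumidity        NDVI_1500m Residential_1000m
#>              5.80             -0.78            -77.00              0.05
```

The selection recovered exactly the four generating terms — higher
temperature and more residential area raise PM2.5, greenness and
humidity lower it — with coefficients close to truth, all retained
under the significance/collinearity/sign gates, and out-of-fold
performance tracking the in-sample fit.

The full study at the default 10 × 10 km scene runs as:

```sh
Rscript analysis/01_simulate.R    # scene, stations, design matrix
Rscript analysis/02_features.R    # buffer-predictor rasters
Rscript analysis/03_design.R      # candidate descriptive statistics
Rscript analysis/04_fit.R         # screen, rank, stepwise model report
Rscript analysis/05_validate.R    # 10-fold CV, prediction maps, exceedance
```

See `vignettes/lur-modelling.Rmd` for the model, the selection gates,
the generator's design and its limitations.

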