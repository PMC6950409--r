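#!/usr/bin/env Rscript
# Step 5 — validate and map.
#
# 10-fold cross-validation of the selected model (coefficients re-fit per
# fold; a full re-selection mode is also available), monthly prediction
# surfaces from the regression equation, period averages, and
# air-quality-guideline exceedance summaries.

suppressPackageStartupMessages(library(lurkit))

study <- readRDS("scratch/study.rds")
model <- readRDS("scratch/model.rds")
dir.create("results/rasters", recursive = TRUE, showWarnings = FALSE)

cv <- kfold_cv(study$design, model, k = 10, seed = 2016)
print(cv)
cat(sprintf("In-sample R2 = %.3f vs pooled out-of-fold R2 = %.3f, RMSE = %.2f\n",
            model$r2, cv$r2, cv$rmse))
write.csv(cv$predictions, "results/cv_predictions.csv", row.names = FALSE)

# monthly surfaces: static land-use terms broadcast, NDVI terms vary by
# month, meteorology terms interpolated to the grid by IDW
monthly_surfaces <- list()
months <- names(study$ndvi$composites)
term_class <- candidate_table(model$terms$name)$var_class

for (key in months) {
  rasters <- list()
  for (i in seq_len(nrow(model$terms))) {
    nm <- model$terms$name[i]
    parsed <- parse_feature_name(nm)
    if (term_class[i] %in% c("land_use")) {
      mask <- feature_raster(study$grid,
                             (study$landuse$raster$values ==
                                study$landuse$classes[[parsed$layer]]) * 1,
                             name = parsed$layer)
      fr <- focal_stat(mask, parsed$radius, "sum", name = nm)
      fr$values <- fr$values * study$grid$cell_size^2 / 1e4
      rasters[[nm]] <- fr
    } else if (term_class[i] == "ndvi") {
      rasters[[nm]] <- focal_stat(study$ndvi$composites[[key]],
                                  parsed$radius, "mean", name = nm)
    } else if (term_class[i] == "distance") {
      lay <- sub("_nearest$", "", nm)
      rasters[[nm]] <- distance_raster(
        study$landuse$vectors[study$landuse$vectors$layer == lay, ],
        study$grid, name = nm)
    } else if (term_class[i] == "meteorology") {
      raw <- c(Temperature = "temperature", RelativeHumidity = "relative_humidity",
               WindSpeed = "wind_speed", Rainfall = "rainfall", UV = "uv")[[nm]]
      ym <- as.integer(strsplit(key, "-")[[1]])
      sub <- study$meteo[study$meteo$variable == raw, ]
      agg <- do.call(rbind, lapply(split(sub, sub$station_id), function(s) {
        m <- monthly_mean(s$date, s$value)
        m <- m[m$year == ym[1] & m$month == ym[2], ]
        if (nrow(m)) data.frame(x = s$x[1], y = s$y[1], value = m$value)
      }))
      rasters[[nm]] <- idw_surface(agg, study$grid, name = nm)
    } else {  # season dummy: constant 0/1 layer per month
      mo <- as.integer(substr(key, 6, 7))
      on <- season_dummies(mo)[[nm]]
      rasters[[nm]] <- feature_raster(study$grid,
                                      matrix(on, study$grid$n_rows,
                                             study$grid$n_cols), name = nm)
    }
  }
  monthly_surfaces[[key]] <- predict_surface(model, rasters, period = key,
                                             floor_at_zero = TRUE)
}

pooled <- period_average(monthly_surfaces, "pooled")
write_raster(pooled, "results/rasters/pm25_pooled.csv")
for (yr in unique(substr(months, 1, 4))) {
  yearly <- period_average(monthly_surfaces[substr(months, 1, 4) == yr], yr)
  write_raster(yearly, sprintf("results/rasters/pm25_%s.csv", yr))
}

cat(sprintf("Pooled 2016-2018 surface: range %.1f - %.1f ug/m3\n",
            min(pooled$values), max(pooled$values)))
ex <- exceedance_summary(pooled)
print(ex, row.names = FALSE)
write.csv(ex, "results/exceedance.csv", row.names = FALSE)
cat("Wrote prediction surfaces, CV table and exceedance summary to results/\n")
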