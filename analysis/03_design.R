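#!/usr/bin/env Rscript
# Step 3 — inspect the station-month design matrix.
#
# The design was assembled in step 1 (monthly aggregation of daily
# meteorology, IDW interpolation to the monitors, monthly NDVI buffers,
# static land-use buffers, season dummies). This step summarises it the
# way a descriptive-statistics table would report the candidates.

suppressPackageStartupMessages(library(lurkit))

design <- read_design("results/design.csv")
print(design)

num <- design$data[design$candidates$name]
summary_tab <- data.frame(
  variable = names(num),
  class = design$candidates$var_class,
  prior = design$candidates$direction_prior,
  min = round(vapply(num, min, numeric(1)), 3),
  max = round(vapply(num, max, numeric(1)), 3),
  sd = round(vapply(num, sd, numeric(1)), 3),
  median = round(vapply(num, median, numeric(1)), 3)
)
write.csv(summary_tab, "results/candidate_summary.csv", row.names = FALSE)
print(head(summary_tab, 12), row.names = FALSE)
cat("...\nWrote results/candidate_summary.csv (",
    nrow(summary_tab), "candidates )\n")
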