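#!/usr/bin/env Rscript
# Stage 2: sample construction. Windows ages to [0.5, 19.5), trims
# implausible and outlying values, keeps one observation per individual
# per age group, drops cohorts contributing < 50 measurements,
# residualizes height on birth year (+ exact age in univariate mode) and
# cohort within strata, and assembles complete pairs.

suppressPackageStartupMessages(library(acegrowth))

cohort <- read.csv("scratch/cohort.csv", stringsAsFactors = FALSE)
dir.create("results/analysis", showWarnings = FALSE, recursive = TRUE)

for (mode in c("univariate", "moderation")) {
  pre <- preprocess_measurements(cohort, mode = mode)
  out <- sprintf("scratch/pairs_%s.csv", mode)
  write.csv(pre$pairs, out, row.names = FALSE)
  cat(sprintf("[%s] %d pairs -> %s\n", mode, nrow(pre$pairs), out))
  for (nm in names(pre$log)) cat(sprintf("  %-20s %d\n", nm, pre$log[[nm]]))
  cat(sprintf("  outliers removed: %d (%.3f%%)\n",
              pre$trim_report$n_removed,
              100 * pre$trim_report$fraction_removed))
  if (mode == "univariate")
    jsonlite::write_json(pre$trim_report["fraction_removed"],
                         "results/analysis/outlier_report.json",
                         auto_unbox = TRUE)
}
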