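#!/usr/bin/env Rscript
# Stage 5: gene-by-age interaction models on same-sex pairs. Path
# coefficients (and zygosity-specific means) are quadratics in age.
# Comparisons: equating the sexes' 15-parameter blocks (df 15), dropping
# the quadratic path terms within each sex (df 3), and equating the three
# regional blocks within each sex (df 30).

suppressPackageStartupMessages(library(acegrowth))

pairs <- read.csv("scratch/pairs_moderation.csv", stringsAsFactors = FALSE)
dir.create("results/analysis", showWarnings = FALSE, recursive = TRUE)

fit_sex <- fit_moderation(pairs, grouping = "sex")
fit_eq <- fit_moderation(pairs, grouping = "sex", equate_groups = TRUE)
sex_test <- lrt(fit_sex, fit_eq)
cat(sprintf("sex equality: delta -2LL = %.1f, delta df = %d, p = %.3g\n",
            sex_test$delta_minus2LL, sex_test$delta_df, sex_test$p_value))

cmp <- data.frame(comparison = "sex_equality",
                  delta_minus2LL = sex_test$delta_minus2LL,
                  delta_df = sex_test$delta_df, p = sex_test$p_value)

for (s in c("M", "F")) {
  ss <- pairs[substr(pairs$group, 3, 3) == s, ]
  quad <- fit_moderation(ss, grouping = "pooled")
  lin <- fit_moderation(ss, grouping = "pooled", path_degree = 1)
  t <- lrt(quad, lin)
  cat(sprintf("[%s] quadratic path terms: delta -2LL = %.1f, df = %d, p = %.3g\n",
              s, t$delta_minus2LL, t$delta_df, t$p_value))
  cmp <- rbind(cmp, data.frame(
    comparison = paste0("quadratic_terms_", s),
    delta_minus2LL = t$delta_minus2LL, delta_df = t$delta_df, p = t$p_value))
  free_reg <- fit_moderation(ss, grouping = "sex_region")
  eq_reg <- fit_moderation(ss, grouping = "sex_region",
                           equate_groups = TRUE)
  tr <- lrt(free_reg, eq_reg)
  cat(sprintf("[%s] region equality: delta -2LL = %.1f, df = %d, p = %.3g\n",
              s, tr$delta_minus2LL, tr$delta_df, tr$p_value))
  cmp <- rbind(cmp, data.frame(
    comparison = paste0("region_equality_", s),
    delta_minus2LL = tr$delta_minus2LL, delta_df = tr$delta_df,
    p = tr$p_value))
}
write.csv(cmp, "results/analysis/moderation_comparisons.csv",
          row.names = FALSE)

curves <- do.call(rbind, lapply(names(fit_sex$params), function(g) {
  vc <- variance_curves(fit_sex$params[[g]])
  cbind(sex = g, vc)
}))
write.csv(curves, "results/analysis/variance_curves.csv", row.names = FALSE)
for (g in names(fit_sex$params))
  cat(sprintf("[%s] additive genetic variance peaks at age %.1f\n", g,
              attr(variance_curves(fit_sex$params[[g]]), "a_peak_age")))
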