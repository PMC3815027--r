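#!/usr/bin/env Rscript
# Step 3 — group statistics: control vs t(13;17).
#
# Reproduces the study's comparisons on the measured records from step 2:
# pooled-variance Student tests on per-nucleus counts and positions,
# chi-squared homogeneity tests on category distributions, and the
# goodness-of-fit of the carrier pair categories against the Mendelian
# segregation expectation (75% colocalized-or-adjacent / 25% distant).

suppressPackageStartupMessages(library(spermfish3d))

ctrl <- read.csv("results/measurements_control.csv", stringsAsFactors = FALSE)
carr <- read.csv("results/measurements_t1317.csv", stringsAsFactors = FALSE)

report <- compare_populations(ctrl, carr,
                              measures = c("n_telomere_clusters",
                                           "n_ac6_clusters", "n_rs2a_clusters",
                                           "n_associations",
                                           "ssc13_ap_pct", "ssc13_ml_pct",
                                           "ssc17_ap_pct", "ssc17_ml_pct",
                                           "gonosome_ap_pct", "gonosome_ml_pct",
                                           "ssc13_border_um", "ssc17_border_um",
                                           "pair_category",
                                           "ssc13_morphology",
                                           "ssc17_morphology"))
write.csv(report, "results/comparison.csv", row.names = FALSE)

fmt <- function(x) ifelse(is.na(x), "", formatC(x, digits = 3, format = "g"))
lines <- c(
  sprintf("Control vs t(13;17) comparison (%d tests, alpha = %.2f)",
          attr(report, "n_tests"), attr(report, "alpha")),
  sprintf("%-20s %-9s %8s %8s %9s %9s %5s",
          "measure", "test", "mean_ctl", "mean_car", "statistic", "p", "sig"),
  sprintf("%-20s %-9s %8s %8s %9s %9s %5s",
          report$measure, report$test, fmt(report$mean_a), fmt(report$mean_b),
          fmt(report$statistic), fmt(report$p_value),
          ifelse(report$significant, "*", "")))

# carrier categories against the segregation-model expectation
obs <- category_counts(carr$pair_category)
expd <- expected_category_proportions(segregation_params(0.5, 0.5))
gof <- chi2_goodness_of_fit(
  c(obs[["colocalized"]] + obs[["adjacent"]], obs[["distant"]]),
  unname(expd))
lines <- c(lines, "",
  sprintf("Carrier pair categories: %d colocalized, %d adjacent, %d distant",
          obs[["colocalized"]], obs[["adjacent"]], obs[["distant"]]),
  sprintf("Segregation model expects %.0f%% proximal / %.0f%% distant",
          100 * expd[["proximal"]], 100 * expd[["distant"]]),
  sprintf("Goodness of fit: chi2 = %.3f, df = %d, p = %.3f %s",
          gof$statistic, gof$df, gof$p_value,
          if (gof$p_value >= 0.05) "(not different from expectation)"
          else "(deviates from expectation)"))

writeLines(lines, "results/comparison.txt")
cat(paste(lines, collapse = "\n"), "\n")
cat("\nReport written to results/comparison.csv and results/comparison.txt\n")
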