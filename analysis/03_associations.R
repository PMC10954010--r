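#!/usr/bin/env Rscript
# Step 3 — association between the index and its components.
#
# Cross-tabulates each component indicator against the Food Security Index
# with Pearson chi-square tests (column-percent layout), and reproduces the
# within-MFS coping-by-PWFE breakdown: the published version from the
# printed counts as a desk check, then the synthetic survey's own version.

suppressPackageStartupMessages(library(cariseg))

scored <- read_survey("results/survey_scored.csv")

assoc <- suppressWarnings(association_report(scored))
for (nm in names(assoc)) {
  tab <- assoc[[nm]]
  cat("\n==", toupper(nm), "vs FSI ==\n")
  print(tab)
  write_crosstab(tab, file.path("results",
                                paste0("assoc_", nm, "_by_fsi.csv")),
                 by = "col")
  message(nm, ": X^2 = ", round(tab$statistic, 1), ", df = ", tab$df,
          ", p ", ifelse(tab$p.value < 0.001, "< 0.001",
                         paste("=", signif(tab$p.value, 3))))
}

cat("\n== published MFS coping x PWFE table (printed counts) ==\n")
t4 <- table4_fixture()
print(t4)
cat("row percentages:\n")
print(percent(t4, "row"))
cat(sprintf("MFS households with PWFE > 50%%: %.1f%%\n",
            100 * sum(t4$col_totals[2:4]) / t4$total))
write_crosstab(t4, "results/published_mfs_coping_by_pwfe.csv", by = "row")

cat("\n== synthetic MFS coping x PWFE table ==\n")
mfs <- scored[scored$fsi_label == "MFS", ]
t4_syn <- suppressWarnings(crosstab(mfs, "csi_cat", "pwfe_cat"))
print(t4_syn)
write_crosstab(t4_syn, "results/synthetic_mfs_coping_by_pwfe.csv",
               by = "row")

message("wrote results/assoc_*.csv and the two MFS cross-tabs")
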