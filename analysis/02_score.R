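#!/usr/bin/env Rscript
# Step 2 — score the survey and build the CARI console.
#
# Complete-cases the raw survey (a household needs every food-day count,
# a usable spending pair and every coping answer), computes the three
# component indicators (FCS, PWFE, CSI), combines them into the four-level
# Food Security Index, and writes the scored survey plus the reporting
# console and the socio-demographic summary.

suppressPackageStartupMessages(library(cariseg))

sv <- read_survey("results/survey_raw.csv")
message("read ", nrow(sv), " households")

cc <- complete_cases(sv)
message("complete cases: ", attr(cc, "retained"),
        " (dropped ", attr(cc, "dropped"), " with missing indicator fields)")

scored <- classify_dataset(compute_indicators(cc))
write_survey(scored, "results/survey_scored.csv")

demo <- describe(scored)
print(demo)
utils::write.csv(demo$frequencies, "results/demographics.csv",
                 row.names = FALSE)

cons <- build_console(scored)
print(cons)
utils::write.csv(as.data.frame(cons), "results/cari_console.csv",
                 row.names = FALSE)

message("FSI counts: ",
        paste(names(table(scored$fsi_label)), table(scored$fsi_label),
              sep = "=", collapse = ", "))
message("wrote results/survey_scored.csv, results/cari_console.csv, ",
        "results/demographics.csv")
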