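#!/usr/bin/env Rscript
# Step 1 — simulate the household survey.
#
# Draws a synthetic survey with the study's design: 2,041 households split
# roughly evenly between urban and non-urban parishes, head-of-household
# demographics matching the published descriptives, and the three CARI
# indicator categories coupled to a latent severity mix of 9/69/18/4
# percent.  A small share of records (83/2041) is left incomplete, as in
# the field data.  Raw responses only — scoring happens in step 2.

suppressPackageStartupMessages(library(cariseg))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 20240817L
dir.create("results", showWarnings = FALSE)

params <- default_params()
sv <- generate(params, seed = seed)
write_survey(sv, "results/survey_raw.csv")

message("simulated ", nrow(sv), " households (seed ", seed, ")")
message("urban share: ", round(mean(sv$area == "urban"), 3))
cfg <- indicator_config()
n_incomplete <- nrow(sv) - attr(complete_cases(sv), "retained")
message("incomplete records: ", n_incomplete)
message("wrote results/survey_raw.csv")
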