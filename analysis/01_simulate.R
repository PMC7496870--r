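#!/usr/bin/env Rscript
# Step 1: generate the study data for the workflow.
#
# Simulates a coding sheet at the scale of the comparative AGL literature
# (~66 articles, ~160 effects nested within them) in its *raw* form: one row
# per test session and condition arm, with per-paradigm summary statistics,
# chance levels, CI-only reporting for a fraction of studies, and
# familiarity-interpreted looking-time effects flagged for re-signing.

library(aglmeta)

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

cfg <- synthetic_config(seed = 1)
records <- simulate_raw_studies(cfg)
targets <- attr(records, "effects")

write_coding_sheet(records, "results/data/coding_sheet_raw.csv")
write_coding_sheet(targets, "results/data/effects_true.csv")

cat(sprintf("simulated %d raw study records (%d articles), true overall effect mu = %.2f\n",
            length(records), length(unique(targets$article_id)), cfg$mu))
cat(sprintf("paradigm families: %d chance-comparison, %d paired-contrast\n",
            sum(targets$paradigm %in% agl_paradigms$paradigm[agl_paradigms$family == "chance"]),
            sum(targets$paradigm %in% agl_paradigms$paradigm[agl_paradigms$family == "paired"])))
cat("wrote results/data/coding_sheet_raw.csv and results/data/effects_true.csv\n")
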