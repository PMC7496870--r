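#!/usr/bin/env Rscript
# Step 4: which design features move the effect size?
#
# Omnibus F-tests for every coded moderator on the full dataset, cell-means
# subgroup estimates per animal class, and per-class moderator tables with
# constant moderators skipped (e.g. modality in classes tested in a single
# modality).

library(aglmeta)

ds <- read_coding_sheet("results/data/effects_harmonized.csv")
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

mt <- moderator_table(ds)
write.table(mt, "results/tables/moderator_tests.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("full-dataset moderator F-tests:\n")
print(transform(mt, F = round(F, 3), p = signif(p, 3)), row.names = FALSE)
for (m in names(attr(mt, "skipped"))) {
  cat("  skipped:", m, "-", attr(mt, "skipped")[m], "\n")
}

sub <- subgroup_effects(ds, "animal_class")
write.table(sub, "results/tables/subgroup_estimates.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("\nper-class weighted effects:\n")
print(transform(sub[, c("term", "estimate", "se", "ci_lower", "ci_upper", "p")],
                estimate = round(estimate, 3)), row.names = FALSE)

for (lev in sort(unique(ds$animal_class))) {
  subset_ds <- filter_subset(ds, function(d) d$animal_class == lev)
  mods <- setdiff(moderator_names(ds),
                  c("animal_class", "animal_species", "human_vs_nonhuman",
                    skipped_moderators(subset_ds)))
  smt <- moderator_table(subset_ds, mods)
  write.table(smt, sprintf("results/tables/moderator_tests_%s.tsv", lev),
              sep = "\t", row.names = FALSE, quote = FALSE)
  cat(sprintf("\n%s (%d effects): %d moderators tested, %d skipped as constant\n",
              lev, nrow(subset_ds), nrow(smt),
              length(skipped_moderators(subset_ds))))
}
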