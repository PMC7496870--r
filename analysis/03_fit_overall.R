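#!/usr/bin/env Rscript
# Step 3: the overall evidence of learning.
#
# Fits the intercept-only three-level random-effects model (effects nested
# in articles) by REML with t-method inference, and tests residual
# heterogeneity with Cochran's Q.

library(aglmeta)

ds <- read_coding_sheet("results/data/effects_harmonized.csv")
fit <- reml_fit(ds)
q <- cochran_q(ds)

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
write.table(coefficient_tests(fit), "results/tables/overall_model.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(data.frame(k = fit$k, Q = q$Q, Q_df = q$df, Q_p = q$p,
                       sigma2_article = fit$sigma2_article,
                       sigma2_study = fit$sigma2_study),
            "results/tables/heterogeneity.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

cat(sprintf("overall weighted effect: %.3f (SE %.3f, 95%% CI [%.3f, %.3f], t(%d), p = %.2g)\n",
            fit$beta[1], fit$se[1], fit$ci_lower[1], fit$ci_upper[1], fit$df,
            fit$p_values[1]))
cat(sprintf("variance components: article %.3f, study-within-article %.3f\n",
            fit$sigma2_article, fit$sigma2_study))
cat(sprintf("Cochran's Q(%d) = %.2f, p = %.2g -> %s\n", q$df, q$Q, q$p,
            if (q$p < 0.05) "heterogeneity beyond sampling error; moderators worth testing"
            else "no detectable heterogeneity"))
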