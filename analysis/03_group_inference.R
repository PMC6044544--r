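#!/usr/bin/env Rscript
# Step 3: group statistics on the score profile.
#
# Per time point, a one-sample t test asks whether the memory is
# detectably represented (score > 0 across subjects); across time points,
# a repeated-measures ANOVA (Mauchly-checked, Greenhouse-Geisser
# corrected when sphericity fails) tests whether representation strength
# changes with memory age.

suppressPackageStartupMessages(library(memrep))

scores <- read_scores_tsv("results/scores_exp1.tsv")

detect <- do.call(rbind, lapply(colnames(scores), function(tp) {
  tt <- one_sample_t(scores[, tp])
  data.frame(time_point_months = as.numeric(tp), mean = tt$mean,
             t = tt$t, df = tt$df, p = tt$p)
}))
detect$p_bonferroni <- pmin(1, detect$p * nrow(detect))
write.table(detect, "results/detectability.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

av <- rm_anova(scores)
anova_tab <- data.frame(effect = "time_point", F = av$F, df1 = av$df1,
                        df2 = av$df2, p = av$p, gg_epsilon = av$epsilon,
                        mauchly_W = av$mauchly_W, mauchly_p = av$mauchly_p,
                        sphericity_violated = av$sphericity_violated)
write.table(anova_tab, "results/rm_anova.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("per-time-point detectability:\n")
print(detect, digits = 3)
cat("\nrepeated-measures ANOVA on memory age:\n")
print(av)
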