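#!/usr/bin/env Rscript
# Inferential layer beyond the per-experiment ANOVAs:
#  - a-priori power: minimum N for the 5-level repeated-measures design
#    at the reference effect size;
#  - lasting-impairment test: paired t of the crowding sd at the longest
#    SOA against the uncrowded baseline sd;
#  - similarity: two-way mixed ANOVA (SOA within, similarity between) on
#    each parameter across the two crowding groups.

suppressPackageStartupMessages(library(maskmix))

# power analysis at the reference effect size F(4,56) = 6.05
eta <- partial_eta_sq(6.05, 4, 56)
n_min <- min_sample_size(df1 = 4, eta_p2 = eta, alpha = 0.05,
                         power_target = 0.95)
cat(sprintf("reference eta_p2 = %.3f -> minimum N = %d (power %.3f; %.3f at N-1)\n",
            eta, n_min, rm_anova_power(n_min, 4, eta),
            rm_anova_power(n_min - 1, 4, eta)))

# crowding outlasts the longest SOA: sd at 475 ms vs uncrowded baseline
fits2 <- read.csv("results/exp2/fits.csv")
long <- fits2[fits2$model == "two_misreport" & fits2$condition == "475", ]
base <- fits2[fits2$model == "standard", ]
m <- merge(long[, c("participant_id", "sd")],
           base[, c("participant_id", "sd")],
           by = "participant_id", suffixes = c("_475", "_baseline"))
tt <- paired_t_cohens_d(m$sd_475, m$sd_baseline)
cat(sprintf("sd at 475 ms vs baseline: t(%d) = %.3f, p = %.4f, d = %.2f (mean diff %.2f deg)\n",
            tt$df, tt$t, tt$p, tt$d, tt$mean_diff))

# target-distractor similarity effect on temporal crowding
fits2s <- read.csv("results/exp2_similar/fits.csv")
groups <- rbind(
  transform(fits2[fits2$model == "two_misreport", ], similarity = "dissimilar"),
  transform(fits2s[fits2s$model == "two_misreport", ],
            participant_id = paste0("S", participant_id),
            similarity = "similar"))
rows <- lapply(c("sd", "g", "beta1", "beta2"), function(par) {
  d <- data.frame(participant = groups$participant_id,
                  within = as.numeric(groups$condition),
                  between = groups$similarity, value = groups[[par]])
  out <- mixed_anova(d)
  out$parameter <- par
  b <- out[out$effect == "between", ]
  cat(sprintf("%-6s similarity F(%d,%d) = %6.2f, p = %.3f, eta_p2 = %.3f\n",
              par, b$df1, b$df2, b$F, b$p, b$eta_p2))
  out
})

dir.create("results/pooled", recursive = TRUE, showWarnings = FALSE)
write.csv(do.call(rbind, rows), "results/pooled/similarity_anova.csv",
          row.names = FALSE)
stats <- data.frame(quantity = c("min_sample_size", "t_sd475_vs_baseline",
                                 "p_sd475_vs_baseline", "cohens_d"),
                    value = c(n_min, tt$t, tt$p, tt$d))
write.csv(stats, "results/pooled/power_and_ttest.csv", row.names = FALSE)
cat("done: similarity ANOVA and power/t-test tables under results/pooled/\n")
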