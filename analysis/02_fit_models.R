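#!/usr/bin/env Rscript
# Preprocess each synthetic experiment and fit the two-misreport mixture
# model to every participant x condition cell (standard model on the
# unmasked baseline), then run the per-parameter one-way repeated-measures
# ANOVAs over SOA. Writes fits.csv, anova.csv and manifest.json per
# experiment under results/<exp>/.

suppressPackageStartupMessages(library(maskmix))

for (nm in c("exp1", "exp2", "exp2_similar", "exp3")) {
  trials <- read_trials(file.path("results/data", nm, "trials.csv"))
  res <- run_pipeline(trials = trials, n_starts = 10, seed = 20,
                      outdir = file.path("results", nm))
  sig <- res$anova[res$anova$p < 0.05, "parameter"]
  cat(sprintf("%-13s %d cells fitted; SOA effect significant for: %s\n",
              nm, nrow(res$fits),
              if (length(sig)) paste(sig, collapse = ", ") else "none"))
}
cat("done: per-cell fits and ANOVA tables under results/\n")
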