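#!/usr/bin/env Rscript
# Step 1 — simulate a demonstration household survey.
#
# Emulates the structure of a stratified MCH household survey: latent wealth
# driving binary asset ownership, three sampling strata (one oversampled, so
# the design is not self-weighting and design weights are unequal), an
# education tier, and three binary indicators whose prevalence is graded by
# wealth.  Writes the microdata fixture (households.csv, individuals.csv)
# and the ground-truth sidecar (truth.json) under results/fixtures/demo/.

suppressPackageStartupMessages(library(mchequity))

cfg <- sim_config(n_households = 10000, seed = 2026)
print(cfg)

survey <- generate_survey(cfg)
print(survey)

paths <- write_fixture(survey, "results/fixtures/demo")
cat("Wrote fixture files:\n")
for (p in paths) cat("  ", p, "\n")

prev <- sapply(cfg$indicators_spec$name, function(nm)
  weighted_prevalence(survey$individuals[[nm]], survey$individuals$weight)$percent)
cat("\nWeighted indicator prevalences (%):\n")
print(round(prev, 2))
cat("\nDesign weights by stratum (normalized to mean 1):\n")
print(tapply(survey$households$weight, survey$households$stratum,
             function(w) round(unique(w), 3)))
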