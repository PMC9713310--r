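#!/usr/bin/env Rscript
# Stage 1 — simulate the colonization study.
#
# Emulates the full sampling design (9 treatment x phenophase variants, 3
# replications, 15 root segments each scored in 15 microscopic fields on a
# 10 x 10 grid) from the shipped variant scenarios, and writes the long
# observation table: one row per microscopic field, 6,075 rows for 405
# mycorrhizal maps.

library(mycomaps)

seed <- 20260925L
dir.create("results", showWarnings = FALSE)

design <- study_design()
scenarios <- read_scenarios(system.file("extdata", "scenarios.yaml",
                                        package = "mycomaps"))
study <- generate_study(scenarios, design, seed = seed)

write_observation_table(study$observations, "results/observations.tsv")

cat("Simulated", length(study$maps), "maps /",
    nrow(study$observations), "observations for",
    length(design$variants), "variants\n")
cat("Wrote results/observations.tsv\n")
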