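#!/usr/bin/env Rscript
# Stage 3 — colonization strategies.
#
# Classifies every map by the intensity / arbuscule-vesicle thresholds
# (resistance < 10%, proliferative 10-25%, transfer > 25% with A/V > 1,
# storage > 25% with A/V <= 1), profiles the strategy shares per variant,
# and counts field-level strategies along every root segment.

library(mycomaps)

design <- study_design()
maps <- parse_observation_table("results/observations.tsv", design)
metrics <- read.delim("results/metrics.tsv")

labelled <- classify_metrics_table(metrics)
write.table(labelled, "results/strategies.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

profile <- strategy_profile(labelled$strategy, labelled$variant)
write.table(profile, "results/strategy_profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Strategy shares (% of maps) per variant:\n")
print(cbind(profile["group"], round(profile[c("Rs", "Ps", "Ts", "Ss")], 1)))

seg <- segment_strategy_counts(maps)
write.table(seg, "results/segment_strategy_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Wrote results/strategies.tsv, results/strategy_profile.tsv,",
    "results/segment_strategy_counts.tsv\n")
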