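#!/usr/bin/env Rscript
# Stage 2 — colonization parameters.
#
# Reads the simulated observation table back through the parser (so this
# stage works identically on any table in the same format), computes the
# per-map parameters (frequency, intensity, structure shares,
# non-mycorrhizal area, degree and the two ratios) and the per-variant
# mean / s.e. / median summary.

library(mycomaps)

design <- study_design()
maps <- parse_observation_table("results/observations.tsv", design)
metrics <- metrics_long_table(maps)
write.table(metrics, "results/metrics.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

agg <- aggregate_group(metrics, "variant")
write.table(agg, "results/metrics_by_variant.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Computed metrics for", nrow(metrics), "maps\n")
wide <- with(subset(agg, parameter %in% c("F", "I", "Arb", "Ves", "DC")),
             tapply(mean, list(group, parameter), identity))
print(round(wide[, c("F", "I", "Arb", "Ves", "DC")], 2))
ok <- with(agg, abs(mean[parameter == "nonM"] -
                      (100 - mean[parameter == "I"])))
cat("complement identity max |mean nonM - (100 - mean I)|:",
    format(max(ok), digits = 3), "\n")
cat("Wrote results/metrics.tsv, results/metrics_by_variant.tsv\n")
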