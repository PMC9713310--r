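#!/usr/bin/env Rscript
# Stage 5 — group statistics.
#
# One-way ANOVA over the nine variants with LSD letters per parameter, the
# Pearson correlation matrix between parameters (with ns flags), the
# arbuscule-vesicle co-occurrence pairs, and PCA ordinations (per-map
# scores, loadings, per-variant centroids) for the untreated and treated
# arms, each anchored by the native A0_B1 profile.

library(mycomaps)

metrics <- read.delim("results/metrics.tsv")

tab <- anova_lsd_table(metrics, "variant")
write.table(tab, "results/anova_lsd.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
itab <- subset(tab, parameter == "I")
cat("Intensity by variant (mean +/- s.e., LSD letters at p < 0.05):\n")
print(data.frame(variant = itab$group,
                 mean = round(itab$mean, 2),
                 se = round(itab$se, 2),
                 letters = itab$letters), row.names = FALSE)
cat(sprintf("Intensity ANOVA: F(%d, %d) = %.2f, p %s\n",
            8, nrow(metrics) - 9, itab$F[1],
            if (itab$p[1] < 0.001) "< 0.001" else sprintf("= %.3f",
                                                          itab$p[1])))

cm <- pearson_matrix(metrics)
print(cm)
write.table(cbind(parameter = rownames(cm$r), as.data.frame(cm$r)),
            "results/correlations.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("r(I, nonM) =", cm$r["I", "nonM"],
    " (structural identity nonM = 100 - I)\n")

co <- cooccurrence_pairs(metrics)
write.table(co, "results/cooccurrence.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

for (arm in c("untreated", "treated")) {
  keep <- metrics$treatment %in% c("A0", if (arm == "untreated") "A1"
                                   else "A2")
  pca <- pca_ordination(metrics[keep, ], group = "variant")
  write.table(pca$centroids,
              sprintf("results/pca_centroids_%s.tsv", arm), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("PCA (%s arm): PC1 %.1f%%, PC2 %.1f%% of variance\n", arm,
              100 * pca$explained[1], 100 * pca$explained[2]))
}
cat("Wrote results/anova_lsd.tsv, correlations.tsv, cooccurrence.tsv,",
    "pca_centroids_*.tsv\n")
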