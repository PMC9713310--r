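#!/usr/bin/env Rscript
# Stage 6 — stage-to-stage forecast models.
#
# For each treatment arm (untreated A1 and treated A2, each anchored by
# the native A0_B1 first-stage profile) and each parameter at stages B2-B5,
# a stepwise AIC-selected linear model on all parameters of all earlier
# stages. Destructively-sampled stages are paired by rank of colonization
# degree within replicate (n = 45 per stage).

library(mycomaps)

metrics <- read.delim("results/metrics.tsv")

all_tabs <- list()
for (arm in c("untreated", "treated")) {
  models <- build_stage_models(metrics, arm = arm, pairing = "rank")
  tab <- forecast_models_table(models)
  tab$arm <- arm
  all_tabs[[arm]] <- tab

  cat("\n==", arm, "arm ==\n")
  for (key in c("B2_F", "B2_I", "B5_F", "B5_I")) {
    m <- models[[key]]
    terms <- if (length(m$coefficients) == 0) "(intercept only)" else
      paste(sprintf("%+.3g %s", m$coefficients, names(m$coefficients)),
            collapse = " ")
    cat(sprintf("%s = %.3g %s   [AIC %.1f, %d step(s)]\n", key,
                m$intercept, terms, m$aic, nrow(m$trace) - 1))
  }
}

write.table(do.call(rbind, all_tabs), "results/forecast_models.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nWrote results/forecast_models.tsv (all responses, both arms)\n")
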