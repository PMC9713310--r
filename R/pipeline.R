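# Sequential orchestration: simulate -> metrics -> classify -> extract ->
# stats -> forecast, with every convention resolved explicitly and recorded
# in a run manifest so a run is reproducible from the manifest alone.

#' Assemble a pipeline configuration
#'
#' All analysis conventions are resolved here, so the manifest never
#' carries silent defaults.
#'
#' @param design A [study_design()].
#' @param scenarios Named list of [colonization_params()] (or a YAML path
#'   for [read_scenarios()]).
#' @param seed Master integer seed.
#' @param out_dir Output directory (created if absent).
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "metrics", "classify", "extract", "stats",
#'   "forecast")`.
#' @param av_policy Zero-vesicle policy for the arbuscule/vesicle ratio.
#' @param thresholds Strategy intensity cut points.
#' @param ranking Median-triplet ranking parameter.
#' @param pairing Forecast stage-pairing mode.
#' @param render Write PNG renderings of the extracted median-scheme maps?
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(design = study_design(),
                            scenarios = default_scenarios(),
                            seed = 1L,
                            out_dir = "results",
                            stages = c("simulate", "metrics", "classify",
                                       "extract", "stats", "forecast"),
                            av_policy = "zero",
                            thresholds = c(10, 25),
                            ranking = "DC",
                            pairing = "rank",
                            render = FALSE) {
  if (is.character(scenarios)) scenarios <- read_scenarios(scenarios)
  stages <- match.arg(stages, several.ok = TRUE)
  if (!"simulate" %in% stages) {
    stop("the pipeline starts from synthetic data; 'simulate' must be ",
         "enabled", call. = FALSE)
  }
  if (any(c("classify", "extract", "stats", "forecast") %in% stages) &&
      !"metrics" %in% stages) {
    stop("stages after 'metrics' require the metrics stage", call. = FALSE)
  }
  structure(
    list(design = design, scenarios = scenarios, seed = as.integer(seed),
         out_dir = out_dir, stages = stages,
         conventions = list(av_policy = av_policy,
                            thresholds = thresholds,
                            ranking = ranking,
                            pairing = pairing),
         render = render),
    class = "pipeline_config"
  )
}

#' Run the colonization-analysis pipeline
#'
#' Executes the enabled stages in order, writes one TSV per output table
#' under the configured directory and a `manifest.json` recording the seed,
#' the resolved conventions, the counts and an MD5 hash of every written
#' file. The same configuration and seed give byte-identical tabular
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(...) file.path(config$out_dir, ...)
  conv <- config$conventions
  manifest <- list(
    package = "mycomaps",
    version = as.character(utils::packageVersion("mycomaps")),
    seed = config$seed,
    conventions = conv,
    stages_run = character(0),
    stages_skipped = setdiff(c("simulate", "metrics", "classify",
                               "extract", "stats", "forecast"),
                             config$stages),
    warnings = character(0),
    counts = list(),
    files = list()
  )
  note <- function(msg) {
    manifest$warnings <<- c(manifest$warnings, msg)
  }
  written <- function(path) {
    manifest$files[[basename(path)]] <<-
      unname(tools::md5sum(path))
  }
  run_stage <- function(name, fn) {
    if (!name %in% config$stages) return(invisible(NULL))
    res <- tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages_run <<- c(manifest$stages_run, name)
    res
  }

  study <- NULL
  metrics <- NULL

  study <- run_stage("simulate", function() {
    st <- generate_study(config$scenarios, config$design, config$seed)
    write_observation_table(st$observations, outfile("observations.tsv"))
    written(outfile("observations.tsv"))
    manifest$counts$maps <<- length(st$maps)
    manifest$counts$observations <<- nrow(st$observations)
    st
  })
  if (is.null(study)) {
    stop("pipeline requires the simulate stage (or pre-parsed maps); ",
         "enable 'simulate'", call. = FALSE)
  }

  metrics <- run_stage("metrics", function() {
    met <- metrics_long_table(study$maps, conv$av_policy)
    utils::write.table(met, outfile("metrics.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written(outfile("metrics.tsv"))
    agg <- aggregate_group(met, "variant")
    utils::write.table(agg, outfile("metrics_by_variant.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written(outfile("metrics_by_variant.tsv"))
    met
  })

  run_stage("classify", function() {
    lab <- classify_metrics_table(metrics, conv$thresholds)
    utils::write.table(lab, outfile("strategies.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written(outfile("strategies.tsv"))
    prof <- strategy_profile(lab$strategy, lab$variant)
    utils::write.table(prof, outfile("strategy_profile.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written(outfile("strategy_profile.tsv"))
    seg <- segment_strategy_counts(study$maps, conv$thresholds,
                                   conv$av_policy)
    utils::write.table(seg, outfile("segment_strategy_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    written(outfile("segment_strategy_counts.tsv"))
    invisible(NULL)
  })

  run_stage("extract", function() {
    schemes <- extraction_schemes(study$maps, conv$ranking, conv$av_policy)
    dir.create(outfile("maps"), showWarnings = FALSE)
    n_median <- 0L
    for (v in names(schemes$median)) {
      trip <- schemes$median[[v]]
      for (w in names(trip)) {
        p <- outfile("maps", paste0(v, "_", w, ".csv"))
        write_map_csv(trip[[w]], p)
        written(p)
        if (isTRUE(config$render)) {
          write_map_png(trip[[w]], sub("\\.csv$", ".png", p))
        }
        n_median <- n_median + 1L
      }
      for (sc in c("max_arb", "max_ves")) {
        p <- outfile("maps", paste0(v, "_", sc, ".csv"))
        write_map_csv(schemes[[sc]][[v]]$map, p)
        written(p)
      }
    }
    manifest$counts$median_scheme_maps <<- n_median
    # position-aligned comparison of the nine median maps
    med_maps <- lapply(schemes$median, `[[`, "median")
    rep_cmp <- multipoint_compare(unname(med_maps), "column")
    utils::write.table(rep_cmp$composition,
                       outfile("multipoint_composition.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written(outfile("multipoint_composition.tsv"))
    utils::write.table(rep_cmp$gaps, outfile("multipoint_gaps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    written(outfile("multipoint_gaps.tsv"))
    invisible(NULL)
  })

  run_stage("stats", function() {
    tab <- withCallingHandlers(
      anova_lsd_table(metrics, "variant"),
      warning = function(w) {
        note(conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    utils::write.table(tab, outfile("anova_lsd.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written(outfile("anova_lsd.tsv"))
    cm <- pearson_matrix(metrics)
    if (length(cm$constant) > 0L) {
      note(paste("constant parameter column(s) in correlations:",
                 paste(cm$constant, collapse = ", ")))
    }
    rtab <- as.data.frame(cm$r)
    rtab <- cbind(parameter = rownames(cm$r), rtab)
    utils::write.table(rtab, outfile("correlations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written(outfile("correlations.tsv"))
    co <- cooccurrence_pairs(metrics)
    utils::write.table(co, outfile("cooccurrence.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written(outfile("cooccurrence.tsv"))
    pca <- pca_ordination(metrics)
    utils::write.table(pca$centroids, outfile("pca_centroids.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    written(outfile("pca_centroids.tsv"))
    invisible(NULL)
  })

  run_stage("forecast", function() {
    all_models <- list()
    for (arm in c("untreated", "treated")) {
      arm_treat <- c("A0", if (arm == "untreated") "A1" else "A2")
      arm_stages <- unique(metrics$phenophase[metrics$treatment %in%
                                                arm_treat])
      if (length(arm_stages) < 2L) {
        note(paste0("forecast: arm '", arm, "' has fewer than two stages; ",
                    "skipped"))
        next
      }
      models <- withCallingHandlers(
        build_stage_models(metrics, arm, conv$pairing),
        warning = function(w) {
          note(conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      tab <- forecast_models_table(models)
      tab$arm <- arm
      all_models[[arm]] <- tab
    }
    utils::write.table(dplyr::bind_rows(all_models),
                       outfile("forecast_models.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written(outfile("forecast_models.tsv"))
    invisible(NULL)
  })

  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
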