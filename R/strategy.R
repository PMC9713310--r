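# Colonization-strategy classifier. Thresholds on intensity and the
# arbuscule/vesicle ratio partition colonized units into four strategies:
#   Rs resistance     I < 10
#   Ps proliferative  10 <= I <= 25
#   Ts transfer       I > 25 and A/V ratio > 1
#   Ss storage        I > 25 and A/V ratio <= 1
# Boundary cases (I exactly 10 or 25, ratio exactly 1) fall to Ps / Ss so
# the function is total; both cut points are configurable.

STRATEGY_LEVELS <- c("Rs", "Ps", "Ts", "Ss")

classify_from_values <- function(I, AV, thresholds) {
  if (I < thresholds[1]) "Rs"
  else if (I <= thresholds[2]) "Ps"
  else if (AV > 1) "Ts"
  else "Ss"
}

#' Classify one map's colonization strategy
#'
#' @param metrics A `map_metrics` object (or anything with numeric `I` and
#'   `AV` entries).
#' @param thresholds Length-2 numeric, the resistance/proliferative and
#'   proliferative/transfer-storage intensity cut points (default
#'   `c(10, 25)` percent).
#' @return One of `"Rs"`, `"Ps"`, `"Ts"`, `"Ss"`.
#' @export
classify_map <- function(metrics, thresholds = c(10, 25)) {
  stopifnot(is.numeric(metrics$I), is.numeric(metrics$AV),
            length(thresholds) == 2L, thresholds[1] < thresholds[2])
  classify_from_values(metrics$I, metrics$AV, thresholds)
}

#' Classify one microscopic field's colonization strategy
#'
#' The map-level thresholds applied to the field's own intensity and
#' arbuscule/vesicle ratio.
#'
#' @param field A [field_grid()].
#' @param thresholds See [classify_map()].
#' @param av_policy Zero-vesicle policy (see [av_ratio()]).
#' @return One of `"Rs"`, `"Ps"`, `"Ts"`, `"Ss"`.
#' @export
classify_field <- function(field, thresholds = c(10, 25),
                           av_policy = "zero") {
  fm <- field_metrics(field, av_policy)
  classify_from_values(fm$I, fm$AV, thresholds)
}

#' Strategy labels for a whole metrics table
#'
#' @param metrics Long metrics table from [metrics_long_table()].
#' @param thresholds See [classify_map()].
#' @return The table with a `strategy` column appended.
#' @export
classify_metrics_table <- function(metrics, thresholds = c(10, 25)) {
  metrics$strategy <- vapply(seq_len(nrow(metrics)), function(i) {
    classify_from_values(metrics$I[i], metrics$AV[i], thresholds)
  }, "")
  metrics
}

#' Group shares of each colonization strategy
#'
#' @param labels Character vector of strategy labels.
#' @param group Grouping vector of the same length (e.g. variant codes).
#' @return Tibble with columns `group, Rs, Ps, Ts, Ss, n`; shares are
#'   percentages summing to 100 per group.
#' @export
strategy_profile <- function(labels, group) {
  stopifnot(length(labels) == length(group))
  if (length(labels) == 0L) {
    stop("aggregation error: no units to profile", call. = FALSE)
  }
  bad <- setdiff(unique(labels), STRATEGY_LEVELS)
  if (length(bad) > 0L) {
    stop("unknown strategy label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tab <- table(factor(group), factor(labels, STRATEGY_LEVELS))
  shares <- 100 * prop.table(tab, margin = 1L)
  out <- tibble::as_tibble(as.data.frame.matrix(shares), rownames = "group")
  out$n <- as.integer(rowSums(tab))
  out
}

#' Field-level strategy counts per segment
#'
#' Every microscopic field of every map is classified and counted, giving
#' the per-segment distribution of strategies along the root (the
#' supplementary per-position view of the strategy analysis).
#'
#' @param maps List of [myco_map()].
#' @param thresholds See [classify_map()].
#' @param av_policy Zero-vesicle policy (see [av_ratio()]).
#' @return Tibble with map keys plus `Rs, Ps, Ts, Ss` field counts (summing
#'   to the fields-per-segment count).
#' @export
segment_strategy_counts <- function(maps, thresholds = c(10, 25),
                                    av_policy = "zero") {
  rows <- lapply(maps, function(m) {
    lab <- vapply(m$fields, classify_field, "", thresholds = thresholds,
                  av_policy = av_policy)
    counts <- table(factor(lab, STRATEGY_LEVELS))
    tibble::tibble(variant = m$variant, replicate = m$replicate,
                   segment = m$segment,
                   Rs = as.integer(counts[["Rs"]]),
                   Ps = as.integer(counts[["Ps"]]),
                   Ts = as.integer(counts[["Ts"]]),
                   Ss = as.integer(counts[["Ss"]]))
  })
  dplyr::bind_rows(rows)
}
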