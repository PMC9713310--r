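# Per-map colonization parameters. Frequency is computed on a microscopic-
# field basis; intensity and the structure shares within colonized fields
# only. That makes degree = F*I/100 an exact identity and keeps the
# non-mycorrhizal complement (100 - I) distinct from 100 - DC.

METRIC_COLS <- c("F", "I", "Arb", "Ves", "Sp", "Hyp", "nonM", "DC",
                 "MnonM", "AV")

#' Per-field arbuscule/vesicle ratio under a zero-vesicle policy
#'
#' @param arb,ves Arbuscule and vesicle cell counts of one field.
#' @param policy What to do when `ves == 0`: `"zero"` scores the ratio 0,
#'   `"infinite"` scores it `Inf` when arbuscules are present (0 otherwise),
#'   `"exclude"` marks the field `NA` so it drops out of the map mean.
#' @return Numeric ratio (possibly `Inf` or `NA`).
#' @export
av_ratio <- function(arb, ves, policy = c("zero", "infinite", "exclude")) {
  policy <- match.arg(policy)
  if (ves > 0) return(arb / ves)
  switch(policy,
         zero = 0,
         infinite = if (arb > 0) Inf else 0,
         exclude = NA_real_)
}

#' Compute the colonization parameters of one map
#'
#' Returns the eight tabulated parameters plus the spore and hypha shares:
#' \describe{
#'   \item{F}{colonization frequency, % of microscopic fields holding any
#'     structure}
#'   \item{I}{colonization intensity, % of cells occupied within colonized
#'     fields}
#'   \item{Arb, Ves, Sp, Hyp}{% of cells that are arbuscules / vesicles /
#'     spores / hyphae within colonized fields; they partition I exactly}
#'   \item{nonM}{non-mycorrhizal area, `100 - I`}
#'   \item{DC}{colonization degree, `F * I / 100`, the % of all cells
#'     occupied}
#'   \item{MnonM}{mycorrhizal/non-mycorrhizal area ratio `I / (100 - I)`,
#'     0 when I = 0 and capped at 999 when I = 100}
#'   \item{AV}{mean per-field arbuscule/vesicle ratio over colonized fields
#'     under `av_policy` (see [av_ratio()])}
#' }
#' A map with no colonized field scores F = I = DC = 0, nonM = 100 and all
#' shares and ratios 0.
#'
#' @param map A [myco_map()].
#' @param av_policy Zero-vesicle policy passed to [av_ratio()].
#' @return Named list of class `map_metrics`.
#' @export
compute_map_metrics <- function(map, av_policy = "zero") {
  if (!inherits(map, "myco_map")) {
    stop("input error: expected a 'myco_map'", call. = FALSE)
  }
  if (length(map$fields) == 0L) {
    stop("input error: map has no fields", call. = FALSE)
  }
  codes <- cell_codes()
  occ <- vapply(map$fields, function(f) sum(f != codes[["EMPTY"]]), 0)
  colonized <- occ > 0
  F_ <- 100 * mean(colonized)

  if (!any(colonized)) {
    m <- list(F = 0, I = 0, Arb = 0, Ves = 0, Sp = 0, Hyp = 0, nonM = 100,
              DC = 0, MnonM = 0, AV = 0)
    return(structure(m, class = "map_metrics"))
  }

  cf <- map$fields[colonized]
  total <- sum(vapply(cf, length, 0L))
  count_code <- function(code) {
    100 * sum(vapply(cf, function(f) sum(f == codes[[code]]), 0)) / total
  }
  I_ <- 100 * sum(occ[colonized]) / total
  Arb <- count_code("ARBUSCULE")
  Ves <- count_code("VESICLE")
  Sp <- count_code("SPORE")
  Hyp <- count_code("HYPHA")
  MnonM <- if (I_ >= 100) 999 else I_ / (100 - I_)
  ratios <- vapply(cf, function(f) {
    av_ratio(sum(f == codes[["ARBUSCULE"]]), sum(f == codes[["VESICLE"]]),
             av_policy)
  }, 0)
  ratios <- ratios[!is.na(ratios)]
  AV <- if (length(ratios) == 0L) 0 else mean(ratios)

  structure(
    list(F = F_, I = I_, Arb = Arb, Ves = Ves, Sp = Sp, Hyp = Hyp,
         nonM = 100 - I_, DC = F_ * I_ / 100, MnonM = MnonM, AV = AV),
    class = "map_metrics"
  )
}

#' Field-level intensity and arbuscule/vesicle ratio
#'
#' The same intensity/ratio pair used for map metrics, computed on a single
#' microscopic field (its own cells only); used by the field-level strategy
#' classifier.
#'
#' @param field A [field_grid()].
#' @param av_policy Zero-vesicle policy (see [av_ratio()]).
#' @return List with `I` (% occupied cells) and `AV`.
#' @export
field_metrics <- function(field, av_policy = "zero") {
  codes <- cell_codes()
  I_ <- 100 * mean(field != codes[["EMPTY"]])
  av <- av_ratio(sum(field == codes[["ARBUSCULE"]]),
                 sum(field == codes[["VESICLE"]]), av_policy)
  list(I = I_, AV = if (is.na(av)) 0 else av)
}

#' Per-map metrics as a long table
#'
#' @param maps List of [myco_map()].
#' @param av_policy Zero-vesicle policy (see [av_ratio()]).
#' @return Tibble with one row per map: the map keys plus all
#'   [compute_map_metrics()] columns.
#' @export
metrics_long_table <- function(maps, av_policy = "zero") {
  rows <- lapply(maps, function(m) {
    met <- compute_map_metrics(m, av_policy)
    tibble::tibble(variant = m$variant, treatment = m$treatment,
                   phenophase = m$phenophase, replicate = m$replicate,
                   segment = m$segment, !!!unclass(met))
  })
  dplyr::bind_rows(rows)
}

#' Group means, standard errors and medians of the colonization parameters
#'
#' One row per group per parameter with mean, standard error
#' (sd / sqrt(n)), median and n, in the layout of a variant-by-parameter
#' summary table.
#'
#' @param metrics Long metrics table from [metrics_long_table()].
#' @param group Grouping column: `"variant"`, `"treatment"` or
#'   `"phenophase"`.
#' @return Tibble with columns `group, parameter, mean, se, median, n`.
#' @export
aggregate_group <- function(metrics, group = "variant") {
  if (!group %in% names(metrics)) {
    stop("aggregation error: no grouping column '", group, "'",
         call. = FALSE)
  }
  if (nrow(metrics) == 0L) {
    stop("aggregation error: empty metrics table", call. = FALSE)
  }
  long <- tidyr::pivot_longer(
    metrics[, c(group, METRIC_COLS)],
    cols = dplyr::all_of(METRIC_COLS),
    names_to = "parameter", values_to = "value"
  )
  out <- dplyr::summarise(
    dplyr::group_by(long, .data[[group]], .data$parameter),
    mean = mean(.data$value),
    se = stats::sd(.data$value) / sqrt(dplyr::n()),
    median = stats::median(.data$value),
    n = dplyr::n(),
    .groups = "drop"
  )
  out$parameter <- factor(out$parameter, levels = METRIC_COLS)
  out <- dplyr::arrange(out, .data[[group]], .data$parameter)
  out$parameter <- as.character(out$parameter)
  names(out)[1] <- "group"
  out
}
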