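# Representative-map extraction and position-aligned comparison. A large
# map database is reduced to interpretable patterns: the median triplet
# (the map at the median of a ranking parameter plus its immediate lower
# and upper neighbours) per group, and the maps with maximal arbuscule or
# vesicle shares; maps are then compared position by position.

#' Rank a group of maps by one colonization parameter
#'
#' @param maps List of [myco_map()] belonging to one group.
#' @param parameter Ranking parameter, any [compute_map_metrics()] column
#'   (default `"DC"`, the colonization degree).
#' @param av_policy Zero-vesicle policy used when computing metrics.
#' @return Tibble with map keys, the ranking `value` and `rank` (ascending;
#'   ties broken by replicate then segment order).
#' @export
rank_maps <- function(maps, parameter = "DC", av_policy = "zero") {
  if (!parameter %in% METRIC_COLS) {
    stop("unknown ranking parameter '", parameter, "'", call. = FALSE)
  }
  vals <- vapply(maps, function(m) {
    compute_map_metrics(m, av_policy)[[parameter]]
  }, 0)
  reps <- vapply(maps, `[[`, 0L, "replicate")
  segs <- vapply(maps, `[[`, 0L, "segment")
  ord <- order(vals, reps, segs)
  tibble::tibble(
    index = ord,
    variant = vapply(maps, `[[`, "", "variant")[ord],
    replicate = reps[ord],
    segment = segs[ord],
    value = vals[ord],
    rank = seq_along(ord)
  )
}

#' Extract the median triplet of a map group
#'
#' The maps ranked at `ceiling(n/2) - 1`, `ceiling(n/2)` and
#' `ceiling(n/2) + 1` (1-based) under the ranking parameter: the median
#' pattern and its lower (Median-) and upper (Median+) neighbours.
#'
#' @inheritParams rank_maps
#' @return Named list of three [myco_map()]s: `median_minus`, `median`,
#'   `median_plus`.
#' @export
extract_median_triplet <- function(maps, parameter = "DC",
                                   av_policy = "zero") {
  n <- length(maps)
  if (n < 3L) {
    stop("extraction error: median triplet needs at least 3 maps, got ", n,
         call. = FALSE)
  }
  rk <- rank_maps(maps, parameter, av_policy)
  mid <- ceiling(n / 2)
  picks <- if (mid - 1L < 1L) 1:3 else (mid - 1L):(mid + 1L)
  out <- lapply(picks, function(r) maps[[rk$index[r]]])
  names(out) <- c("median_minus", "median", "median_plus")
  out
}

#' Extract the map maximizing a structure share
#'
#' The group's map with the highest arbuscule (or vesicle) percentage; ties
#' go to the higher colonization degree, then to input order. A group where
#' the structure is absent everywhere still returns its first map (by the
#' tie-break) with `max_value = 0`.
#'
#' @param maps List of [myco_map()] belonging to one group.
#' @param structure `"Arb"` or `"Ves"`.
#' @param av_policy Zero-vesicle policy used when computing metrics.
#' @return List with the winning `map`, its `max_value` and its input
#'   `index`.
#' @export
extract_extreme_map <- function(maps, structure = c("Arb", "Ves"),
                                av_policy = "zero") {
  structure <- match.arg(structure)
  if (length(maps) == 0L) {
    stop("extraction error: empty map group", call. = FALSE)
  }
  mets <- lapply(maps, compute_map_metrics, av_policy = av_policy)
  vals <- vapply(mets, `[[`, 0, structure)
  dcs <- vapply(mets, `[[`, 0, "DC")
  best <- order(-vals, -dcs)[1]  # stable: input order breaks remaining ties
  list(map = maps[[best]], max_value = vals[best], index = best)
}

#' Compare colonized areas across maps position by position
#'
#' Maps sharing one grid geometry are aligned on a common position axis
#' (whole microscopic fields, or single grid columns in longitudinal order)
#' and the structure composition at every position is tabulated, together
#' with each map's uncolonized gaps (maximal runs of positions holding no
#' structure at all).
#'
#' @param maps List of >= 2 [myco_map()] with identical geometry.
#' @param granularity `"field"` (one position per microscopic field) or
#'   `"column"` (one position per grid column, fields concatenated).
#' @return List of class `multipoint_report` with elements
#'   `composition` (tibble: `map, position, EMPTY, HYPHA, ARBUSCULE,
#'   VESICLE, SPORE` fractions summing to 1) and `gaps` (tibble: `map,
#'   start, length` of each uncolonized run; a gap-free map contributes no
#'   rows).
#' @export
multipoint_compare <- function(maps, granularity = c("field", "column")) {
  granularity <- match.arg(granularity)
  if (length(maps) < 2L) {
    stop("comparison error: need at least 2 maps", call. = FALSE)
  }
  geom <- vapply(maps, function(m) {
    c(length(m$fields), dim(m$fields[[1]]))
  }, integer(3))
  if (any(geom != geom[, 1])) {
    stop("comparison error: maps differ in grid geometry", call. = FALSE)
  }

  comp_rows <- list()
  gap_rows <- list()
  for (m in maps) {
    id <- map_id(m)
    wide <- do.call(cbind, m$fields)  # rows x (fields*cols)
    pos_cols <- if (granularity == "field") {
      split(seq_len(ncol(wide)),
            rep(seq_along(m$fields), each = ncol(m$fields[[1]])))
    } else {
      as.list(seq_len(ncol(wide)))
    }
    frac <- t(vapply(pos_cols, function(jj) {
      cells <- wide[, jj]
      tabulate(as.integer(cells) + 1L, nbins = 5L) / length(cells)
    }, numeric(5)))
    colnames(frac) <- .code_names
    comp_rows[[id]] <- dplyr::bind_cols(
      tibble::tibble(map = id, position = seq_len(nrow(frac))),
      tibble::as_tibble(frac)
    )
    occupied <- unname(frac[, "EMPTY"] < 1)
    r <- rle(!occupied)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    is_gap <- r$values
    if (any(is_gap)) {
      gap_rows[[id]] <- tibble::tibble(map = id,
                                       start = starts[is_gap],
                                       length = r$lengths[is_gap])
    }
  }
  structure(
    list(
      composition = dplyr::bind_rows(comp_rows),
      gaps = if (length(gap_rows) == 0L) {
        tibble::tibble(map = character(), start = integer(),
                       length = integer())
      } else {
        dplyr::bind_rows(gap_rows)
      },
      granularity = granularity,
      positions = nrow(comp_rows[[1]])
    ),
    class = "multipoint_report"
  )
}

#' Run all three extraction schemes over a study
#'
#' Per variant group: the median triplet under the ranking parameter, the
#' maximum-arbuscule map and the maximum-vesicle map (the three comparative
#' schemes of the pattern analysis).
#'
#' @param maps All study maps.
#' @param parameter Ranking parameter for the median triplet.
#' @param av_policy Zero-vesicle policy used when computing metrics.
#' @return List with `median` (named list variant -> triplet), `max_arb`
#'   and `max_ves` (named lists variant -> extreme extraction).
#' @export
extraction_schemes <- function(maps, parameter = "DC", av_policy = "zero") {
  variants <- vapply(maps, `[[`, "", "variant")
  groups <- split(maps, factor(variants, unique(variants)))
  list(
    median = lapply(groups, extract_median_triplet, parameter = parameter,
                    av_policy = av_policy),
    max_arb = lapply(groups, extract_extreme_map, structure = "Arb",
                     av_policy = av_policy),
    max_ves = lapply(groups, extract_extreme_map, structure = "Ves",
                     av_policy = av_policy)
  )
}
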