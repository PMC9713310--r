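#' Study design for a gridded colonization survey
#'
#' Describes the sampling layout of a root-colonization study: which
#' treatment x phenophase variants were observed, how many field replicates,
#' how many 1-cm root segments per variant, how many microscopic fields per
#' segment, and the grid resolution used to code each field.
#'
#' @param variants Character vector of variant codes, conventionally
#'   `"<treatment>_<phenophase>"` (e.g. `"A1_B3"`).
#' @param replicates Number of field replications.
#' @param segments Number of root segments per variant and replicate.
#' @param fields Number of microscopic fields observed per segment.
#' @param grid_rows,grid_cols Grid resolution of one microscopic field.
#'
#' @return An object of class `study_design`.
#' @export
#' @examples
#' d <- study_design()
#' n_maps(d)     # 405
#' n_records(d)  # 6075
study_design <- function(variants = default_variants(),
                         replicates = 3L,
                         segments = 15L,
                         fields = 15L,
                         grid_rows = 10L,
                         grid_cols = 10L) {
  stopifnot(length(variants) >= 1L, !anyDuplicated(variants))
  for (v in c(replicates, segments, fields, grid_rows, grid_cols)) {
    if (!is.numeric(v) || length(v) != 1L || v < 1L || v != round(v)) {
      stop("design counts must be positive integers", call. = FALSE)
    }
  }
  structure(
    list(
      variants = as.character(variants),
      replicates = as.integer(replicates),
      segments = as.integer(segments),
      fields = as.integer(fields),
      grid_rows = as.integer(grid_rows),
      grid_cols = as.integer(grid_cols)
    ),
    class = "study_design"
  )
}

#' Default variant codes of the maize biostimulator study layout
#'
#' One native-profile control (`A0_B1`, 2-4 leaves) plus untreated (`A1`) and
#' biostimulator-treated (`A2`) plants observed at phenophases B2 (6 leaves),
#' B3 (8-10 leaves), B4 (cob formation) and B5 (physiological maturity).
#'
#' @return Character vector of nine variant codes.
#' @export
default_variants <- function() {
  c("A0_B1",
    paste0("A1_B", 2:5),
    paste0("A2_B", 2:5))
}

#' Split a variant code into treatment and phenophase
#' @param variant Character vector of `"<treatment>_<phenophase>"` codes.
#' @return A data frame with columns `treatment` and `phenophase`.
#' @export
split_variant <- function(variant) {
  parts <- strsplit(as.character(variant), "_", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("variant codes must look like '<treatment>_<phenophase>': ",
         paste(unique(variant[bad]), collapse = ", "), call. = FALSE)
  }
  data.frame(
    treatment = vapply(parts, `[`, "", 1L),
    phenophase = vapply(parts, `[`, "", 2L)
  )
}

#' Expected map and observation counts of a design
#'
#' A map is one root segment (an ordered run of microscopic fields); an
#' observation record is one microscopic field.
#'
#' @param design A [study_design()].
#' @return Integer count.
#' @export
n_maps <- function(design) {
  stopifnot(inherits(design, "study_design"))
  length(design$variants) * design$replicates * design$segments
}

#' @rdname n_maps
#' @export
n_records <- function(design) {
  n_maps(design) * design$fields
}

#' @export
print.study_design <- function(x, ...) {
  cat("Colonization study design\n")
  cat("  variants:  ", length(x$variants), " (",
      paste(x$variants, collapse = ", "), ")\n", sep = "")
  cat("  replicates:", x$replicates,
      " segments:", x$segments,
      " fields/segment:", x$fields, "\n")
  cat("  grid:      ", x$grid_rows, "x", x$grid_cols, "cells per field\n")
  cat("  expected:  ", n_maps(x), "maps,", n_records(x), "observations\n")
  invisible(x)
}
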