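# Cell coding: each grid cell of a microscopic field holds exactly one
# structure code. Integer codes index CELL_CODES; symbols are the fixed
# one-character serialization alphabet.

#' Cell codes of a mycorrhizal map
#'
#' Grid cells carry exactly one structure: empty root area, hypha (the
#' carrier network), arbuscule (nutrient-exchange structure), vesicle
#' (storage structure) or spore. Cells are stored as integers `0:4` in this
#' order; `cell_symbols()` gives the one-character serialization alphabet.
#'
#' @return `cell_codes()` returns the named integer code vector;
#'   `cell_symbols()` the named character symbol vector.
#' @export
cell_codes <- function() {
  c(EMPTY = 0L, HYPHA = 1L, ARBUSCULE = 2L, VESICLE = 3L, SPORE = 4L)
}

#' @rdname cell_codes
#' @export
cell_symbols <- function() {
  c(EMPTY = "0", HYPHA = "H", ARBUSCULE = "A", VESICLE = "V", SPORE = "S")
}

.code_names <- c("EMPTY", "HYPHA", "ARBUSCULE", "VESICLE", "SPORE")

# When a source reports several structures in one cell the cell keeps the
# highest-precedence one: ARBUSCULE > VESICLE > SPORE > HYPHA.
.code_precedence <- c(ARBUSCULE = 4L, VESICLE = 3L, SPORE = 2L, HYPHA = 1L,
                      EMPTY = 0L)

#' Resolve multiple structures reported in one cell to a single code
#'
#' @param codes Integer vector of candidate codes for one cell.
#' @return The retained single code under the precedence
#'   ARBUSCULE > VESICLE > SPORE > HYPHA (EMPTY only if nothing else).
#' @export
resolve_cell <- function(codes) {
  codes <- as.integer(codes)
  validate_codes(codes)
  if (length(codes) == 0L) return(cell_codes()[["EMPTY"]])
  prec <- .code_precedence[.code_names[codes + 1L]]
  codes[[which.max(prec)]]
}

validate_codes <- function(codes) {
  if (anyNA(codes) || any(codes < 0L | codes > 4L)) {
    stop("unknown cell code; valid codes are 0 (EMPTY) .. 4 (SPORE)",
         call. = FALSE)
  }
  invisible(codes)
}

#' Construct one microscopic-field grid
#'
#' @param cells Integer matrix (rows x cols) of cell codes, or a vector plus
#'   `rows`/`cols` filled row-major.
#' @param rows,cols Grid dimensions when `cells` is a vector.
#' @return An integer matrix of class `field_grid`.
#' @export
field_grid <- function(cells, rows = NULL, cols = NULL) {
  if (!is.matrix(cells)) {
    stopifnot(!is.null(rows), !is.null(cols))
    if (length(cells) != rows * cols) {
      stop("cell count ", length(cells), " != rows*cols = ", rows * cols,
           call. = FALSE)
    }
    cells <- matrix(as.integer(cells), nrow = rows, ncol = cols,
                    byrow = TRUE)
  }
  storage.mode(cells) <- "integer"
  if (nrow(cells) < 1L || ncol(cells) < 1L) {
    stop("a field grid needs at least one cell", call. = FALSE)
  }
  validate_codes(cells)
  class(cells) <- c("field_grid", class(cells))
  cells
}

#' Construct a mycorrhizal map (one root segment)
#'
#' A map is the ordered run of microscopic-field grids scored along one 1-cm
#' root segment, proximal to distal, together with its position in the study
#' layout.
#'
#' @param variant Variant code (`"<treatment>_<phenophase>"`).
#' @param replicate Replication index (1-based).
#' @param segment Segment index within variant x replicate (1-based).
#' @param fields List of [field_grid()] matrices with identical dimensions.
#' @return An object of class `myco_map`.
#' @export
myco_map <- function(variant, replicate, segment, fields) {
  if (length(fields) == 0L) {
    stop("a map needs at least one microscopic field", call. = FALSE)
  }
  fields <- lapply(fields, function(f) {
    if (inherits(f, "field_grid")) f else field_grid(f)
  })
  dims <- vapply(fields, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all field grids in a map must share the same dimensions",
         call. = FALSE)
  }
  tp <- split_variant(variant)
  structure(
    list(
      variant = as.character(variant),
      treatment = tp$treatment,
      phenophase = tp$phenophase,
      replicate = as.integer(replicate),
      segment = as.integer(segment),
      fields = fields
    ),
    class = "myco_map"
  )
}

#' @export
print.myco_map <- function(x, ...) {
  d <- dim(x$fields[[1]])
  cat(sprintf("Mycorrhizal map %s rep %d segment %d: %d fields of %dx%d\n",
              x$variant, x$replicate, x$segment, length(x$fields),
              d[1], d[2]))
  invisible(x)
}

map_id <- function(map) {
  paste(map$variant, map$replicate, map$segment, sep = ".")
}

# ---- grid serialization -----------------------------------------------------
# Row-major one-character codes; '|' joins rows, ';' joins fields.

#' Serialize field grids to their compact string form
#'
#' One character per cell (`0HAVS`), rows joined by `|`, fields joined by
#' `;`. `serialize_grid()` handles one field; `serialize_fields()` a list.
#'
#' @param grid A [field_grid()].
#' @return Character scalar.
#' @export
serialize_grid <- function(grid) {
  syms <- cell_symbols()
  chars <- matrix(syms[grid + 1L], nrow = nrow(grid))
  paste(apply(chars, 1L, paste0, collapse = ""), collapse = "|")
}

#' @rdname serialize_grid
#' @param fields List of field grids.
#' @export
serialize_fields <- function(fields) {
  paste(vapply(fields, serialize_grid, ""), collapse = ";")
}

#' Decode the compact grid string back into field grids
#'
#' @param text Serialized grid string (see [serialize_grid()]).
#' @return `parse_grid()` returns one [field_grid()]; `parse_fields()` a
#'   list of them (splitting on `;`).
#' @export
parse_grid <- function(text) {
  rows <- strsplit(text, "|", fixed = TRUE)[[1]]
  if (length(rows) == 0L || any(nchar(rows) == 0L)) {
    stop("malformed grid string: empty row", call. = FALSE)
  }
  if (length(unique(nchar(rows))) != 1L) {
    stop("malformed grid string: ragged rows", call. = FALSE)
  }
  syms <- cell_symbols()
  lookup <- stats::setNames(cell_codes(), syms)
  chars <- strsplit(rows, "", fixed = TRUE)
  flat <- unlist(chars, use.names = FALSE)
  codes <- lookup[flat]
  if (anyNA(codes)) {
    stop("malformed grid string: unknown symbol '",
         paste(unique(flat[is.na(codes)]), collapse = "', '"), "'",
         call. = FALSE)
  }
  field_grid(as.integer(codes), rows = length(rows), cols = nchar(rows[1]))
}

#' @rdname parse_grid
#' @export
parse_fields <- function(text) {
  lapply(strsplit(text, ";", fixed = TRUE)[[1]], parse_grid)
}

# ---- observation tables -----------------------------------------------------

#' Flatten maps to a long observation table
#'
#' One row per microscopic field with the map keys, field index and the
#' serialized grid; the inverse of [parse_observation_table()].
#'
#' @param maps List of [myco_map()] objects.
#' @return A tibble with columns `variant, treatment, phenophase, replicate,
#'   segment, field_index, grid`.
#' @export
observation_table <- function(maps) {
  rows <- lapply(maps, function(m) {
    tibble::tibble(
      variant = m$variant,
      treatment = m$treatment,
      phenophase = m$phenophase,
      replicate = m$replicate,
      segment = m$segment,
      field_index = seq_along(m$fields),
      grid = vapply(m$fields, serialize_grid, "")
    )
  })
  dplyr::bind_rows(rows)
}

#' Read an observation table into mycorrhizal maps
#'
#' Accepts a TSV file path or an already-read data frame with columns
#' `variant, replicate, segment, field_index, grid` (plus optional
#' `treatment`/`phenophase`, which are rederived from `variant`). Records
#' are grouped into one map per (variant, replicate, segment), fields
#' ordered by `field_index`.
#'
#' @param x Path to a UTF-8 tab-separated file, or a data frame.
#' @param design A [study_design()]; used to validate the declared field
#'   count per segment and the grid dimensions.
#' @return List of [myco_map()] objects ordered by
#'   (variant, replicate, segment).
#' @export
parse_observation_table <- function(x, design = study_design()) {
  tbl <- if (is.character(x)) {
    utils::read.delim(x, sep = "\t", header = TRUE, colClasses = "character",
                      fileEncoding = "UTF-8")
  } else {
    as.data.frame(x)
  }
  needed <- c("variant", "replicate", "segment", "field_index", "grid")
  missing_cols <- setdiff(needed, names(tbl))
  if (length(missing_cols) > 0L) {
    stop("observation table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tbl$replicate <- as.integer(tbl$replicate)
  tbl$segment <- as.integer(tbl$segment)
  tbl$field_index <- as.integer(tbl$field_index)

  key <- paste(tbl$variant, tbl$replicate, tbl$segment, tbl$field_index)
  if (anyDuplicated(key)) {
    stop("integrity error: duplicate (variant, replicate, segment, field) ",
         "record: ", key[which(duplicated(key))[1]], call. = FALSE)
  }
  unknown <- setdiff(unique(tbl$variant), design$variants)
  if (length(unknown) > 0L) {
    stop("integrity error: variant(s) not in design: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  ord <- order(match(tbl$variant, design$variants), tbl$replicate,
               tbl$segment, tbl$field_index)
  tbl <- tbl[ord, , drop = FALSE]
  grp <- paste(tbl$variant, tbl$replicate, tbl$segment, sep = ".")
  maps <- lapply(split(seq_len(nrow(tbl)), factor(grp, unique(grp))),
                 function(idx) {
    sub <- tbl[idx, , drop = FALSE]
    if (nrow(sub) != design$fields) {
      stop("integrity error: segment ", grp[idx[1]], " has ", nrow(sub),
           " fields, design declares ", design$fields, call. = FALSE)
    }
    if (!identical(sub$field_index, seq_len(design$fields))) {
      stop("integrity error: segment ", grp[idx[1]],
           " field indices are not 1..", design$fields, call. = FALSE)
    }
    fields <- lapply(seq_len(nrow(sub)), function(i) {
      g <- tryCatch(parse_grid(sub$grid[i]),
                    error = function(e) {
                      stop("parse error in record (", sub$variant[i], ", ",
                           sub$replicate[i], ", ", sub$segment[i], ", field ",
                           sub$field_index[i], "): ", conditionMessage(e),
                           call. = FALSE)
                    })
      if (nrow(g) != design$grid_rows || ncol(g) != design$grid_cols) {
        stop("dimension error: record (", sub$variant[i], ", ",
             sub$replicate[i], ", ", sub$segment[i], ", field ",
             sub$field_index[i], ") is ", nrow(g), "x", ncol(g),
             ", design declares ", design$grid_rows, "x", design$grid_cols,
             call. = FALSE)
      }
      g
    })
    myco_map(sub$variant[1], sub$replicate[1], sub$segment[1], fields)
  })
  unname(maps)
}

#' Write an observation table as TSV
#' @param tbl Observation table (see [observation_table()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_observation_table <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# ---- grid CSV (one map per file) -------------------------------------------

#' Write/read one map as a grid CSV
#'
#' One character per cell, comma-separated within a row, one row per line;
#' consecutive field blocks separated by a blank line. `read_map_csv()`
#' restores the grids; map keys live in the file name by convention, so the
#' caller supplies them.
#'
#' @param map A [myco_map()].
#' @param path File path.
#' @return `write_map_csv()` returns `path` invisibly; `read_map_csv()` a
#'   list of [field_grid()]s.
#' @export
write_map_csv <- function(map, path) {
  syms <- cell_symbols()
  blocks <- vapply(map$fields, function(f) {
    chars <- matrix(syms[f + 1L], nrow = nrow(f))
    paste(apply(chars, 1L, paste, collapse = ","), collapse = "\n")
  }, "")
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

#' @rdname write_map_csv
#' @export
read_map_csv <- function(path) {
  lines <- readLines(path)
  # split on blank lines into field blocks
  grp <- cumsum(lines == "")
  blocks <- split(lines[lines != ""], grp[lines != ""])
  lapply(blocks, function(b) {
    parse_grid(paste(gsub(",", "", b, fixed = TRUE), collapse = "|"))
  })
}

# ---- rendering --------------------------------------------------------------

#' Default map palette
#'
#' Hyphae blue, arbuscules red, vesicles green, spores gray, empty cells
#' white.
#' @return Named character vector of colors per code name.
#' @export
default_palette <- function() {
  c(EMPTY = "#FFFFFF", HYPHA = "#1F4FFF", ARBUSCULE = "#E02020",
    VESICLE = "#18A018", SPORE = "#808080")
}

#' Read a palette override from a YAML file
#'
#' The file maps code names (EMPTY/HYPHA/ARBUSCULE/VESICLE/SPORE) to colors;
#' unnamed codes keep the default.
#' @param path YAML file path.
#' @return Named color vector as in [default_palette()].
#' @export
read_palette <- function(path) {
  pal <- default_palette()
  over <- yaml::read_yaml(path)
  unknown <- setdiff(names(over), names(pal))
  if (length(unknown) > 0L) {
    stop("palette file names unknown code(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  pal[names(over)] <- unlist(over)
  pal
}

#' Render a map as a raster image
#'
#' One `scale` x `scale` pixel block per cell; fields are stacked
#' left-to-right along the root axis in longitudinal order.
#'
#' @param map A [myco_map()].
#' @param palette Named color vector (see [default_palette()]).
#' @param scale Pixel block edge per cell.
#' @return Numeric array (height x width x 3, RGB in `[0,1]`) suitable for
#'   [write_map_png()].
#' @export
render_map <- function(map, palette = default_palette(), scale = 4L) {
  if (!all(.code_names %in% names(palette))) {
    stop("palette must name all five cell codes", call. = FALSE)
  }
  wide <- do.call(cbind, map$fields)  # rows x (fields*cols)
  validate_codes(wide)
  rgb <- grDevices::col2rgb(palette[.code_names]) / 255
  img <- array(0, dim = c(nrow(wide) * scale, ncol(wide) * scale, 3))
  rows <- rep(seq_len(nrow(wide)), each = scale)
  cols <- rep(seq_len(ncol(wide)), each = scale)
  for (ch in 1:3) {
    img[, , ch] <- matrix(rgb[ch, wide[rows, cols] + 1L],
                          nrow = nrow(wide) * scale)
  }
  img
}

#' @rdname render_map
#' @param path PNG output path.
#' @export
write_map_png <- function(map, path, palette = default_palette(),
                          scale = 4L) {
  png::writePNG(render_map(map, palette, scale), path)
  invisible(path)
}
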