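# Builders for small hand-constructed maps and an independent brute-force
# metrics oracle used across the suite.

CODE <- cell_codes()

uniform_field <- function(code, rows = 10, cols = 10) {
  field_grid(matrix(code, rows, cols))
}

# fill the first `n` cells (row-major) with `code`, rest empty
partial_field <- function(n, code = CODE[["HYPHA"]], rows = 10, cols = 10) {
  cells <- rep(CODE[["EMPTY"]], rows * cols)
  if (n > 0) cells[seq_len(n)] <- code
  field_grid(cells, rows = rows, cols = cols)
}

# field with given counts of each structure, packed row-major
counts_field <- function(hypha = 0, arb = 0, ves = 0, spore = 0,
                         rows = 10, cols = 10) {
  cells <- c(rep(CODE[["HYPHA"]], hypha), rep(CODE[["ARBUSCULE"]], arb),
             rep(CODE[["VESICLE"]], ves), rep(CODE[["SPORE"]], spore))
  stopifnot(length(cells) <= rows * cols)
  cells <- c(cells, rep(CODE[["EMPTY"]], rows * cols - length(cells)))
  field_grid(cells, rows = rows, cols = cols)
}

make_map <- function(fields, variant = "A1_B2", replicate = 1,
                     segment = 1) {
  myco_map(variant, replicate, segment, fields)
}

# a small random map with all codes present at random positions
random_small_map <- function(n_fields = 3, rows = 4, cols = 5,
                             variant = "A1_B2", replicate = 1,
                             segment = 1) {
  fields <- replicate(n_fields, {
    field_grid(sample(0:4, rows * cols, replace = TRUE,
                      prob = c(0.5, 0.3, 0.1, 0.05, 0.05)),
               rows = rows, cols = cols)
  }, simplify = FALSE)
  myco_map(variant, replicate, segment, fields)
}

# Brute-force metrics oracle: walks every cell individually, keeping
# per-field tallies, without reusing any vectorized implementation path.
oracle_metrics <- function(map, av_policy = "zero") {
  nf <- length(map$fields)
  colonized_fields <- 0
  cells_col <- 0; occ <- 0; arb <- 0; ves <- 0; sp <- 0; hyp <- 0
  ratios <- c()
  for (f in map$fields) {
    f_occ <- 0; f_arb <- 0; f_ves <- 0; f_sp <- 0; f_hyp <- 0
    for (r in seq_len(nrow(f))) {
      for (cc in seq_len(ncol(f))) {
        v <- f[r, cc]
        if (v != 0) f_occ <- f_occ + 1
        if (v == 2) f_arb <- f_arb + 1
        if (v == 3) f_ves <- f_ves + 1
        if (v == 4) f_sp <- f_sp + 1
        if (v == 1) f_hyp <- f_hyp + 1
      }
    }
    if (f_occ > 0) {
      colonized_fields <- colonized_fields + 1
      cells_col <- cells_col + length(f)
      occ <- occ + f_occ; arb <- arb + f_arb; ves <- ves + f_ves
      sp <- sp + f_sp; hyp <- hyp + f_hyp
      ratios <- c(ratios, if (f_ves > 0) f_arb / f_ves
                  else switch(av_policy, zero = 0,
                              infinite = if (f_arb > 0) Inf else 0,
                              exclude = NA_real_))
    }
  }
  F_ <- 100 * colonized_fields / nf
  if (colonized_fields == 0) {
    return(list(F = 0, I = 0, Arb = 0, Ves = 0, Sp = 0, Hyp = 0,
                nonM = 100, DC = 0, MnonM = 0, AV = 0))
  }
  I_ <- 100 * occ / cells_col
  ratios <- ratios[!is.na(ratios)]
  list(F = F_, I = I_, Arb = 100 * arb / cells_col,
       Ves = 100 * ves / cells_col, Sp = 100 * sp / cells_col,
       Hyp = 100 * hyp / cells_col, nonM = 100 - I_, DC = F_ * I_ / 100,
       MnonM = if (I_ >= 100) 999 else I_ / (100 - I_),
       AV = if (length(ratios) == 0) 0 else mean(ratios))
}

# small synthetic study shared by several tests
tiny_design <- function(variants = c("A0_B1", "A1_B2"), replicates = 2,
                        segments = 4, fields = 6, rows = 6, cols = 6) {
  study_design(variants = variants, replicates = replicates,
               segments = segments, fields = fields, grid_rows = rows,
               grid_cols = cols)
}
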