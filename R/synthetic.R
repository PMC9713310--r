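# Synthetic colonization-pattern generator. The target is statistical
# structure, not fungal mechanism: per-field colonization probability phi,
# within-field cell occupancy p, lateral (column-to-column) persistence rho,
# and per-cell structure shares (alpha, nu, sigma) for arbuscules, vesicles
# and spores, the remainder being hyphae.

#' Colonization parameters of one variant
#'
#' @param phi Probability that a microscopic field contains any fungal
#'   structure (drives colonization frequency, `E[F] = 100*phi`).
#' @param p Target occupied-cell fraction within a colonized field (drives
#'   colonization intensity, `E[I] = 100*p`).
#' @param rho Column-persistence of the two-state occupancy chain that picks
#'   colonized grid columns; higher values give laterally clustered
#'   colonization with longer uncolonized gaps.
#' @param alpha,nu,sigma Probability that an occupied cell is an arbuscule,
#'   vesicle or spore respectively (`alpha + nu + sigma <= 1`; the rest are
#'   hyphae).
#' @return An object of class `colonization_params`.
#' @export
colonization_params <- function(phi, p, rho = 0.7, alpha = 0, nu = 0,
                                sigma = 0) {
  probs <- c(phi = phi, p = p, rho = rho, alpha = alpha, nu = nu,
             sigma = sigma)
  if (anyNA(probs) || any(probs < 0) || any(probs > 1)) {
    stop("parameter error: all probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  if (alpha + nu + sigma > 1 + 1e-12) {
    stop("parameter error: alpha + nu + sigma must not exceed 1",
         call. = FALSE)
  }
  structure(as.list(probs), class = "colonization_params")
}

# Two-state column chain at stationarity p with colonized-state persistence
# rho11. For p > 1/(2 - rho) no stationary chain with that persistence
# exists (the required 0->1 rate exceeds 1), so persistence is raised to
# (2p-1)/p, the smallest feasible value, keeping stationarity at p exact.
column_chain_rates <- function(p, rho) {
  if (p >= 1) return(list(rho11 = 1, q01 = 1, p_any = 1))
  rho11 <- max(rho, if (p > 0.5) (2 * p - 1) / p else 0)
  q01 <- p * (1 - rho11) / (1 - p)
  list(rho11 = rho11, q01 = q01, p_any = NA_real_)
}

# P(at least one colonized column) for a C-column stationary draw.
p_any_column <- function(p, rho, cols) {
  if (p >= 1) return(1)
  if (p <= 0) return(0)
  r <- column_chain_rates(p, rho)
  1 - (1 - p) * (1 - r$q01)^(cols - 1L)
}

#' Generate one microscopic-field grid
#'
#' With probability `1 - phi` the field is empty. Otherwise colonized
#' columns are drawn from a two-state Markov chain (stationary occupancy
#' `p`, persistence `rho`), redrawn until at least one column is colonized;
#' each colonized column receives one vertically contiguous occupied run
#' whose random length has mean `rows * P(any colonized column)`, which
#' exactly cancels the redraw conditioning so the expected occupied-cell
#' fraction of a colonized field equals `p`. Occupied cells are labelled
#' arbuscule/vesicle/spore/hypha with probabilities
#' `(alpha, nu, sigma, 1 - alpha - nu - sigma)`.
#'
#' Uses the current RNG stream; seed upstream (see [generate_map()]) for
#' reproducibility.
#'
#' @param params A [colonization_params()].
#' @param rows,cols Grid dimensions.
#' @return A [field_grid()].
#' @export
generate_field <- function(params, rows = 10L, cols = 10L) {
  stopifnot(inherits(params, "colonization_params"))
  codes <- cell_codes()
  empty <- matrix(codes[["EMPTY"]], nrow = rows, ncol = cols)
  if (params$p <= 0 || stats::runif(1) >= params$phi) {
    return(field_grid(empty))
  }
  r <- column_chain_rates(params$p, params$rho)
  state <- logical(cols)
  for (try in seq_len(10000L)) {
    state[1] <- stats::runif(1) < params$p
    if (cols > 1L) {
      for (j in 2:cols) {
        state[j] <- stats::runif(1) <
          (if (state[j - 1L]) r$rho11 else r$q01)
      }
    }
    if (any(state)) break
  }
  if (!any(state)) state[sample.int(cols, 1L)] <- TRUE

  # contiguous run length: 1 + Binomial(rows-1, pr) with mean rows * P(any)
  p_any <- p_any_column(params$p, params$rho, cols)
  target_mean <- rows * p_any
  pr <- if (rows > 1L) max(0, min(1, (target_mean - 1) / (rows - 1))) else 0

  grid <- empty
  for (j in which(state)) {
    len <- 1L + stats::rbinom(1L, rows - 1L, pr)
    start <- sample.int(rows - len + 1L, 1L)
    run <- start:(start + len - 1L)
    u <- stats::runif(len)
    lab <- ifelse(u < params$alpha, codes[["ARBUSCULE"]],
           ifelse(u < params$alpha + params$nu, codes[["VESICLE"]],
           ifelse(u < params$alpha + params$nu + params$sigma,
                  codes[["SPORE"]], codes[["HYPHA"]])))
    grid[run, j] <- lab
  }
  field_grid(grid)
}

# Deterministic 31-bit seed from the master seed and map coordinates, so any
# map (and any subset of a study) is reproducible on its own.
derive_seed <- function(master, ...) {
  key <- paste(master, ..., sep = "/")
  h <- 17
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

#' Variant scenarios
#'
#' A scenario set maps each variant code to its [colonization_params()].
#' `default_scenarios()` ships nine variants whose frequency/intensity
#' trajectories mimic a maize biostimulator study: colonization rises to the
#' 8-10-leaf and cob-formation phenophases and falls at maturity, treated
#' plants lag untreated ones, vesicles stay below 1% of colonized root area
#' and arbuscules range from a few percent to ~12%.
#'
#' @return Named list of [colonization_params()] keyed by variant code.
#' @export
default_scenarios <- function() {
  # phi = F/100, p = I/100, alpha = Arb/I, nu = Ves/I, small spore share
  tab <- list(
    #           phi     p     alpha   nu     sigma
    A0_B1 = c(0.747, 0.426, 0.286, 0.0061, 0.005),
    A1_B2 = c(0.609, 0.296, 0.188, 0.0088, 0.005),
    A1_B3 = c(0.764, 0.461, 0.204, 0.0050, 0.005),
    A1_B4 = c(0.774, 0.405, 0.202, 0.0212, 0.005),
    A1_B5 = c(0.627, 0.301, 0.100, 0.0253, 0.005),
    A2_B2 = c(0.525, 0.272, 0.086, 0.0029, 0.005),
    A2_B3 = c(0.717, 0.404, 0.137, 0.0030, 0.005),
    A2_B4 = c(0.681, 0.346, 0.153, 0.0237, 0.005),
    A2_B5 = c(0.509, 0.261, 0.164, 0.0092, 0.005)
  )
  lapply(tab, function(v) {
    colonization_params(phi = v[1], p = v[2], alpha = v[3], nu = v[4],
                        sigma = v[5])
  })
}

#' Read variant scenarios from a YAML file
#'
#' The file maps variant codes to parameter lists
#' (`phi, p, rho, alpha, nu, sigma`); omitted entries use the
#' [colonization_params()] defaults.
#'
#' @param path YAML file path.
#' @return Named list of [colonization_params()].
#' @export
read_scenarios <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(v) do.call(colonization_params, as.list(v)))
}

#' Generate one synthetic map
#'
#' Fields are drawn independently from the variant's parameters under a seed
#' derived from `(seed, variant, replicate, segment)`, so the same inputs
#' always give the same map.
#'
#' @param scenarios Named list of [colonization_params()] keyed by variant.
#' @param variant Variant code; must be present in `scenarios`.
#' @param replicate,segment Map coordinates.
#' @param design A [study_design()] (grid geometry and fields per segment).
#' @param seed Master integer seed.
#' @return A [myco_map()].
#' @export
generate_map <- function(scenarios, variant, replicate, segment,
                         design = study_design(), seed = 1L) {
  if (!variant %in% names(scenarios)) {
    stop("no scenario for variant '", variant, "'", call. = FALSE)
  }
  params <- scenarios[[variant]]
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(seed, variant, replicate, segment))
  fields <- replicate(design$fields,
                      generate_field(params, design$grid_rows,
                                     design$grid_cols),
                      simplify = FALSE)
  myco_map(variant, replicate, segment, fields)
}

#' Generate a full synthetic study
#'
#' One map per (variant, replicate, segment) of the design; the default
#' design (9 variants x 3 replicates x 15 segments x 15 fields) yields 405
#' maps and a 6,075-row observation table.
#'
#' @param scenarios Named list of [colonization_params()]; must cover every
#'   design variant.
#' @param design A [study_design()].
#' @param seed Master integer seed.
#' @return List with elements `maps` (list of [myco_map()]) and
#'   `observations` (long tibble, one row per microscopic field).
#' @export
generate_study <- function(scenarios = default_scenarios(),
                           design = study_design(), seed = 1L) {
  missing_sc <- setdiff(design$variants, names(scenarios))
  if (length(missing_sc) > 0L) {
    stop("configuration error: no scenario for variant(s): ",
         paste(missing_sc, collapse = ", "), call. = FALSE)
  }
  layout <- expand.grid(segment = seq_len(design$segments),
                        replicate = seq_len(design$replicates),
                        variant = design$variants,
                        stringsAsFactors = FALSE)
  layout <- layout[order(match(layout$variant, design$variants),
                         layout$replicate, layout$segment), ]
  maps <- lapply(seq_len(nrow(layout)), function(i) {
    generate_map(scenarios, layout$variant[i], layout$replicate[i],
                 layout$segment[i], design, seed)
  })
  list(maps = maps, observations = observation_table(maps))
}
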