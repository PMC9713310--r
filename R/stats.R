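# Group statistics over the per-map parameter table: one-way ANOVA with an
# LSD post-hoc compact letter display, a Pearson correlation matrix with
# t-based significance flags, arbuscule-vesicle co-occurrence pairs and a
# PCA ordination with group centroids.

#' One-way analysis of variance
#'
#' Classical between/within decomposition of `values` over the levels of
#' `groups` (the combined treatment x phenophase factor is treated as a
#' single multi-level factor).
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector of the same length.
#' @return List of class `anova_result`: `F`, `df1`, `df2`, `p`, `mse`,
#'   `ss_between`, `ss_within`, `group_means`, `group_sizes`, and a
#'   `degenerate` flag (TRUE when both sums of squares are zero, in which
#'   case `F` and `p` are `NaN`).
#' @export
one_way_anova <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  g <- factor(groups)
  if (nlevels(g) < 2L) {
    stop("input error: ANOVA needs at least 2 groups", call. = FALSE)
  }
  sizes <- table(g)
  if (any(sizes < 2L)) {
    stop("input error: every group needs at least 2 observations; ",
         "offending group(s): ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  means <- tapply(values, g, mean)
  grand <- mean(values)
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum((values - means[g])^2)
  df1 <- nlevels(g) - 1L
  df2 <- length(values) - nlevels(g)
  mse <- ssw / df2
  degenerate <- ssb < 1e-300 && ssw < 1e-300
  F_ <- if (degenerate) NaN else ssb / df1 / mse
  p <- if (degenerate) NaN else stats::pf(F_, df1, df2, lower.tail = FALSE)
  structure(
    list(F = F_, df1 = df1, df2 = df2, p = p, mse = mse,
         ss_between = ssb, ss_within = ssw,
         group_means = as.numeric(means),
         group_sizes = as.integer(sizes),
         group_levels = levels(g),
         degenerate = degenerate),
    class = "anova_result"
  )
}

#' Least-significant-difference letter display
#'
#' Pairwise LSD at level `alpha`:
#' `LSD_ij = t(1 - alpha/2, df) * sqrt(mse * (1/n_i + 1/n_j))`; two groups
#' differ when their mean difference exceeds it. Letters are assigned by
#' scanning the means in descending order and lettering every maximal run
#' of mutually non-different groups, so groups sharing a letter are
#' pairwise non-significant and groups sharing none differ.
#'
#' @param means Named numeric vector of group means (names = group labels).
#' @param sizes Group sizes, recycled if scalar.
#' @param mse ANOVA mean square error.
#' @param df Error degrees of freedom.
#' @param alpha Significance level.
#' @return Tibble `group, mean, n, letters`, ordered by descending mean,
#'   with the pairwise `distinct` logical matrix as attribute
#'   `"pairwise"`. If no letter assignment can represent the pairwise
#'   matrix (possible with very unbalanced sizes) a warning is raised.
#' @export
lsd_letters <- function(means, sizes, mse, df, alpha = 0.05) {
  if (df <= 0) stop("input error: error df must be positive", call. = FALSE)
  k <- length(means)
  if (is.null(names(means))) names(means) <- paste0("g", seq_len(k))
  sizes <- rep_len(sizes, k)
  tcrit <- stats::qt(1 - alpha / 2, df)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]; n <- sizes[ord]

  distinct <- matrix(FALSE, k, k, dimnames = list(names(m), names(m)))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      lsd <- tcrit * sqrt(mse * (1 / n[i] + 1 / n[j]))
      distinct[i, j] <- distinct[j, i] <- abs(m[i] - m[j]) > lsd
    }
  }

  # for every start, the maximal run of mutually non-distinct groups;
  # runs contained in another run are dropped, survivors get one letter each
  intervals <- lapply(seq_len(k), function(i) {
    j <- i
    while (j < k && !any(distinct[i:j, j + 1L])) j <- j + 1L
    c(i, j)
  })
  keep <- rep(TRUE, length(intervals))
  for (a in seq_along(intervals)) {
    for (b in seq_along(intervals)) {
      if (a != b && keep[b] &&
          intervals[[a]][1] <= intervals[[b]][1] &&
          intervals[[a]][2] >= intervals[[b]][2] &&
          !identical(intervals[[a]], intervals[[b]])) {
        keep[b] <- FALSE
      }
    }
  }
  intervals <- intervals[keep]
  letter_of <- vapply(seq_along(intervals), function(a) {
    paste(rep(letters[(a - 1L) %% 26L + 1L], (a - 1L) %/% 26L + 1L),
          collapse = "")
  }, "")
  lab <- vapply(seq_len(k), function(g) {
    paste(letter_of[vapply(intervals, function(iv) {
      g >= iv[1] && g <= iv[2]
    }, TRUE)], collapse = "")
  }, "")

  # verify the display reproduces the pairwise matrix
  share <- outer(seq_len(k), seq_len(k), Vectorize(function(a, b) {
    any(strsplit(lab[a], "")[[1]] %in% strsplit(lab[b], "")[[1]])
  }))
  if (any(share[distinct]) || any(!share[!distinct & upper.tri(distinct)])) {
    warning("LSD letter display cannot represent the pairwise pattern ",
            "exactly (non-interval significance structure)", call. = FALSE)
  }

  out <- tibble::tibble(group = names(m), mean = as.numeric(m),
                        n = as.integer(n), letters = lab)
  attr(out, "pairwise") <- distinct
  out
}

#' ANOVA + LSD letters for every colonization parameter
#'
#' @param metrics Long metrics table from [metrics_long_table()].
#' @param group Grouping column (default `"variant"`).
#' @param alpha Significance level.
#' @return Tibble with one row per group x parameter (`mean, se, letters,
#'   n`) plus per-parameter `F` and `p` columns, mirroring the layout of a
#'   variant-by-parameter summary table.
#' @export
anova_lsd_table <- function(metrics, group = "variant", alpha = 0.05) {
  out <- lapply(METRIC_COLS, function(param) {
    av <- one_way_anova(metrics[[param]], metrics[[group]])
    means <- stats::setNames(av$group_means, av$group_levels)
    lt <- lsd_letters(means, av$group_sizes, av$mse, av$df2, alpha)
    se <- tapply(metrics[[param]], factor(metrics[[group]]), function(x) {
      stats::sd(x) / sqrt(length(x))
    })
    lt$se <- as.numeric(se[lt$group])
    lt$parameter <- param
    lt$F <- av$F
    lt$p <- av$p
    lt[, c("parameter", "group", "mean", "se", "n", "letters", "F", "p")]
  })
  dplyr::bind_rows(out)
}

#' Pearson correlation matrix with significance flags
#'
#' All pairwise correlations between the parameter columns, with two-sided
#' t-based p-values and an `ns` flag at level `alpha`. Constant columns are
#' flagged and their correlations set to `NA` rather than raising an error.
#'
#' @param metrics Long metrics table (or any data frame); only the columns
#'   in `parameters` are used.
#' @param parameters Character vector of column names (default: the eight
#'   tabulated parameters).
#' @param alpha Significance level for the `ns` flag.
#' @return List of class `cor_matrix`: `r`, `p`, `significant` (logical),
#'   `n`, `constant` (names of zero-variance columns).
#' @export
pearson_matrix <- function(metrics,
                           parameters = c("F", "I", "Arb", "Ves", "nonM",
                                          "DC", "MnonM", "AV"),
                           alpha = 0.05) {
  x <- as.data.frame(metrics)[, parameters, drop = FALSE]
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 maps for correlations", call. = FALSE)
  sds <- vapply(x, stats::sd, 0)
  constant <- names(sds)[sds == 0 | is.na(sds)]
  r <- suppressWarnings(stats::cor(x))
  r[constant, ] <- NA_real_
  r[, constant] <- NA_real_
  diag(r) <- ifelse(colnames(r) %in% constant, NA_real_, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  diag(p) <- 0
  structure(
    list(r = r, p = p, significant = p < alpha, n = n, constant = constant,
         alpha = alpha),
    class = "cor_matrix"
  )
}

#' @export
print.cor_matrix <- function(x, digits = 2, ...) {
  cat("Pearson correlations (n = ", x$n, "), 'ns' at p >= ", x$alpha,
      ":\n", sep = "")
  disp <- matrix(sprintf("%.*f", digits, x$r), nrow = nrow(x$r),
                 dimnames = dimnames(x$r))
  disp[!x$significant & !is.na(x$r)] <-
    paste0(disp[!x$significant & !is.na(x$r)], " ns")
  print(disp, quote = FALSE)
  if (length(x$constant) > 0L) {
    cat("constant column(s):", paste(x$constant, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Arbuscule-vesicle co-occurrence pairs
#'
#' One (arbuscule %, vesicle %) pair per map, grouped for scatterplotting
#' the simultaneous presence of the two structures.
#'
#' @param metrics Long metrics table from [metrics_long_table()].
#' @param group Grouping column (default `"variant"`).
#' @return Tibble `group, Arb, Ves`, one row per map.
#' @export
cooccurrence_pairs <- function(metrics, group = "variant") {
  tibble::tibble(group = metrics[[group]], Arb = metrics$Arb,
                 Ves = metrics$Ves)
}

#' PCA ordination of the colonization parameters
#'
#' Principal components of the standardized (correlation-matrix) parameter
#' table, with per-map scores, loadings, explained-variance fractions and
#' per-group score centroids. The non-mycorrhizal-area column is excluded
#' by default: it is perfectly collinear with intensity, so its vector
#' carries no extra information (set `include_nonM = TRUE` to display the
#' combined intensity/non-mycorrhizal axis anyway).
#'
#' @param metrics Long metrics table from [metrics_long_table()].
#' @param group Grouping column for centroids (default `"variant"`).
#' @param parameters Parameter columns to ordinate.
#' @param include_nonM Keep the `nonM` column?
#' @return List of class `pca_ordination`: `scores`, `loadings`,
#'   `explained` (fractions summing to 1), `centroids` (tibble), `rank`
#'   (number of non-degenerate components) and `dropped` (zero-variance
#'   columns removed before scaling).
#' @export
pca_ordination <- function(metrics, group = "variant",
                           parameters = c("F", "I", "Arb", "Ves", "nonM",
                                          "DC", "MnonM", "AV"),
                           include_nonM = FALSE) {
  if (!include_nonM) parameters <- setdiff(parameters, "nonM")
  x <- as.data.frame(metrics)[, parameters, drop = FALSE]
  if (nrow(x) < 3L || ncol(x) < 2L) {
    stop("PCA needs >= 3 maps and >= 2 parameters", call. = FALSE)
  }
  sds <- vapply(x, stats::sd, 0)
  dropped <- names(sds)[sds == 0 | is.na(sds)]
  x <- x[, setdiff(names(x), dropped), drop = FALSE]
  fit <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  explained <- fit$sdev^2 / sum(fit$sdev^2)
  rank <- sum(fit$sdev > 1e-10)
  g <- factor(metrics[[group]])
  centroids <- stats::aggregate(fit$x, list(group = g), mean)
  structure(
    list(scores = fit$x, loadings = fit$rotation, explained = explained,
         centroids = tibble::as_tibble(centroids), rank = rank,
         dropped = dropped),
    class = "pca_ordination"
  )
}
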