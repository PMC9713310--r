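test_that("one-way ANOVA matches the classical decomposition and the t-test", {
  set.seed(51)
  # two-group F equals the squared equal-variance t statistic
  for (i in 1:10) {
    y <- rnorm(24)
    g <- rep(c("a", "b"), each = 12)
    av <- one_way_anova(y, g)
    tt <- t.test(y[g == "a"], y[g == "b"], var.equal = TRUE)
    expect_equal(av$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(av$p, tt$p.value, tolerance = 1e-10)
    # sums of squares decompose the total
    expect_equal(av$ss_between + av$ss_within, sum((y - mean(y))^2),
                 tolerance = 1e-10)
  }
  # cross-check against stats::aov on a multi-group draw
  y <- rnorm(60); g <- rep(letters[1:5], each = 12)
  av <- one_way_anova(y, g)
  ref <- summary(stats::aov(y ~ factor(g)))[[1]]
  expect_equal(av$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(av$mse, ref$`Mean Sq`[2], tolerance = 1e-10)
})

test_that("degenerate and invalid ANOVA inputs are handled", {
  expect_true(one_way_anova(rep(5, 10), rep(c("a", "b"), 5))$degenerate)
  expect_true(is.nan(one_way_anova(rep(5, 10), rep(c("a", "b"), 5))$F))
  # equal group means with noise give a near-zero F
  set.seed(52)
  eps <- rnorm(20, sd = 0.1)
  y <- c(eps, eps + 0)  # same mean structure in both groups
  av <- one_way_anova(c(10 + eps, 10 + eps), rep(c("a", "b"), each = 20))
  expect_lt(av$F, 1e-10)
  expect_error(one_way_anova(1:5, c("a", "a", "a", "a", "b")),
               "at least 2 observations")
  expect_error(one_way_anova(1:5, rep("a", 5)), "at least 2 groups")
})

test_that("LSD letters follow the pairwise threshold decisions", {
  # far-apart means get distinct letters
  lt <- lsd_letters(c(g1 = 10, g2 = 50), sizes = 10, mse = 4, df = 18)
  expect_equal(lt$letters, c("a", "b"))
  # identical means share one letter
  lt <- lsd_letters(c(g1 = 10, g2 = 10, g3 = 10), sizes = 10, mse = 4,
                    df = 27)
  expect_equal(lt$letters, c("a", "a", "a"))
  # only the extremes differ: a / ab / b
  # LSD = qt(.975, 27) * sqrt(4 * 2/10) ~= 1.84; gaps of 1.2 vs 2.4
  lt <- lsd_letters(c(lo = 10, mid = 11.2, hi = 12.4), sizes = 10, mse = 4,
                    df = 27)
  expect_equal(lt$letters, c("a", "ab", "b"))
  expect_equal(lt$group, c("hi", "mid", "lo"))
  expect_error(lsd_letters(c(a = 1, b = 2), 5, 1, df = 0), "positive")
})

test_that("letter displays reproduce the brute-force pairwise matrix", {
  set.seed(53)
  for (i in 1:50) {
    k <- sample(3:8, 1)
    means <- stats::setNames(rnorm(k, sd = sample(c(0.5, 2, 5), 1)),
                             paste0("g", 1:k))
    n <- sample(5:15, 1)
    mse <- runif(1, 0.5, 4)
    df <- k * (n - 1)
    lt <- lsd_letters(means, n, mse, df)
    tcrit <- qt(0.975, df)
    lsd <- tcrit * sqrt(mse * 2 / n)
    share <- function(a, b) {
      any(strsplit(a, "")[[1]] %in% strsplit(b, "")[[1]])
    }
    for (a in 1:(k - 1)) {
      for (b in (a + 1):k) {
        differ <- abs(lt$mean[a] - lt$mean[b]) > lsd
        expect_equal(!share(lt$letters[a], lt$letters[b]), differ)
      }
    }
  }
})

test_that("the ANOVA-LSD table mirrors the group summary layout", {
  d <- tiny_design(segments = 5)
  st <- generate_study(default_scenarios()[d$variants], d, seed = 6)
  tab <- anova_lsd_table(metrics_long_table(st$maps))
  expect_setequal(unique(tab$parameter),
                  c("F", "I", "Arb", "Ves", "Sp", "Hyp", "nonM", "DC",
                    "MnonM", "AV"))
  expect_equal(nrow(tab), 10 * 2)  # parameters x groups
  expect_true(all(tab$letters != ""))
})

test_that("Pearson correlations carry exact structural identities and ns flags", {
  d <- tiny_design(segments = 6)
  st <- generate_study(default_scenarios()[d$variants], d, seed = 14)
  mt <- metrics_long_table(st$maps)
  cm <- pearson_matrix(mt)
  expect_equal(cm$r["I", "nonM"], -1, tolerance = 1e-12)
  expect_equal(cm$r["I", "I"], 1)
  expect_true(isSymmetric(cm$r))
  expect_true(all(abs(cm$r[!is.na(cm$r)]) <= 1 + 1e-12))
  # independent noise columns: small r, flagged ns
  set.seed(54)
  x <- data.frame(a = rnorm(1000), b = rnorm(1000))
  cm2 <- pearson_matrix(x, parameters = c("a", "b"))
  expect_lt(abs(cm2$r["a", "b"]), 0.1)
  expect_false(cm2$significant["a", "b"])
  # constant columns are flagged, not fatal
  x$c <- 1
  cm3 <- pearson_matrix(x, parameters = c("a", "b", "c"))
  expect_equal(cm3$constant, "c")
  expect_true(all(is.na(cm3$r["c", ])))
  expect_error(pearson_matrix(x[1:2, ], parameters = c("a", "b")),
               "at least 3")
})

test_that("co-occurrence pairs are one (Arb, Ves) point per map", {
  d <- tiny_design()
  st <- generate_study(default_scenarios()[d$variants], d, seed = 15)
  mt <- metrics_long_table(st$maps)
  co <- cooccurrence_pairs(mt)
  expect_equal(nrow(co), n_maps(d))
  expect_true(all(co$Arb >= 0 & co$Ves >= 0))
  one <- make_map(list(counts_field(hypha = 30, arb = 15, ves = 5)))
  co1 <- cooccurrence_pairs(metrics_long_table(list(one)))
  expect_equal(co1$Arb, 15)
  expect_equal(co1$Ves, 5)
  # a vesicle-free study sits on the Ves = 0 axis
  sc0 <- list(A1_B2 = colonization_params(phi = 1, p = 0.4, alpha = 0.3,
                                          nu = 0))
  d0 <- study_design(variants = "A1_B2", replicates = 1, segments = 10,
                     fields = 5, grid_rows = 5, grid_cols = 5)
  co0 <- cooccurrence_pairs(
    metrics_long_table(generate_study(sc0, d0, seed = 4)$maps))
  expect_true(all(co0$Ves == 0))
})

test_that("the PCA ordination is an orthonormal eigendecomposition with centroids", {
  d <- tiny_design(segments = 8)
  st <- generate_study(default_scenarios()[d$variants], d, seed = 16)
  mt <- metrics_long_table(st$maps)
  pca <- pca_ordination(mt)
  # loadings orthonormal, explained variance sums to one
  L <- pca$loadings
  expect_equal(t(L) %*% L, diag(ncol(L)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(pca$explained), 1, tolerance = 1e-12)
  # centroids are the member-score means
  for (g in unique(mt$variant)) {
    want <- colMeans(pca$scores[mt$variant == g, , drop = FALSE])
    got <- as.numeric(pca$centroids[pca$centroids$group == g, -1])
    expect_equal(got, unname(want), tolerance = 1e-10)
  }
  # retained components reconstruct the standardized data
  X <- scale(as.data.frame(mt)[, rownames(L)])
  recon <- pca$scores %*% t(L)
  expect_lt(max(abs(recon - X)), 1e-8)
  # nonM is excluded by default, included on request
  expect_false("nonM" %in% rownames(L))
  expect_true("nonM" %in%
                rownames(pca_ordination(mt, include_nonM = TRUE)$loadings))
})

test_that("collinear inputs concentrate the variance on the first component", {
  x <- data.frame(variant = "v", a = 1:30, b = 2 * (1:30) + 3)
  pca <- pca_ordination(x, parameters = c("a", "b"))
  expect_equal(pca$explained[1], 1, tolerance = 1e-12)
  expect_equal(pca$rank, 1)
})

test_that("PCA scores agree with an independent ordination implementation", {
  skip_if_not_installed("vegan")
  d <- tiny_design(segments = 5)
  st <- generate_study(default_scenarios()[d$variants], d, seed = 26)
  mt <- metrics_long_table(st$maps)
  pca <- pca_ordination(mt)
  X <- as.data.frame(mt)[, rownames(pca$loadings)]
  rda <- vegan::rda(X, scale = TRUE)
  ref <- vegan::scores(rda, display = "sites", choices = 1:2,
                       scaling = 0)
  # same subspace up to per-axis sign and scale
  for (ax in 1:2) {
    expect_equal(abs(stats::cor(pca$scores[, ax], ref[, ax])), 1,
                 tolerance = 1e-8)
  }
})
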