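test_that("OLS recovers exact linear relations and the stated AIC convention", {
  x <- matrix(1:10, dimnames = list(NULL, "x"))
  y <- 2 * (1:10) + 1
  fit <- fit_linear_model(y, x)
  expect_equal(unname(fit$coefficients), c(1, 2), tolerance = 1e-10)
  expect_lt(fit$rss, 1e-18)
  # a numerically exact fit drives the AIC far below the intercept model
  expect_lt(fit$aic, fit_linear_model(y)$aic - 100)
  expect_equal(mycomaps:::ols_aic(10, 0, 1), -Inf)
  # AIC closed form: n log(RSS/n) + 2(k+1)
  expect_equal(mycomaps:::ols_aic(n = 10, rss = 10, k = 1), 4.0)
  expect_equal(mycomaps:::ols_aic(n = 20, rss = 40, k = 3),
               20 * log(2) + 8)
})

test_that("OLS coefficients match the pseudoinverse oracle on random instances", {
  set.seed(61)
  for (i in 1:20) {
    n <- sample(20:40, 1); k <- sample(1:5, 1)
    X <- matrix(rnorm(n * k), n, dimnames = list(NULL, paste0("x", 1:k)))
    y <- rnorm(n)
    fit <- fit_linear_model(y, X)
    Xi <- cbind(1, X)
    beta <- solve(t(Xi) %*% Xi) %*% t(Xi) %*% y
    expect_equal(unname(fit$coefficients), as.numeric(beta),
                 tolerance = 1e-8)
    # AIC matches the lm/extractAIC convention
    lmfit <- stats::lm(y ~ X)
    expect_equal(fit$aic, stats::extractAIC(lmfit)[2], tolerance = 1e-8)
  }
})

test_that("rank-deficient and undersized fits raise informative errors", {
  X <- cbind(a = rnorm(10), b = 1:10)
  X <- cbind(X, c = X[, "a"] + X[, "b"])
  expect_error(fit_linear_model(rnorm(10), X), "singular")
  expect_error(fit_linear_model(rnorm(3), cbind(a = 1:3, b = c(2, 1, 3))),
               "n > predictors")
})

test_that("stepwise selection finds planted predictors and stays at the intercept for noise", {
  set.seed(62)
  # an exact single-predictor relation is selected with ~zero residual
  x <- data.frame(u = rnorm(50), v = rnorm(50), w = rnorm(50))
  y <- 3 * x$v - 1
  m <- stepwise_select(y, x)
  expect_equal(m$predictors, "v")
  expect_lt(m$rss, 1e-18)
  expect_equal(unname(m$coefficients["v"]), 3, tolerance = 1e-10)

  # pure noise keeps the intercept-only model at the closed-form rate:
  # a lone candidate enters iff its squared sample correlation exceeds
  # 1 - exp(-2/n) (AIC improvement condition), and under the null
  # r^2 ~ Beta(1/2, (n-2)/2); with c near-independent candidates the
  # intercept survives with probability ~ (1 - p_single)^c
  n <- 200
  p_single <- stats::pbeta(1 - exp(-2 / n), 1 / 2, (n - 2) / 2,
                           lower.tail = FALSE)
  p_keep <- (1 - p_single)^3
  keep <- vapply(1:100, function(r) {
    set.seed(6200 + r)
    cand <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    length(stepwise_select(rnorm(n), cand)$predictors) == 0
  }, TRUE)
  expect_lt(abs(mean(keep) - p_keep),
            3 * sqrt(p_keep * (1 - p_keep) / 100))
})

test_that("the accepted trace is strictly AIC-decreasing and ends at the reported model", {
  set.seed(63)
  x <- as.data.frame(matrix(rnorm(300), 50, 6,
                            dimnames = list(NULL, paste0("x", 1:6))))
  y <- 2 * x$x1 - x$x4 + rnorm(50, sd = 0.5)
  m <- stepwise_select(y, x)
  expect_true(all(diff(m$trace$aic) < 0))
  expect_equal(m$trace$aic[nrow(m$trace)], m$aic)
  expect_true(all(c("x1", "x4") %in% m$predictors))
})

test_that("stepwise reaches the exhaustive all-subsets optimum on small candidate pools", {
  set.seed(64)
  for (i in 1:5) {
    n <- 60; k <- 8
    X <- as.data.frame(matrix(rnorm(n * k), n,
                              dimnames = list(NULL, paste0("x", 1:k))))
    beta <- c(1.5, 0, 0, -2, 0, 0.8, 0, 0)
    y <- as.matrix(X) %*% beta + rnorm(n)
    m <- stepwise_select(y, X)
    # exhaustive search over all 2^8 subsets
    best_aic <- Inf
    for (mask in 0:(2^k - 1)) {
      sel <- paste0("x", 1:k)[bitwAnd(mask, 2^(0:(k - 1))) > 0]
      aic <- fit_linear_model(y, if (length(sel)) X[sel])$aic
      best_aic <- min(best_aic, aic)
    }
    expect_equal(m$aic, best_aic, tolerance = 1e-9)
  }
})

test_that("stepwise agrees with the reference stepwise implementation", {
  set.seed(65)
  X <- as.data.frame(matrix(rnorm(200), 40, 5,
                            dimnames = list(NULL, paste0("x", 1:5))))
  y <- 1 + 2 * X$x2 - 3 * X$x5 + rnorm(40)
  m <- stepwise_select(y, X)
  dat <- cbind(y = y, X)
  ref <- stats::step(stats::lm(y ~ 1, data = dat),
                     scope = stats::formula(stats::lm(y ~ ., data = dat)),
                     direction = "both", trace = 0)
  expect_setequal(m$predictors, setdiff(names(stats::coef(ref)),
                                        "(Intercept)"))
  expect_equal(m$aic, stats::extractAIC(ref)[2], tolerance = 1e-8)
})

test_that("collinear candidates are skipped instead of crashing the search", {
  set.seed(66)
  x <- data.frame(a = rnorm(30))
  x$b <- 100 - x$a  # exact complement, as intensity and non-mycorrhizal area
  y <- 2 * x$a + rnorm(30, sd = 0.1)
  m <- stepwise_select(y, x)
  expect_length(m$predictors, 1)
  expect_lt(m$aic, fit_linear_model(y)$aic)
})

test_that("forecast predictions are the linear combination of stored coefficients", {
  m <- structure(list(intercept = 60.28,
                      coefficients = c(B1_I = 2.4),
                      predictors = "B1_I"),
                 class = "forecast_model")
  expect_equal(forecast_parameter(m, list(B1_I = 10)), 84.28)
  expect_error(forecast_parameter(m, list(B1_F = 10)), "missing predictor")
  m0 <- structure(list(intercept = 7.5, coefficients = numeric(0),
                       predictors = character(0)),
                  class = "forecast_model")
  expect_equal(forecast_parameter(m0, list()), 7.5)
  # OLS identity: training predictions average to the mean response
  set.seed(67)
  x <- data.frame(a = rnorm(40), b = rnorm(40))
  y <- 5 + x$a - 2 * x$b + rnorm(40)
  fit <- stepwise_select(y, x)
  preds <- forecast_parameter(fit, x)
  expect_equal(mean(preds), mean(y), tolerance = 1e-10)
})

test_that("stage models use only strictly earlier stages as candidates", {
  d <- study_design(variants = c("A0_B1", paste0("A1_B", 2:5)),
                    replicates = 3, segments = 6, fields = 6,
                    grid_rows = 6, grid_cols = 6)
  st <- generate_study(default_scenarios()[d$variants], d, seed = 20)
  mt <- metrics_long_table(st$maps)
  models <- build_stage_models(mt, arm = "untreated")
  # a B2 response draws candidates from B1 only
  cand_b2 <- attr(models[["B2_F"]], "candidates")
  expect_true(all(startsWith(cand_b2, "B1_")))
  expect_length(cand_b2, 8)
  # a B5 response sees 4 earlier stages x 8 parameters = 32 candidates
  cand_b5 <- attr(models[["B5_I"]], "candidates")
  expect_length(cand_b5, 32)
  expect_setequal(unique(sub("_.*", "", cand_b5)),
                  c("B1", "B2", "B3", "B4"))
  # every selected predictor comes from the candidate pool
  for (key in names(models)) {
    expect_true(all(models[[key]]$predictors %in%
                      attr(models[[key]], "candidates")))
  }
  # one model per parameter per stage >= 2
  expect_length(models, 8 * 4)
})

test_that("planted cross-stage effects are recovered by the stage models", {
  # B2 intensity depends linearly on B1 vesicles by construction:
  # replicate the study table, overwrite the response, and refit
  reps <- vapply(1:100, function(r) {
    set.seed(700 + r)
    n <- 45
    b1 <- data.frame(B1_F = runif(n, 40, 90), B1_I = runif(n, 20, 60),
                     B1_Arb = runif(n, 0, 15), B1_Ves = runif(n, 0, 3),
                     B1_DC = runif(n, 10, 50), B1_MnonM = runif(n, 0.2, 2),
                     B1_AV = runif(n, 0, 2))
    b1$B1_nonM <- 100 - b1$B1_I
    y <- 20 + 4 * b1$B1_Ves + rnorm(n, sd = 1)
    m <- stepwise_select(y, b1)
    if (!"B1_Ves" %in% m$predictors) return(FALSE)
    # coefficient recovery is judged on the full-candidate refit, which is
    # free of post-selection bias (nonM dropped: collinear with I)
    fit <- stats::lm(y ~ ., data = b1[, setdiff(names(b1), "B1_nonM")])
    est <- stats::coef(fit)[["B1_Ves"]]
    se <- summary(fit)$coefficients["B1_Ves", "Std. Error"]
    abs(est - 4) < 2 * se
  }, TRUE)
  expect_gte(mean(reps), 0.9)
})

test_that("zero-variance responses collapse to intercept-only models with a warning", {
  d <- study_design(variants = c("A0_B1", "A1_B2"), replicates = 3,
                    segments = 4, fields = 4, grid_rows = 4, grid_cols = 4)
  sc <- list(A0_B1 = colonization_params(phi = 0.7, p = 0.5, alpha = 0.2),
             A1_B2 = colonization_params(phi = 1, p = 1))  # saturated stage
  st <- generate_study(sc, d, seed = 21)
  mt <- metrics_long_table(st$maps)
  w <- capture_warnings(models <- build_stage_models(mt,
                                                     arm = "untreated"))
  expect_true(any(grepl("zero variance", w)))
  expect_length(models[["B2_F"]]$predictors, 0)
  expect_equal(models[["B2_F"]]$intercept, 100)
})
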