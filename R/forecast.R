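# Stage-to-stage forecast models: for each colonization parameter at a
# growth stage >= 2, an ordinary-least-squares model on the parameters of
# all strictly earlier stages, with predictors chosen by bidirectional
# stepwise search under the Akaike information criterion
# AIC = n*log(RSS/n) + 2*(k+1)   (Gaussian likelihood up to a constant,
# k = number of predictors; identical to stats::extractAIC for lm fits).

ols_aic <- function(n, rss, k) {
  if (rss <= 0) return(-Inf)
  n * log(rss / n) + 2 * (k + 1)
}

#' Ordinary least squares with the selection AIC
#'
#' QR-based OLS of `y` on the columns of `x` plus an intercept.
#'
#' @param y Numeric response vector.
#' @param x Numeric matrix or data frame of predictors (may have zero
#'   columns for the intercept-only model).
#' @return List: `coefficients` (intercept first), `fitted`, `residuals`,
#'   `rss`, `n`, `k`, `aic`.
#' @export
fit_linear_model <- function(y, x = NULL) {
  n <- length(y)
  x <- if (is.null(x)) matrix(nrow = n, ncol = 0) else as.matrix(x)
  if (nrow(x) != n) stop("predictor rows != length(y)", call. = FALSE)
  k <- ncol(x)
  if (n <= k + 1L) {
    stop("input error: need n > predictors + 1 (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, x)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    aliased <- colnames(X)[is.na(fit$coefficients)]
    stop("singular fit: column(s) ", paste(aliased, collapse = ", "),
         " are linearly dependent", call. = FALSE)
  }
  rss <- sum(fit$residuals^2)
  list(coefficients = fit$coefficients, fitted = fit$fitted.values,
       residuals = fit$residuals, rss = rss, n = n, k = k,
       aic = ols_aic(n, rss, k))
}

#' Bidirectional stepwise AIC selection
#'
#' Starts from the intercept-only model; at every step all single-predictor
#' additions and deletions are scored and the lowest-AIC move is accepted
#' if it strictly lowers the AIC, otherwise the search stops. Candidates
#' whose addition makes the fit singular are skipped. Deterministic for a
#' given column order (ties go to the earlier-scored move: additions in
#' column order, then deletions in selection order).
#'
#' @param y Numeric response.
#' @param candidates Numeric matrix/data frame of candidate predictors with
#'   column names.
#' @param direction `"both"` (default), `"forward"` (no deletions) or
#'   `"backward"` (start from the full model, no additions).
#' @return Object of class `forecast_model`: `response` (attr name if any),
#'   `intercept`, `coefficients` (named, selected predictors only), `n`,
#'   `rss`, `aic`, and `trace` (tibble `action, predictor, aic` of accepted
#'   steps, strictly decreasing in AIC after the start row).
#' @export
stepwise_select <- function(y, candidates, direction = "both") {
  direction <- match.arg(direction, c("both", "forward", "backward"))
  candidates <- as.data.frame(candidates)
  if (ncol(candidates) < 1L) {
    stop("need at least one candidate predictor", call. = FALSE)
  }
  nm <- names(candidates)
  current <- if (direction == "backward") nm else character(0)
  fit_cur <- fit_linear_model(y, if (length(current)) {
    candidates[current]
  })
  trace <- tibble::tibble(action = "start",
                          predictor = NA_character_,
                          aic = fit_cur$aic)
  repeat {
    moves <- list()
    if (direction != "backward") {
      for (v in setdiff(nm, current)) {
        moves[[length(moves) + 1L]] <- list(action = "add", predictor = v,
                                            set = c(current, v))
      }
    }
    if (direction != "forward") {
      for (v in current) {
        moves[[length(moves) + 1L]] <- list(action = "drop", predictor = v,
                                            set = setdiff(current, v))
      }
    }
    if (length(moves) == 0L) break
    aics <- vapply(moves, function(mv) {
      tryCatch(fit_linear_model(y, if (length(mv$set)) {
        candidates[mv$set]
      })$aic, error = function(e) Inf)
    }, 0)
    best <- which.min(aics)  # first minimum on ties
    if (!(aics[best] < fit_cur$aic - 1e-10)) break
    current <- moves[[best]]$set
    fit_cur <- fit_linear_model(y, if (length(current)) {
      candidates[current]
    })
    trace <- rbind(trace, tibble::tibble(action = moves[[best]]$action,
                                         predictor = moves[[best]]$predictor,
                                         aic = fit_cur$aic))
  }
  coefs <- fit_cur$coefficients
  structure(
    list(intercept = unname(coefs[1]),
         coefficients = coefs[-1],
         predictors = current,
         n = fit_cur$n, rss = fit_cur$rss, aic = fit_cur$aic,
         trace = trace),
    class = "forecast_model"
  )
}

#' @export
print.forecast_model <- function(x, ...) {
  cat("Forecast model (stepwise AIC): intercept ",
      sprintf("%.4g", x$intercept), sep = "")
  if (length(x$coefficients) > 0L) {
    cat(", predictors:\n")
    for (v in names(x$coefficients)) {
      cat(sprintf("  %+.4g * %s\n", x$coefficients[[v]], v))
    }
  } else {
    cat(" (intercept-only)\n")
  }
  cat(sprintf("n = %d, RSS = %.4g, AIC = %.4g, %d accepted step(s)\n",
              x$n, x$rss, x$aic, nrow(x$trace) - 1L))
  invisible(x)
}

#' Predict from a forecast model
#'
#' `intercept + sum(coefficient * predictor)` over the model's selected
#' predictors.
#'
#' @param model A `forecast_model`.
#' @param newdata Named list, vector or data frame holding every selected
#'   predictor.
#' @return Numeric prediction(s).
#' @export
forecast_parameter <- function(model, newdata) {
  stopifnot(inherits(model, "forecast_model"))
  newdata <- as.data.frame(as.list(newdata))
  if (nrow(newdata) == 0L && length(model$predictors) == 0L) {
    return(model$intercept)
  }
  missing_p <- setdiff(model$predictors, names(newdata))
  if (length(missing_p) > 0L) {
    stop("input error: missing predictor(s): ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  out <- rep(model$intercept, nrow(newdata))
  for (v in model$predictors) {
    out <- out + model$coefficients[[v]] * newdata[[v]]
  }
  out
}

# Wide stage table: one row per (replicate, unit), one column per
# stage_parameter. Pairing across destructively-sampled stages is by rank
# of the ranking parameter within replicate ("rank", default) or by segment
# index ("segment", exact when synthetic data carries longitudinal
# identity).
stage_wide_table <- function(metrics, pairing = c("rank", "segment"),
                             rank_by = "DC") {
  pairing <- match.arg(pairing)
  metrics <- dplyr::arrange(metrics, .data$phenophase, .data$replicate,
                            .data$segment)
  if (pairing == "rank") {
    metrics <- dplyr::mutate(
      dplyr::group_by(metrics, .data$phenophase, .data$replicate),
      unit = rank(.data[[rank_by]], ties.method = "first"),
      .keep = "all"
    )
    metrics <- dplyr::ungroup(metrics)
  } else {
    metrics$unit <- metrics$segment
  }
  long <- tidyr::pivot_longer(
    metrics[, c("phenophase", "replicate", "unit", FORECAST_PARAMS)],
    cols = dplyr::all_of(FORECAST_PARAMS),
    names_to = "parameter", values_to = "value"
  )
  tidyr::pivot_wider(long,
                     names_from = c("phenophase", "parameter"),
                     names_sep = "_", values_from = "value")
}

FORECAST_PARAMS <- c("F", "I", "Arb", "Ves", "nonM", "DC", "MnonM", "AV")

#' Stage-to-stage forecast models for one treatment arm
#'
#' For every parameter and every growth stage from the second onward, a
#' stepwise-AIC model of that stage's parameter on all parameters of all
#' strictly earlier stages. The native first-stage profile (`A0_B1`) is
#' prepended to both arms as stage B1. Because stages are destructively
#' sampled, observations are paired across stages per replicate, either by
#' rank of a ranking parameter or by segment index (see `pairing`).
#'
#' @param metrics Long metrics table of the full study
#'   (see [metrics_long_table()]).
#' @param arm `"untreated"` (A1 plus the native A0 profile) or `"treated"`
#'   (A2 plus the native A0 profile).
#' @param pairing `"rank"` or `"segment"` (see Details).
#' @param rank_by Ranking parameter for `pairing = "rank"`.
#' @param parameters Response parameters to model.
#' @return Named list `"<stage>_<parameter>"` -> `forecast_model`; each
#'   model's `candidates` attribute lists its candidate pool. Zero-variance
#'   responses yield intercept-only models with a warning.
#' @export
build_stage_models <- function(metrics, arm = c("untreated", "treated"),
                               pairing = c("rank", "segment"),
                               rank_by = "DC",
                               parameters = FORECAST_PARAMS) {
  arm <- match.arg(arm)
  keep <- metrics$treatment %in% c("A0", if (arm == "untreated") "A1" else
                                   "A2")
  sub <- metrics[keep, , drop = FALSE]
  wide <- stage_wide_table(sub, pairing, rank_by)
  stages <- sort(unique(sub$phenophase))
  if (length(stages) < 2L) {
    stop("pairing error: need at least two linkable stages", call. = FALSE)
  }
  if (anyNA(wide)) {
    stop("pairing error: stages are not linkable into complete ",
         "(replicate, unit) rows", call. = FALSE)
  }
  models <- list()
  for (s_idx in 2:length(stages)) {
    target <- stages[s_idx]
    earlier <- stages[seq_len(s_idx - 1L)]
    cand_cols <- as.vector(outer(earlier, FORECAST_PARAMS, paste,
                                 sep = "_"))
    cand_cols <- intersect(cand_cols, names(wide))
    for (param in parameters) {
      y <- wide[[paste(target, param, sep = "_")]]
      key <- paste(target, param, sep = "_")
      if (stats::sd(y) == 0) {
        warning("response ", key, " has zero variance; intercept-only ",
                "model returned", call. = FALSE)
        fit0 <- fit_linear_model(y)
        models[[key]] <- structure(
          list(intercept = unname(fit0$coefficients[1]),
               coefficients = stats::setNames(numeric(0), character(0)),
               predictors = character(0), n = fit0$n, rss = fit0$rss,
               aic = fit0$aic,
               trace = tibble::tibble(action = "start",
                                      predictor = NA_character_,
                                      aic = fit0$aic)),
          class = "forecast_model")
      } else {
        models[[key]] <- stepwise_select(y, wide[cand_cols])
      }
      attr(models[[key]], "candidates") <- cand_cols
      attr(models[[key]], "response") <- key
    }
  }
  models
}

#' Export a model list as a coefficients table
#'
#' @param models Named list from [build_stage_models()].
#' @return Tibble `response, term, estimate, n, aic` (one `(Intercept)` row
#'   per model plus one row per selected predictor).
#' @export
forecast_models_table <- function(models) {
  rows <- lapply(names(models), function(key) {
    m <- models[[key]]
    tibble::tibble(
      response = key,
      term = c("(Intercept)", names(m$coefficients)),
      estimate = c(m$intercept, as.numeric(m$coefficients)),
      n = m$n,
      aic = m$aic
    )
  })
  dplyr::bind_rows(rows)
}
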