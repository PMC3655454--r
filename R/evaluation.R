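#' Forecast result container
#'
#' Bundles the predictions of a multi-step forecast with the matching
#' observed values (when known), per-step errors (`actual - predicted`)
#' and the aggregate RMSE. Step indices are 1-based absolute sample
#' indices: step `j` predicts sample `origin + j - 1`.
#'
#' @param origin 1-based index of the first forecast step.
#' @param predicted numeric vector of predictions.
#' @param actual optional numeric vector of observed values, same length.
#' @param model_descriptor free-text description of the forecaster.
#' @return an object of class `caar_forecast_result`: list with `origin`,
#'   `horizon`, `predicted`, `actual`, `errors`, `rmse`,
#'   `model_descriptor`. `errors` and `rmse` are `NULL` without actuals.
#' @export
forecast_result <- function(origin, predicted, actual = NULL,
                            model_descriptor = "") {
  stopifnot(length(predicted) >= 1)
  if (!is.null(actual) && length(actual) != length(predicted)) {
    stop("actual and predicted lengths differ", call. = FALSE)
  }
  errors <- if (is.null(actual)) NULL else actual - predicted
  structure(list(origin = as.integer(origin),
                 horizon = length(predicted),
                 predicted = as.numeric(predicted),
                 actual = if (is.null(actual)) NULL else as.numeric(actual),
                 errors = errors,
                 rmse = if (is.null(errors)) NULL else sqrt(mean(errors^2)),
                 model_descriptor = model_descriptor),
            class = "caar_forecast_result")
}

#' @export
print.caar_forecast_result <- function(x, ...) {
  cat(sprintf("<caar_forecast_result> %s: steps %d..%d (horizon %d)\n",
              x$model_descriptor, x$origin, x$origin + x$horizon - 1L,
              x$horizon))
  if (!is.null(x$rmse)) cat(sprintf("  RMSE %.6g\n", x$rmse))
  invisible(x)
}

#' Root mean square forecast error
#'
#' @param actual,predicted equal-length non-empty numeric vectors.
#' @return `sqrt(mean((actual - predicted)^2))`.
#' @examples
#' rmse(c(0, 0), c(3, 4))  # sqrt(12.5)
#' @export
rmse <- function(actual, predicted) {
  actual <- as.numeric(actual)
  predicted <- as.numeric(predicted)
  if (length(actual) == 0 || length(actual) != length(predicted)) {
    stop("rmse needs two equal-length, non-empty vectors", call. = FALSE)
  }
  sqrt(mean((actual - predicted)^2))
}

#' Nearest-neighbour window forecast (baseline)
#'
#' Analogue forecasting with a growing training span: to predict sample
#' `o`, the trailing window `x[o-m .. o-1]` is matched (Euclidean
#' distance) against every historical window of length `m` whose successor
#' lies inside the training span, and the best match's successor is the
#' prediction; ties go to the earliest match. The span starts at
#' `train_end` and grows by one observed sample per step — for the first
#' forecast the training period is `1..train_end`, for the next
#' `1..train_end + 1`, and so on.
#'
#' @param x a [caar_series()] or numeric vector.
#' @param start 1-based index of the first forecast step.
#' @param horizon number of steps (actuals must exist through
#'   `start + horizon - 1`).
#' @param window_m matching-window length (positive integer).
#' @param train_end last index of the initial training span; default
#'   `start - 1`.
#' @return a [forecast_result()].
#' @export
nn_forecast <- function(x, start, horizon, window_m, train_end = start - 1L) {
  x <- as.numeric(as_caar_series(x))
  stopifnot(window_m >= 1, window_m == as.integer(window_m), horizon >= 1)
  last <- start + horizon - 1L
  if (last > length(x)) {
    stop(sprintf("nearest-neighbour forecasting needs actuals through index %d",
                 last), call. = FALSE)
  }
  if (train_end > start - 1L) {
    stop("train_end cannot exceed start - 1", call. = FALSE)
  }
  if (train_end < window_m + 1L) {
    stop(sprintf(
      "training span 1..%d is too short for window length %d (needs at least %d samples)",
      train_end, window_m, window_m + 1L), call. = FALSE)
  }
  pred <- numeric(horizon)
  for (j in seq_len(horizon)) {
    o <- start + j - 1L
    span_end <- train_end + j - 1L          # training span 1..span_end
    query <- x[(o - window_m):(o - 1L)]
    ends <- window_m:(span_end - 1L)        # candidate window end indices
    d2 <- vapply(ends, function(e) {
      sum((x[(e - window_m + 1L):e] - query)^2)
    }, numeric(1))
    best <- ends[which.min(d2)]             # which.min takes the earliest tie
    pred[j] <- x[best + 1L]
  }
  forecast_result(origin = start, predicted = pred, actual = x[start:last],
                  model_descriptor = sprintf("nn(m=%d)", window_m))
}

#' Compare forecasting models on one series
#'
#' Runs each model specification over the same rolling split and tabulates
#' the RMSEs. A specification is a named list with `model` equal to
#' `"caar"`, `"ar"` or `"nn"` plus the model's parameters: `p` and
#' optional `W` for `"caar"`; `p`, optional `method` (`"yw"`/`"ls"`) and
#' `train_window` for `"ar"`; `m` and optional `train_end` for `"nn"`
#' (`m` defaults to the order of the first CA-AR spec, for a like-for-like
#' regressor span).
#'
#' @param x a [caar_series()] or numeric vector.
#' @param specs list of model specifications (possibly empty).
#' @param start 1-based index of the first forecast step.
#' @param horizon number of rolling steps.
#' @return a data frame with columns `model`, `order`, `window`, `start`,
#'   `horizon`, `rmse`, one row per spec in input order, plus the
#'   forecasts as attribute `"results"`.
#' @examples
#' x <- gen_ar(0.6, noise_sd = 1, length = 400, seed = 3)
#' compare_models(x, list(list(model = "caar", p = 3),
#'                        list(model = "ar", p = 3)),
#'                start = 301, horizon = 50)
#' @export
compare_models <- function(x, specs, start, horizon) {
  x <- as_caar_series(x)
  empty <- data.frame(model = character(), order = integer(),
                      window = integer(), start = integer(),
                      horizon = integer(), rmse = numeric())
  if (length(specs) == 0) return(empty)
  default_m <- NULL
  for (sp in specs) {
    if (identical(sp$model, "caar") && is.null(default_m)) default_m <- sp$p
  }
  rows <- empty
  results <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    if (is.null(sp$model)) stop(sprintf("spec %d has no model field", k),
                                call. = FALSE)
    res <- tryCatch(
      switch(sp$model,
        caar = {
          W <- if (is.null(sp$W)) sp$p else sp$W
          caar_forecast(x, start, horizon, p = sp$p, W = W, mode = "rolling")
        },
        ar = ar_forecast(x, start, horizon, p = sp$p,
                         method = if (is.null(sp$method)) "yw" else sp$method,
                         train_window = sp$train_window, mode = "rolling"),
        nn = {
          m <- if (!is.null(sp$m)) sp$m else default_m
          if (is.null(m)) stop("nn spec needs a window length m", call. = FALSE)
          nn_forecast(x, start, horizon, window_m = m,
                      train_end = if (is.null(sp$train_end)) start - 1L
                                  else sp$train_end)
        },
        stop(sprintf("unknown model '%s'", sp$model), call. = FALSE)),
      error = function(e) {
        stop(sprintf("model spec %d (%s) failed: %s", k, sp$model,
                     conditionMessage(e)), call. = FALSE)
      })
    results[[k]] <- res
    rows <- rbind(rows, data.frame(
      model = sp$model,
      order = if (sp$model == "nn") NA_integer_ else as.integer(sp$p),
      window = switch(sp$model,
        caar = if (is.null(sp$W)) as.integer(sp$p) else as.integer(sp$W),
        ar = if (is.null(sp$train_window)) NA_integer_
             else as.integer(sp$train_window),
        nn = if (!is.null(sp$m)) as.integer(sp$m) else as.integer(default_m)),
      start = as.integer(start),
      horizon = as.integer(horizon),
      rmse = if (is.null(res$rmse)) NA_real_ else res$rmse))
  }
  rownames(rows) <- NULL
  attr(rows, "results") <- results
  rows
}
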