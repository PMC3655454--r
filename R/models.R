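#' Fit a standard AR(p) model
#'
#' `fit_ar_yw()` solves the Yule-Walker equations from the sample
#' autocovariances of the mean-removed series (the textbook "standard AR"
#' estimator); `fit_ar_ls()` uses conditional least squares, regressing
#' `x_t` on `(1, x_{t-1}, ..., x_{t-p})`. For large stationary samples the
#' two should agree closely; near the unit root Yule-Walker is noticeably
#' biased toward stationarity, which is part of the motivation for the
#' sign-coerced forecaster.
#'
#' @param x a [caar_series()] or numeric vector with at least `p + 2`
#'   samples and positive variance.
#' @param p positive integer model order.
#' @return an object of class `caar_ar_model`: list with `order_p`,
#'   `coeffs`, `intercept` (set so the implied process mean matches the
#'   sample mean for `fit_ar_yw`; directly estimated for `fit_ar_ls`),
#'   `noise_var` and `method`.
#' @examples
#' x <- gen_ar(0.5, noise_sd = 1, length = 2000, seed = 1)
#' fit_ar_yw(x, 1)$coeffs
#' @export
fit_ar_yw <- function(x, p) {
  x <- as.numeric(as_caar_series(x))
  check_ar_input(x, p)
  f <- tryCatch(
    stats::ar(x, aic = FALSE, order.max = p, method = "yule-walker",
              demean = TRUE),
    error = function(e) {
      stop(sprintf("Yule-Walker system could not be solved: %s",
                   conditionMessage(e)), call. = FALSE)
    })
  coeffs <- as.numeric(f$ar)
  new_ar_model(p, coeffs, intercept = f$x.mean * (1 - sum(coeffs)),
               noise_var = as.numeric(f$var.pred), method = "yule-walker")
}

#' @rdname fit_ar_yw
#' @export
fit_ar_ls <- function(x, p) {
  x <- as.numeric(as_caar_series(x))
  check_ar_input(x, p)
  n <- length(x)
  y <- x[(p + 1):n]
  X <- cbind(1, vapply(seq_len(p), function(i) x[(p + 1 - i):(n - i)],
                       numeric(n - p)))
  fit <- stats::lm.fit(X, y)
  # pivoting drops aliased (collinear) lags; zero them, keeping the fitted
  # values of the pivoted least-squares solution
  fit$coefficients[is.na(fit$coefficients)] <- 0
  dof <- max(1L, length(y) - p - 1L)
  new_ar_model(p, as.numeric(fit$coefficients[-1]),
               intercept = as.numeric(fit$coefficients[1]),
               noise_var = sum(fit$residuals^2) / dof, method = "least-squares")
}

check_ar_input <- function(x, p) {
  stopifnot(p >= 1, p == as.integer(p))
  if (length(x) < p + 2) {
    stop(sprintf("need at least p + 2 = %d samples to fit AR(%d)", p + 2, p),
         call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("degenerate input: constant series has zero variance", call. = FALSE)
  }
}

new_ar_model <- function(p, coeffs, intercept, noise_var, method) {
  structure(list(order_p = as.integer(p), coeffs = coeffs,
                 intercept = intercept, noise_var = noise_var,
                 method = method),
            class = "caar_ar_model")
}

#' @export
print.caar_ar_model <- function(x, ...) {
  cat(sprintf("<caar_ar_model> AR(%d), %s\n  coeffs: %s\n  intercept %.6g, noise variance %.6g\n",
              x$order_p, x$method,
              paste(signif(x$coeffs, 5), collapse = " "),
              x$intercept, x$noise_var))
  invisible(x)
}

#' One-step AR prediction
#'
#' Returns `intercept + sum(coeffs_i * x_{t-i})` given the trailing history
#' (no noise term).
#'
#' @param model a `caar_ar_model`.
#' @param history numeric vector of at least `p` samples, most recent last.
#' @return the one-step prediction.
#' @export
ar_one_step <- function(model, history) {
  stopifnot(inherits(model, "caar_ar_model"))
  p <- model$order_p
  history <- as.numeric(history)
  if (length(history) < p) {
    stop(sprintf("need at least %d history samples for AR(%d)", p, p),
         call. = FALSE)
  }
  model$intercept + sum(model$coeffs * history[length(history) - seq_len(p) + 1L])
}

# Candidate sign matrix: 2^(p-1) rows, first column +1, remaining lags
# enumerated in lexicographic order with +1 before -1 and lag 2 most
# significant -- so which.min on RSS realizes the documented tie-break.
sign_candidates <- function(p) {
  K <- 2L^(p - 1L)
  S <- matrix(1, nrow = K, ncol = p)
  if (p > 1L) {
    k <- 0:(K - 1L)
    for (i in seq_len(p - 1L)) {
      S[, i + 1L] <- 1 - 2 * ((k %/% 2L^(p - 1L - i)) %% 2L)
    }
  }
  S
}

#' Select CA-AR signs at a forecast origin
#'
#' The coercively adjusted AR model replaces estimated coefficients with a
#' per-origin sign pattern: `x_t = c + sum(pi_i * x_{t-i}) + e_t` with
#' every `pi_i` in `{-1, +1}` and `pi_1 = +1`. At forecast origin `t` the
#' `W` most recent one-step pairs (targets `x_s`, regressors
#' `x_{s-1}..x_{s-p}`, `s = t-W .. t-1`) score every one of the
#' `2^(p-1)` admissible sign vectors: for each candidate the least-squares
#' intercept is the window mean of the residuals
#' `x_s - sum(pi_i * x_{s-i})`, and the candidate minimizing the residual
#' sum of squares wins. Ties break to the lexicographically smaller sign
#' vector (+1 before -1, lag 2 first), so the search is deterministic.
#'
#' @param x a [caar_series()] or numeric vector.
#' @param t forecast origin: 1-based index of the sample being predicted.
#' @param p positive integer order; `p > 20` is refused unless
#'   `force = TRUE` (the search is exponential in `p`).
#' @param W fit-window length (number of scoring pairs); default `p`.
#' @param force override the `p > 20` guard.
#' @return list with `signs` (length-`p` vector of +/-1), `intercept`,
#'   `rss`, and `window` (the pair targets used, `t-W .. t-1`).
#' @examples
#' x <- gen_caar(c(1, -1, 1), intercept = 0.3, length = 60, seed = 1)
#' select_signs(x, t = 50, p = 3)
#' @export
select_signs <- function(x, t, p, W = p, force = FALSE) {
  x <- as.numeric(as_caar_series(x))
  stopifnot(p >= 1, p == as.integer(p), W >= 1, W == as.integer(W))
  if (p > 20 && !force) {
    stop(sprintf(
      "p = %d implies %g sign candidates per step; pass force = TRUE to search anyway",
      p, 2^(p - 1)), call. = FALSE)
  }
  if (t > length(x) + 1L) {
    stop(sprintf("origin t = %d lies beyond the series end + 1 (%d)",
                 t, length(x) + 1L), call. = FALSE)
  }
  if (t - W - p < 1L) {
    stop(sprintf(
      "insufficient history at origin t = %d: sign selection needs the %d samples x[%d..%d]",
      t, W + p, t - W - p, t - 1L), call. = FALSE)
  }
  s_idx <- (t - W):(t - 1L)
  Y <- x[s_idx]
  L <- vapply(seq_len(p), function(i) x[s_idx - i], numeric(W))
  if (W == 1L) L <- matrix(L, nrow = 1L)
  S <- sign_candidates(p)
  R <- Y - L %*% t(S)              # W x 2^(p-1) residual targets
  chat <- colMeans(R)
  rss <- colSums((R - rep(chat, each = W))^2)
  k <- which.min(rss)
  list(signs = S[k, ], intercept = chat[k], rss = rss[k],
       window = range(s_idx))
}

#' One-step CA-AR forecast
#'
#' Selects the sign pattern and intercept at origin `t` with
#' [select_signs()] and returns `c_hat + sum(pi_i * x_{t-i})`. The signs
#' may differ at every origin: the coefficients are per-time.
#'
#' @inheritParams select_signs
#' @return the one-step prediction (a number).
#' @export
caar_one_step <- function(x, t, p, W = p, force = FALSE) {
  x <- as.numeric(as_caar_series(x))
  sel <- select_signs(x, t, p, W = W, force = force)
  sel$intercept + sum(sel$signs * x[t - seq_len(p)])
}

#' Multi-step CA-AR forecast
#'
#' `mode = "rolling"` (the protocol of the evaluation experiments)
#' re-selects the signs at every step using only observed values up to the
#' step's origin, so each prediction is a true one-step-ahead forecast;
#' it requires observed values through `start + horizon - 1`.
#' `mode = "recursive"` conditions on the observations up to `start - 1`
#' only and feeds its own predictions back as history.
#'
#' @param x a [caar_series()] or numeric vector.
#' @param start 1-based index of the first forecast step.
#' @param horizon number of steps to forecast.
#' @param p CA-AR order.
#' @param W fit-window length; default `p`.
#' @param mode `"rolling"` or `"recursive"`.
#' @param force override the exponential-search guard of [select_signs()].
#' @return a [forecast_result()] (with actuals and RMSE whenever the
#'   series holds observed values at the forecast indices).
#' @examples
#' x <- gen_caar(c(1, -1), intercept = 0.2, length = 80, seed = 2)
#' caar_forecast(x, start = 61, horizon = 20, p = 2)$rmse
#' @export
caar_forecast <- function(x, start, horizon, p, W = p,
                          mode = c("rolling", "recursive"), force = FALSE) {
  xs <- as_caar_series(x)
  x <- as.numeric(xs)
  mode <- match.arg(mode)
  stopifnot(horizon >= 1, horizon == as.integer(horizon))
  last <- start + horizon - 1L
  if (mode == "rolling" && last > length(x)) {
    stop(sprintf(
      "rolling mode needs observed values through index %d but the series ends at %d; use mode = \"recursive\"",
      last, length(x)), call. = FALSE)
  }
  pred <- numeric(horizon)
  if (mode == "rolling") {
    for (j in seq_len(horizon)) {
      pred[j] <- caar_one_step(x, start + j - 1L, p, W = W, force = force)
    }
  } else {
    work <- x[seq_len(start - 1L)]
    for (j in seq_len(horizon)) {
      pred[j] <- caar_one_step(work, start + j - 1L, p, W = W, force = force)
      work <- c(work, pred[j])
    }
  }
  actual <- if (last <= length(x)) x[start:last] else NULL
  forecast_result(origin = start, predicted = pred, actual = actual,
                  model_descriptor = sprintf("caar(p=%d,W=%d,%s)", p, W, mode))
}

#' Multi-step standard-AR forecast (baseline)
#'
#' The standard-AR counterpart of [caar_forecast()]: at every rolling step
#' the AR(p) model is refit on the trailing `train_window` samples (default:
#' all history to date) by Yule-Walker — the textbook estimator for the
#' standard AR baseline — or conditional least squares, and predicts one
#' step ahead. Recursive mode fits once at the start and iterates on its
#' own predictions.
#'
#' If a refit fails or produces a non-finite prediction (possible on
#' numerically extreme nonstationary stretches), the affected steps are
#' `NaN` and the RMSE is reported as `NaN`.
#'
#' @inheritParams caar_forecast
#' @param method `"yw"` (Yule-Walker, default) or `"ls"`.
#' @param train_window number of trailing samples used per refit; `NULL`
#'   for all history.
#' @return a [forecast_result()].
#' @export
ar_forecast <- function(x, start, horizon, p, method = c("yw", "ls"),
                        train_window = NULL,
                        mode = c("rolling", "recursive")) {
  xs <- as_caar_series(x)
  x <- as.numeric(xs)
  method <- match.arg(method)
  mode <- match.arg(mode)
  stopifnot(horizon >= 1)
  last <- start + horizon - 1L
  if (mode == "rolling" && last > length(x)) {
    stop(sprintf(
      "rolling mode needs observed values through index %d but the series ends at %d",
      last, length(x)), call. = FALSE)
  }
  fit_fun <- if (method == "yw") fit_ar_yw else fit_ar_ls
  one <- function(history) {
    lo <- if (is.null(train_window)) 1L else max(1L, length(history) - train_window + 1L)
    m <- tryCatch(fit_fun(history[lo:length(history)], p),
                  error = function(e) NULL)
    if (is.null(m)) return(NaN)
    v <- ar_one_step(m, history)
    if (!is.finite(v)) NaN else v
  }
  pred <- numeric(horizon)
  if (mode == "rolling") {
    for (j in seq_len(horizon)) pred[j] <- one(x[seq_len(start + j - 2L)])
  } else {
    work <- x[seq_len(start - 1L)]
    for (j in seq_len(horizon)) {
      pred[j] <- one(work)
      work <- c(work, pred[j])
    }
  }
  actual <- if (last <= length(x)) x[start:last] else NULL
  forecast_result(origin = start, predicted = pred, actual = actual,
                  model_descriptor = sprintf("ar(p=%d,%s,%s)", p, method, mode))
}
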