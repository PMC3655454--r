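# Run code with a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Simulate a stationary AR(p) process
#'
#' Forward simulation of `x_t = intercept + sum(coeffs_i * x_{t-i}) + e_t`
#' with Gaussian innovations. The recursion is initialized at the process
#' mean and a burn-in stretch is discarded to wash out the transient.
#'
#' @param coeffs numeric vector of AR coefficients (may be empty for pure
#'   noise). Unless `check_stationarity = FALSE`, all roots of the
#'   characteristic polynomial must lie outside the unit circle.
#' @param intercept intercept term.
#' @param noise_sd innovation standard deviation (positive).
#' @param length number of samples returned.
#' @param seed integer seed; the output is a pure function of the arguments.
#' @param burn_in number of initial samples discarded (default 500).
#' @param check_stationarity set `FALSE` to allow unit-root/explosive
#'   coefficients (e.g. `coeffs = 1` reproduces a random walk).
#' @return a [caar_series()].
#' @examples
#' x <- gen_ar(0.5, noise_sd = 1, length = 1000, seed = 1)
#' @export
gen_ar <- function(coeffs, intercept = 0, noise_sd = 1, length, seed,
                   burn_in = 500, check_stationarity = TRUE) {
  coeffs <- as.numeric(coeffs)
  stopifnot(noise_sd > 0, length >= 1, burn_in >= 0)
  p <- base::length(coeffs)
  if (p > 0 && check_stationarity) {
    roots <- polyroot(c(1, -coeffs))
    m <- Mod(roots)
    if (any(m <= 1 + 1e-12)) {
      stop(sprintf(
        "nonstationary AR coefficients: characteristic root of modulus %.6g inside or on the unit circle",
        min(m)), call. = FALSE)
    }
  }
  ntot <- length + burn_in
  x <- with_seed(seed, {
    e <- stats::rnorm(ntot, 0, noise_sd)
    if (p == 0) {
      intercept + e
    } else {
      mu <- if (abs(1 - sum(coeffs)) > 1e-12) intercept / (1 - sum(coeffs)) else 0
      as.numeric(stats::filter(intercept + e, coeffs, method = "recursive",
                               init = rep(mu, p)))
    }
  })
  caar_series(x[(burn_in + 1):ntot], label = sprintf("ar%d", p))
}

#' Simulate a noisy sinusoid
#'
#' `x_t = amplitude * sin(2 * pi * t / period_samples) + e_t`, `t = 1..length`.
#'
#' @param period_samples period in samples; must be at least 2 (Nyquist).
#' @param amplitude sinusoid amplitude.
#' @param noise_sd Gaussian noise standard deviation (0 for a clean tone).
#' @param length number of samples.
#' @param seed integer seed (only used when `noise_sd > 0`).
#' @return a [caar_series()].
#' @export
gen_sine <- function(period_samples, amplitude = 1, noise_sd = 0, length,
                     seed = 0) {
  stopifnot(length >= 1, noise_sd >= 0)
  if (period_samples < 2) {
    stop("period_samples must be at least 2 samples (aliasing)", call. = FALSE)
  }
  t <- seq_len(length)
  x <- amplitude * sin(2 * pi * t / period_samples)
  if (noise_sd > 0) {
    x <- x + with_seed(seed, stats::rnorm(length, 0, noise_sd))
  }
  caar_series(x, label = sprintf("sine%g", period_samples))
}

#' Simulate a Gaussian random walk with drift
#'
#' `x_t = sum_{s<=t} (drift + e_s)` with `x_0 = 0`, the phi = 1 unit-root
#' special case of the AR(1) model.
#'
#' @param step_sd standard deviation of the Gaussian steps (positive).
#' @param drift per-step drift.
#' @param length number of samples.
#' @param seed integer seed.
#' @return a [caar_series()].
#' @export
gen_random_walk <- function(step_sd = 1, drift = 0, length, seed) {
  stopifnot(step_sd > 0, length >= 1)
  x <- with_seed(seed, cumsum(drift + stats::rnorm(length, 0, step_sd)))
  caar_series(x, label = "walk")
}

#' Sample a Weierstrass function
#'
#' `W(t) = sum_{k=0}^{n_terms} a^k cos(b^k pi t)` sampled uniformly on
#' `t in [0, 2]`. For `0 < a < 1 < b` with `a * b > 1` the graph of `W` is a
#' fractal with box-counting dimension `2 + log(a) / log(b)` — a
#' deterministic calibration fixture with a closed-form dimension.
#'
#' @param a amplitude decay factor, in (0, 1).
#' @param b frequency growth factor, greater than 1; `a * b` must exceed 1.
#' @param n_terms number of series terms; defaults to the smallest count
#'   with `a^n_terms < 1e-6`.
#' @param length number of samples.
#' @return a [caar_series()].
#' @examples
#' w <- gen_weierstrass(0.7, 3, length = 1024)
#' 2 + log(0.7) / log(3)  # theoretical graph dimension
#' @export
gen_weierstrass <- function(a, b, n_terms = NULL, length) {
  stopifnot(a > 0, a < 1, b > 1, length >= 2)
  if (a * b <= 1) {
    stop(sprintf("a * b = %.6g <= 1: the graph is rectifiable, not fractal",
                 a * b), call. = FALSE)
  }
  if (is.null(n_terms)) n_terms <- ceiling(log(1e-6) / log(a))
  t <- seq(0, 2, length.out = length)
  w <- numeric(length)
  for (k in 0:n_terms) w <- w + a^k * cos(b^k * pi * t)
  caar_series(w, label = sprintf("weierstrass_a%g_b%g", a, b))
}

#' Configuration for the random-coefficient process simulator
#'
#' Holds the parameters of the two-point coefficient law: each coefficient
#' equals `+theta` with probability `alpha` and `-theta` with probability
#' `1 - alpha`, so `E(phi) = theta * (2 * alpha - 1)` and
#' `Var(phi) = 4 * alpha * (1 - alpha) * theta^2`.
#'
#' @param theta coefficient magnitude, non-negative (`theta = 1` gives the
#'   pure +1/-1 coefficient process).
#' @param alpha probability of the positive sign, strictly inside (0, 1).
#' @param order_p autoregressive order (positive integer).
#' @param noise_sd innovation standard deviation (positive).
#' @param length number of samples.
#' @param seed integer seed; fully determines the realization.
#' @return an object of class `rc_sim_config`.
#' @export
rc_sim_config <- function(theta, alpha, order_p, noise_sd, length, seed) {
  stopifnot(is.numeric(theta), theta >= 0, is.finite(theta),
            is.numeric(alpha), alpha > 0, alpha < 1,
            order_p >= 1, order_p == as.integer(order_p),
            noise_sd > 0, length >= 1)
  structure(list(theta = theta, alpha = alpha, order_p = as.integer(order_p),
                 noise_sd = noise_sd, length = as.integer(length),
                 seed = as.integer(seed)),
            class = "rc_sim_config")
}

#' Simulate the random-coefficient +/-theta autoregression
#'
#' Simulates `x_t = sum_i phi_{t,i} x_{t-i} + e_t` where each coefficient
#' `phi_{t,i} = +theta` with probability `alpha` and `-theta` otherwise.
#' With `theta = 1` the solutions of this recursion are exactly the
#' sign-flipped accumulated-noise processes that generalize the random
#' walk (all signs +1) and the alternating-sign unit-root case.
#'
#' `sign_mode = "fixed"` draws one sign vector per realization and holds it
#' over time (the model class the CA-AR forecaster spans);
#' `sign_mode = "per_step"` redraws the signs independently at every time
#' step (the literal i.i.d.-in-t coefficient sequence). With
#' `first_sign_positive = TRUE` the lag-1 sign is pinned to +1, matching
#' the CA-AR convention that the first coefficient is +1.
#'
#' The realized signs are retrievable from the result as
#' `attr(x, "signs")` (a vector for `"fixed"`, a `length x p` matrix for
#' `"per_step"`).
#'
#' @param cfg an [rc_sim_config()].
#' @param sign_mode `"fixed"` or `"per_step"`; see Details.
#' @param first_sign_positive pin the lag-1 sign at +1 (default `FALSE`).
#' @return a [caar_series()] with a `"signs"` attribute.
#' @examples
#' cfg <- rc_sim_config(theta = 1, alpha = 0.5, order_p = 3,
#'                      noise_sd = 0.1, length = 200, seed = 1)
#' x <- simulate_rc_process(cfg, first_sign_positive = TRUE)
#' attr(x, "signs")
#' @export
simulate_rc_process <- function(cfg, sign_mode = c("fixed", "per_step"),
                                first_sign_positive = FALSE) {
  stopifnot(inherits(cfg, "rc_sim_config"))
  sign_mode <- match.arg(sign_mode)
  p <- cfg$order_p
  n <- cfg$length
  out <- with_seed(cfg$seed, {
    e <- stats::rnorm(n, 0, cfg$noise_sd)
    draw <- function(k) ifelse(stats::runif(k) < cfg$alpha, 1, -1)
    if (sign_mode == "fixed") {
      s <- draw(p)
      if (first_sign_positive) s[1L] <- 1
      signs <- s
    } else {
      signs <- matrix(draw(n * p), nrow = n, ncol = p)
      if (first_sign_positive) signs[, 1L] <- 1
    }
    x <- numeric(n)
    for (t in seq_len(n)) {
      s <- if (sign_mode == "fixed") signs else signs[t, ]
      acc <- 0
      for (i in seq_len(min(p, t - 1L))) acc <- acc + cfg$theta * s[i] * x[t - i]
      x[t] <- acc + e[t]
    }
    list(x = x, signs = signs)
  })
  res <- caar_series(out$x, label = sprintf("rc_theta%g", cfg$theta))
  attr(res, "signs") <- out$signs
  res
}

#' Generate a noiseless-or-noisy CA-AR path with known signs
#'
#' Simulates `x_t = intercept + sum_i signs_i * x_{t-i} + e_t` from given
#' +/-1 signs — the data-generating form of the CA-AR model itself. Used
#' as an identifiability fixture: with `noise_sd = 0` the sign search must
#' recover `signs` and `intercept` exactly.
#'
#' @param signs vector of +1/-1 with first entry +1.
#' @param intercept intercept `c`.
#' @param noise_sd innovation sd; 0 for a noiseless path.
#' @param length number of samples.
#' @param seed integer seed for the innovations and the random start values.
#' @param init optional numeric vector of `length(signs)` start values;
#'   defaults to standard-normal draws.
#' @return a [caar_series()].
#' @export
gen_caar <- function(signs, intercept = 0, noise_sd = 0, length, seed = 0,
                     init = NULL) {
  signs <- as.numeric(signs)
  p <- base::length(signs)
  stopifnot(p >= 1, all(abs(signs) == 1), length > p, noise_sd >= 0)
  if (signs[1L] != 1) stop("the first sign must be +1", call. = FALSE)
  x <- with_seed(seed, {
    x <- numeric(length)
    x[seq_len(p)] <- if (is.null(init)) stats::rnorm(p) else {
      stopifnot(base::length(init) == p)
      as.numeric(init)
    }
    e <- if (noise_sd > 0) stats::rnorm(length, 0, noise_sd) else numeric(length)
    for (t in (p + 1):length) {
      x[t] <- intercept + sum(signs * x[t - seq_len(p)]) + e[t]
    }
    x
  })
  caar_series(x, label = "caar_path")
}
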