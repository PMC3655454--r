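#' Real cepstrum with periodicity peak detection
#'
#' Computes the real cepstrum — the inverse DFT of the log magnitude
#' spectrum of the mean-removed signal — and searches a quefrency band for
#' peaks. A periodic component of period `q` samples shows up as a peak at
#' quefrency `q` (and at its multiples, the rahmonics); the reported
#' fundamental is therefore the smallest quefrency attaining the band
#' maximum (to a relative tolerance of 1e-6, so exactly repeated rahmonic
#' peaks resolve to the fundamental).
#'
#' The signal may optionally be Hann-tapered before the DFT; the default is
#' no taper. Spectral magnitudes below `1e-12` times the maximum are
#' floored before taking logs so that exactly periodic signals (whose
#' spectra are zero off the harmonics) do not produce `-Inf`.
#'
#' A peak is called significant when its cepstral value exceeds
#' `median + 5 * mad` of the cepstrum inside the band — a robust,
#' scale-free rule; the `periodic` verdict is `TRUE` iff at least one peak
#' is significant.
#'
#' @param x a [caar_series()] or numeric vector, length at least 8.
#' @param band integer vector of length 2: quefrency search band in
#'   samples; default `c(2, floor(n/2))`.
#' @param taper apply a Hann window before the DFT (default `FALSE`).
#' @return an object of class `caar_cepstrum`: a list with `quefrency`
#'   (0-based sample lags), `cepstrum`, `band`, `peaks` (data frame of
#'   significant local maxima with columns `quefrency`, `value`,
#'   `prominence`, ordered by decreasing prominence), `fundamental`,
#'   `threshold_used` and `periodic`.
#' @examples
#' x <- rep(0, 1000); x[seq(1, 1000, by = 50)] <- 1
#' real_cepstrum(x)$fundamental  # 50
#' @export
real_cepstrum <- function(x, band = NULL, taper = FALSE) {
  x <- as.numeric(as_caar_series(x))
  n <- length(x)
  if (n < 8) stop("cepstrum needs at least 8 samples", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("degenerate input: constant signal has an undefined log spectrum",
         call. = FALSE)
  }
  x <- x - mean(x)
  if (taper) x <- x * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  S <- Mod(stats::fft(x))
  S[S < 1e-12 * max(S)] <- 1e-12 * max(S)
  cep <- Re(stats::fft(log(S), inverse = TRUE)) / n
  if (is.null(band)) band <- c(2L, floor(n / 2))
  stopifnot(length(band) == 2L, band[1] >= 1, band[2] > band[1],
            band[2] <= n - 1)
  q <- band[1]:band[2]
  cb <- cep[q + 1L]  # quefrency k lives at index k + 1
  thr <- stats::median(cb) + 5 * stats::mad(cb)

  # local maxima inside the band (flat-topped peaks keep their left sample)
  m <- length(cb)
  loc <- which(cb[2:(m - 1)] > cb[1:(m - 2)] & cb[2:(m - 1)] >= cb[3:m]) + 1L
  sig <- loc[cb[loc] > thr]
  prominence <- function(i) {
    left <- if (i > 1) min(cb[1:(i - 1)]) else cb[i]
    right <- if (i < m) min(cb[(i + 1):m]) else cb[i]
    cb[i] - max(left, right)
  }
  peaks <- data.frame(quefrency = q[sig], value = cb[sig],
                      prominence = vapply(sig, prominence, numeric(1)))
  peaks <- peaks[order(-peaks$prominence), , drop = FALSE]
  rownames(peaks) <- NULL

  top <- max(cb)
  fundamental <- q[which(cb >= top - 1e-6 * abs(top))[1L]]
  structure(list(quefrency = 0:(n - 1), cepstrum = cep, band = band,
                 peaks = peaks, fundamental = fundamental,
                 threshold_used = thr, periodic = nrow(peaks) > 0),
            class = "caar_cepstrum")
}

#' @export
print.caar_cepstrum <- function(x, ...) {
  cat(sprintf("<caar_cepstrum> band %d..%d, periodic: %s\n",
              x$band[1], x$band[2], x$periodic))
  cat(sprintf(" fundamental quefrency: %d; threshold %.4g; %d significant peak(s)\n",
              x$fundamental, x$threshold_used, nrow(x$peaks)))
  invisible(x)
}

#' Lag-plot pairs and lag autocorrelation
#'
#' Builds the scatter pairs `(x_{t-L}, x_t)` of a lag plot and the sample
#' autocorrelation at lag `L` (mean-centred, biased normalization by `n`).
#' Structure in the lag plot — e.g. the linear pattern of normal EEG at
#' `L = 1` — indicates nonrandomness and hence predictability.
#'
#' @param x a [caar_series()] or numeric vector.
#' @param L positive integer lag, smaller than `length(x)`.
#' @return an object of class `caar_lag_plot`: list with `lag`, `pairs`
#'   (data frame with columns `x_lagged`, `x`, in time order) and
#'   `lag_autocorr`.
#' @export
lag_pairs <- function(x, L) {
  x <- as.numeric(as_caar_series(x))
  n <- length(x)
  stopifnot(L >= 1, L == as.integer(L))
  if (L >= n) {
    stop(sprintf("lag L = %d must be smaller than the series length %d", L, n),
         call. = FALSE)
  }
  idx <- (L + 1):n
  r <- as.numeric(stats::acf(x, lag.max = L, plot = FALSE,
                             demean = TRUE)$acf[L + 1L])
  structure(list(lag = as.integer(L),
                 pairs = data.frame(x_lagged = x[idx - L], x = x[idx]),
                 lag_autocorr = r),
            class = "caar_lag_plot")
}

#' @export
print.caar_lag_plot <- function(x, ...) {
  cat(sprintf("<caar_lag_plot> lag %d, %d pairs, autocorrelation %.4f\n",
              x$lag, nrow(x$pairs), x$lag_autocorr))
  invisible(x)
}

#' Autocorrelation-based randomness verdict
#'
#' Declares a series "random" when the sample autocorrelation magnitude at
#' every requested lag stays below a threshold, by default the standard
#' white-noise band `2 / sqrt(n)`. This formalizes the by-eye reading of a
#' lag plot as an explicit test.
#'
#' @param x a [caar_series()] or numeric vector.
#' @param lags positive integer lags to inspect (all smaller than the
#'   series length).
#' @param threshold autocorrelation magnitude threshold; default
#'   `2 / sqrt(length(x))`.
#' @return `TRUE` ("random") or `FALSE` ("nonrandom").
#' @export
randomness_verdict <- function(x, lags = c(1L, 20L), threshold = NULL) {
  x <- as.numeric(as_caar_series(x))
  if (length(lags) == 0) stop("need at least one lag", call. = FALSE)
  if (is.null(threshold)) threshold <- 2 / sqrt(length(x))
  r <- vapply(lags, function(L) lag_pairs(x, L)$lag_autocorr, numeric(1))
  all(abs(r) < threshold)
}
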