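#' Grid ladders for box counting
#'
#' A grid ladder is the ordered set of box side lengths used for a
#' box-counting scan. The default ladder runs from 0.1 to 10000 in
#' multiplications of 2: sizes `0.1 * 2^k` for `k = 0..16` (the largest,
#' 6553.6, is the last not exceeding 10000). Sizes are absolute, in the
#' same units as the counted object (sample-index units horizontally, raw
#' amplitude units vertically for a signal graph).
#'
#' @param sizes vector of positive box sizes; at least 5 are needed for a
#'   slope fit.
#' @return an object of class `caar_grid_ladder` (numeric vector of sizes,
#'   sorted ascending).
#' @export
grid_ladder <- function(sizes) {
  sizes <- sort(as.numeric(sizes))
  if (length(sizes) < 5) {
    stop("a grid ladder needs at least 5 sizes for a slope fit", call. = FALSE)
  }
  if (any(sizes <= 0) || anyDuplicated(sizes)) {
    stop("grid sizes must be positive and distinct", call. = FALSE)
  }
  structure(sizes, class = "caar_grid_ladder")
}

#' @rdname grid_ladder
#' @export
default_grid_ladder <- function() {
  grid_ladder(0.1 * 2^(0:16))
}

exclusive_floor <- function(x) {
  f <- floor(x)
  f - (x == f)
}

# Count grid cells of unit side touched by the polyline with vertices
# (u, v), u strictly increasing; cells are half-open [k, k+1) x [r, r+1),
# clamped to the bounding box. Works in grid units: callers divide their
# coordinates by the box size first.
count_cells_polyline <- function(u, v) {
  n <- length(u)
  if (n == 1L) return(1L)
  rmax <- floor(max(v))
  cmax <- floor(max(u))
  ua <- u[-n]; ub <- u[-1]
  va <- v[-n]; vb <- v[-1]
  c1 <- floor(ua)
  cr <- exclusive_floor(ub)
  nc <- pmax(cr - c1 + 1, 1)
  cols <- rep(c1, nc) + sequence(nc) - 1
  id <- rep(seq_len(n - 1L), nc)
  pa <- pmax(ua[id], cols)
  pb <- pmin(ub[id], cols + 1)
  du <- (ub - ua)[id]
  dv <- (vb - va)[id]
  vA <- va[id] + dv * (pa - ua[id]) / du    # attained at the closed left end
  vB <- va[id] + dv * (pb - ua[id]) / du    # approached at the open right end
  inc <- dv >= 0
  r1 <- ifelse(inc, floor(vA), floor(vB))
  r2 <- ifelse(inc, exclusive_floor(vB), floor(vA))
  r1 <- pmin(pmax(r1, 0), rmax)
  r2 <- pmax(pmin(pmax(r2, 0), rmax), r1)
  cols <- pmin(pmax(cols, 0), cmax)
  nr <- r2 - r1 + 1
  keys <- rep(cols, nr) * (rmax + 2) + rep(r1, nr) + sequence(nr) - 1
  keys <- c(keys, floor(u[n]) * (rmax + 2) + floor(v[n]))  # final point
  length(unique(keys))
}

# Count unit cells occupied by a point cloud given as a matrix (rows =
# points), already in grid units and anchored at the per-axis minima.
count_cells_points <- function(m) {
  g <- floor(m)
  keys <- do.call(paste, c(lapply(seq_len(ncol(g)), function(j) g[, j]),
                           sep = ","))
  length(unique(keys))
}

#' Box-count the planar graph of a signal
#'
#' Treats the signal as the polyline `{(t, x_t)}` — `t` in raw 1-based
#' sample-index units, amplitude in raw signal units, linearly interpolated
#' between samples — and, for every ladder size `eps`, counts the distinct
#' grid cells of side `eps` that the polyline touches. The grid is anchored
#' at the curve's bounding-box minimum corner and cells are half-open, so
#' each point belongs to exactly one cell. The fractal dimension is the
#' fitted slope of `log N_eps` against `log(1 / eps)` (see
#' [fit_dimension()]).
#'
#' For a planar curve the slope should land in `[1, 2]`; a fitted slope
#' outside that range raises a warning (not an error).
#'
#' @param x a [caar_series()] or numeric vector of length at least 2.
#' @param ladder a [grid_ladder()]; default [default_grid_ladder()].
#' @param range_policy fitting range policy passed to [fit_dimension()].
#' @param normalize rescale the curve into a 4096 x 4096 box before
#'   counting, for unit-free use of the absolute default ladder.
#' @return an object of class `caar_box_count`: list with `sizes`,
#'   `counts`, `log_inv_eps`, `log_counts`, `slope`, `intercept`,
#'   `linear_range` (index pair into `sizes`), `r_squared` and `kind`.
#' @examples
#' bc <- box_count_curve(gen_weierstrass(0.7, 3, length = 512), normalize = TRUE)
#' bc$slope
#' @export
box_count_curve <- function(x, ladder = default_grid_ladder(),
                            range_policy = "auto", normalize = FALSE) {
  x <- as.numeric(as_caar_series(x))
  n <- length(x)
  if (n < 2) stop("box counting a curve needs at least 2 samples", call. = FALSE)
  ladder <- if (inherits(ladder, "caar_grid_ladder")) ladder else grid_ladder(ladder)
  t <- as.numeric(seq_len(n))
  y <- x
  if (normalize) {
    t <- (t - 1) / (n - 1) * 4096
    ry <- range(y)
    y <- if (diff(ry) > 0) (y - ry[1]) / diff(ry) * 4096 else y * 0
  }
  y0 <- min(y)
  t0 <- t[1]
  counts <- vapply(as.numeric(ladder), function(eps) {
    count_cells_polyline((t - t0) / eps, (y - y0) / eps)
  }, numeric(1))
  finish_box_count(ladder, counts, range_policy, kind = "curve")
}

#' Box-count a delay-coordinate point cloud
#'
#' Counts, for every ladder size, the distinct hypercubes of that side
#' containing at least one delay vector (pure point occupancy — no
#' interpolation between consecutive vectors). The grid is anchored at the
#' per-axis minima. Phase-space slopes may legitimately exceed 2.
#'
#' @param ps a [embed_delay()] phase space.
#' @param ladder a [grid_ladder()].
#' @param range_policy fitting range policy passed to [fit_dimension()].
#' @return a `caar_box_count` object, as [box_count_curve()].
#' @export
box_count_points <- function(ps, ladder = default_grid_ladder(),
                             range_policy = "auto") {
  stopifnot(inherits(ps, "caar_phase_space"))
  ladder <- if (inherits(ladder, "caar_grid_ladder")) ladder else grid_ladder(ladder)
  m <- ps$vectors
  if (nrow(m) < 2) stop("box counting needs at least 2 vectors", call. = FALSE)
  mins <- apply(m, 2, min)
  centred <- sweep(m, 2, mins)
  counts <- vapply(as.numeric(ladder), function(eps) {
    count_cells_points(centred / eps)
  }, numeric(1))
  finish_box_count(ladder, counts, range_policy, kind = "points")
}

finish_box_count <- function(ladder, counts, range_policy, kind) {
  sizes <- as.numeric(ladder)
  if (any(diff(counts) > 0)) {
    warning("box counts are not monotone non-increasing in the grid size",
            call. = FALSE)
  }
  fit <- fit_dimension(sizes, counts, range_policy)
  if (kind == "curve" && (fit$slope < 1 - 0.02 || fit$slope > 2 + 0.02)) {
    warning(sprintf(
      "fitted curve dimension %.3f lies outside the planar range [1, 2]",
      fit$slope), call. = FALSE)
  }
  structure(list(sizes = sizes, counts = counts,
                 log_inv_eps = log(1 / sizes), log_counts = log(counts),
                 slope = fit$slope, intercept = fit$intercept,
                 linear_range = fit$linear_range, r_squared = fit$r_squared,
                 kind = kind),
            class = "caar_box_count")
}

#' @export
print.caar_box_count <- function(x, ...) {
  cat(sprintf(
    "<caar_box_count> (%s) %d sizes in [%g, %g]\n  dimension %.4f (R^2 %.5f, fitted on sizes %d..%d)\n",
    x$kind, length(x$sizes), min(x$sizes), max(x$sizes),
    x$slope, x$r_squared, x$linear_range[1], x$linear_range[2]))
  invisible(x)
}

#' Fit a fractal dimension from box counts
#'
#' Ordinary least squares of `log N_eps` on `log(1 / eps)`; the slope is
#' the estimated dimension. Under the `"auto"` policy the fitted sub-range
#' is the contiguous window of at least 5 points maximizing R-squared,
#' which excludes the flat saturation plateaus at very small and very
#' large grid sizes; ties prefer the longer window, then the window of
#' smaller sizes. `"full"` fits every point; `c(i, j)` fits the points
#' `i..j` of the size-sorted ladder.
#'
#' @param sizes vector of box sizes (at least 5).
#' @param counts matching vector of positive box counts.
#' @param range_policy `"auto"`, `"full"`, or an integer pair `c(i, j)`.
#' @return list with `slope`, `intercept`, `linear_range` (integer pair of
#'   indices into the size-sorted input) and `r_squared`.
#' @examples
#' sizes <- 2^(0:9)
#' counts <- round(exp(3) / sizes)  # slope 1 line
#' fit_dimension(sizes, counts)$slope
#' @export
fit_dimension <- function(sizes, counts, range_policy = "auto") {
  stopifnot(length(sizes) == length(counts))
  ord <- order(sizes)
  sizes <- as.numeric(sizes)[ord]
  counts <- as.numeric(counts)[ord]
  n <- length(sizes)
  if (n < 5) stop("dimension fit needs at least 5 (size, count) points",
                  call. = FALSE)
  if (any(counts < 1)) stop("box counts must all be at least 1", call. = FALSE)
  lx <- log(1 / sizes)
  ly <- log(counts)

  ols <- function(i, j) {
    xs <- lx[i:j]; ys <- ly[i:j]
    mx <- mean(xs); my <- mean(ys)
    sxx <- sum((xs - mx)^2)
    syy <- sum((ys - my)^2)
    sxy <- sum((xs - mx) * (ys - my))
    slope <- sxy / sxx
    r2 <- if (syy == 0) 0 else (sxy * sxy) / (sxx * syy)
    list(slope = slope, intercept = my - slope * mx, r_squared = r2,
         linear_range = c(i, j))
  }

  if (identical(range_policy, "full")) return(ols(1L, n))
  if (is.numeric(range_policy)) {
    stopifnot(length(range_policy) == 2L)
    i <- as.integer(range_policy[1]); j <- as.integer(range_policy[2])
    if (i < 1 || j > n || j - i + 1 < 2) {
      stop("explicit range must select at least 2 points inside the ladder",
           call. = FALSE)
    }
    return(ols(i, j))
  }
  if (!identical(range_policy, "auto")) {
    stop("range_policy must be \"auto\", \"full\" or an index pair",
         call. = FALSE)
  }
  best <- NULL
  for (i in 1:(n - 4L)) {
    for (j in (i + 4L):n) {
      f <- ols(i, j)
      len <- j - i + 1L
      if (is.null(best) ||
          f$r_squared > best$r_squared + 1e-12 ||
          (abs(f$r_squared - best$r_squared) <= 1e-12 &&
           (len > best$len ||
            (len == best$len && i < best$linear_range[1])))) {
        best <- c(f, list(len = len))
      }
    }
  }
  best$len <- NULL
  best
}

#' Delay-coordinate embedding
#'
#' Forms the delay vectors `V_t = [x_t, x_{t-tau}, ..., x_{t-L*tau}]` for
#' every valid `t`, in time order. The phase space is the
#' `(L + 1)`-dimensional space of these vectors; its box-counting
#' dimension estimates the effective dimensionality of the signal's
#' dynamics and is used to pick the CA-AR order.
#'
#' @param x a [caar_series()] or numeric vector.
#' @param tau positive integer time delay, in samples.
#' @param L non-negative integer lag count; embedding dimension is `L + 1`.
#' @return an object of class `caar_phase_space`: list with `vectors` (an
#'   `(n - L*tau) x (L+1)` matrix, column 1 holding `x_t`) and `config`
#'   (list of `tau`, `L`).
#' @examples
#' embed_delay(1:4, tau = 1, L = 1)$vectors
#' @export
embed_delay <- function(x, tau = 1L, L = 20L) {
  x <- as.numeric(as_caar_series(x))
  n <- length(x)
  stopifnot(tau >= 1, tau == as.integer(tau), L >= 0, L == as.integer(L))
  if (L * tau >= n) {
    stop(sprintf("embedding needs L * tau < series length (%d * %d >= %d)",
                 L, tau, n), call. = FALSE)
  }
  ts <- (L * tau + 1L):n
  vec <- vapply(0:L, function(k) x[ts - k * tau], numeric(length(ts)))
  if (length(ts) == 1L) vec <- matrix(vec, nrow = 1L)
  structure(list(vectors = vec,
                 config = list(tau = as.integer(tau), L = as.integer(L))),
            class = "caar_phase_space")
}

#' @export
print.caar_phase_space <- function(x, ...) {
  cat(sprintf("<caar_phase_space> %d vectors in %d dimensions (tau %d, L %d)\n",
              nrow(x$vectors), ncol(x$vectors), x$config$tau, x$config$L))
  invisible(x)
}

#' Model order from phase-space slopes
#'
#' `order_from_slopes()` rounds the average slope up to the next integer
#' (the ceiling; an exact integer average stays put) with a floor of 1.
#' `select_order()` computes the phase-space box-count slope of every
#' supplied signal and applies that rule: the designated collection should
#' be the normal (baseline) signals, since the order must capture the
#' normal dynamics that abnormal behaviour departs from.
#'
#' @param signals a single series or a list of them.
#' @param tau,L embedding parameters (defaults `tau = 1`, `L = 20`).
#' @param ladder a [grid_ladder()].
#' @param range_policy passed to [fit_dimension()].
#' @return `select_order()`: a list with `order` (positive integer),
#'   `slopes` (per-signal) and `mean_slope`. `order_from_slopes()`: the
#'   integer order.
#' @examples
#' order_from_slopes(c(4.2, 4.6))  # 5
#' @export
select_order <- function(signals, tau = 1L, L = 20L,
                         ladder = default_grid_ladder(),
                         range_policy = "auto") {
  if (!is.list(signals)) signals <- list(signals)
  if (length(signals) == 0) {
    stop("need at least one signal to select an order", call. = FALSE)
  }
  slopes <- vapply(signals, function(s) {
    box_count_points(embed_delay(s, tau = tau, L = L), ladder = ladder,
                     range_policy = range_policy)$slope
  }, numeric(1))
  list(order = order_from_slopes(slopes), slopes = slopes,
       mean_slope = mean(slopes))
}

#' @rdname select_order
#' @param slopes numeric vector of per-signal slopes.
#' @export
order_from_slopes <- function(slopes) {
  stopifnot(length(slopes) >= 1, all(is.finite(slopes)))
  max(1L, as.integer(ceiling(mean(slopes))))
}
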