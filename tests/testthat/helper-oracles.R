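# Independent brute-force oracles used to validate the fast implementations.

# Exhaustive sign search: plain nested loops over every +/-1 vector with the
# first entry fixed at +1, scoring each candidate on the W most recent
# one-step pairs before origin t. Returns the RSS-minimal candidate with
# ties to the lexicographically smaller vector (+1 before -1).
brute_select_signs <- function(x, t, p, W) {
  x <- as.numeric(x)
  cands <- list(1)
  for (i in seq_len(p - 1)) {
    cands <- unlist(lapply(cands, function(v) list(c(v, 1), c(v, -1))),
                    recursive = FALSE)
  }
  best <- NULL
  for (signs in cands) {
    res <- numeric(W)
    for (w in seq_len(W)) {
      s <- t - W + w - 1L
      acc <- 0
      for (i in seq_len(p)) acc <- acc + signs[i] * x[s - i]
      res[w] <- x[s] - acc
    }
    chat <- mean(res)
    rss <- sum((res - chat)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(signs = signs, intercept = chat, rss = rss)
    }
  }
  best
}

# Dense-sampling box-count oracle for the polyline (u, v) in grid units:
# samples each segment finely (plus the column boundaries and points just
# left of them, where the per-column extremes of a linear piece live) and
# collects the cells of the sampled points. Exact for polylines because a
# linear piece attains every intermediate level.
oracle_polyline_cells <- function(u, v) {
  n <- length(u)
  rmax <- floor(max(v)); cmax <- floor(max(u))
  keys <- c()
  for (k in seq_len(n - 1)) {
    du <- u[k + 1] - u[k]; dv <- v[k + 1] - v[k]
    m <- 64 + ceiling(16 * (abs(du) + abs(dv)))
    uu <- u[k] + du * (0:(m - 1)) / m
    ints <- ceiling(u[k]):floor(u[k + 1])
    ints <- ints[ints >= u[k] & ints <= u[k + 1]]
    d <- 1e-9
    uu <- c(uu, ints, ints - d, u[k + 1] - d)
    uu <- uu[uu >= u[k] & uu < u[k + 1]]
    vv <- v[k] + dv * (uu - u[k]) / du
    cc <- pmin(pmax(floor(uu), 0), cmax)
    rr <- pmin(pmax(floor(vv), 0), rmax)
    keys <- c(keys, cc * (rmax + 2) + rr)
  }
  keys <- c(keys, floor(u[n]) * (rmax + 2) + floor(v[n]))
  length(unique(keys))
}

# Curve box count by the oracle, mirroring box_count_curve's anchoring.
oracle_curve_count <- function(x, eps) {
  x <- as.numeric(x)
  t <- as.numeric(seq_along(x))
  oracle_polyline_cells((t - t[1]) / eps, (x - min(x)) / eps)
}

# Exhaustive 2-D occupancy: scan every cell of the bounding box and test
# point membership directly.
brute_occupancy_2d <- function(pts, eps) {
  lo <- apply(pts, 2, min)
  n1 <- floor((max(pts[, 1]) - lo[1]) / eps)
  n2 <- floor((max(pts[, 2]) - lo[2]) / eps)
  count <- 0L
  for (i in 0:n1) {
    for (j in 0:n2) {
      hit <- any(pts[, 1] >= lo[1] + i * eps & pts[, 1] < lo[1] + (i + 1) * eps &
                 pts[, 2] >= lo[2] + j * eps & pts[, 2] < lo[2] + (j + 1) * eps)
      # points exactly on the upper bounding edge belong to the edge cell
      if (!hit && (i == n1 || j == n2)) {
        hit <- any(floor((pts[, 1] - lo[1]) / eps) == i &
                   floor((pts[, 2] - lo[2]) / eps) == j)
      }
      if (hit) count <- count + 1L
    }
  }
  count
}

# Nearest-neighbour forecast by a plain double-loop scan.
brute_nn_forecast <- function(x, start, horizon, m, train_end = start - 1) {
  x <- as.numeric(x)
  pred <- numeric(horizon)
  for (j in seq_len(horizon)) {
    o <- start + j - 1
    span_end <- train_end + j - 1
    query <- x[(o - m):(o - 1)]
    bestd <- Inf; best <- NA
    for (e in m:(span_end - 1)) {
      d <- sum((x[(e - m + 1):e] - query)^2)
      if (d < bestd) { bestd <- d; best <- e }
    }
    pred[j] <- x[best + 1]
  }
  pred
}

# All-windows search for the R^2-maximal contiguous fit, via lm().
brute_best_window <- function(sizes, counts, minpts = 5) {
  lx <- log(1 / sizes); ly <- log(counts)
  n <- length(sizes)
  best <- NULL
  for (i in 1:(n - minpts + 1)) {
    for (j in (i + minpts - 1):n) {
      f <- stats::lm(y ~ x, data = data.frame(x = lx[i:j], y = ly[i:j]))
      r2 <- if (stats::var(ly[i:j]) == 0) 0 else summary(f)$r.squared
      len <- j - i + 1
      if (is.null(best) || r2 > best$r2 + 1e-12 ||
          (abs(r2 - best$r2) <= 1e-12 &&
           (len > best$len || (len == best$len && i < best$i)))) {
        best <- list(r2 = r2, slope = unname(stats::coef(f)[2]),
                     i = i, j = j, len = len)
      }
    }
  }
  best
}
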