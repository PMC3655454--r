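test_that("the default grid ladder follows the 0.1..10000 doubling rule", {
  lad <- default_grid_ladder()
  expect_length(lad, 17)
  expect_equal(lad[1], 0.1)
  expect_equal(lad[17], 6553.6)
  expect_true(all(as.numeric(lad) <= 10000))
  expect_equal(as.numeric(lad)[-1] / as.numeric(lad)[-17], rep(2, 16))
  expect_error(grid_ladder(c(1, 2, 4)), "at least 5")
  expect_error(grid_ladder(c(0, 1, 2, 4, 8)), "positive")
})

test_that("fit_dimension recovers exact and plateaued log-log lines", {
  sizes <- 2^(0:9)
  counts <- exp(1 * log(1 / sizes) + 8)
  f <- fit_dimension(sizes, counts)
  expect_equal(f$slope, 1, tolerance = 1e-12)
  expect_equal(f$intercept, 8, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  # plateau at the 4 largest sizes plus a clean slope-1.5 region
  sizes2 <- 2^(0:11)
  counts2 <- pmax(round(exp(1.5 * log(1 / sizes2) + 14)), 1)
  counts2[9:12] <- counts2[9]
  f2 <- fit_dimension(sizes2, counts2)
  expect_lte(f2$linear_range[2], 9)
  expect_equal(f2$slope, 1.5, tolerance = 0.02)

  # auto window agrees with an exhaustive all-windows search
  set.seed(31)
  for (k in 1:5) {
    cnt <- sort(round(exp(stats::runif(10, 0, 8))), decreasing = TRUE)
    cnt <- pmax(cnt, 1)
    sz <- 2^(0:9)
    f3 <- fit_dimension(sz, cnt)
    ref <- brute_best_window(sz, cnt)
    expect_equal(f3$linear_range, c(ref$i, ref$j))
    expect_equal(f3$slope, ref$slope, tolerance = 1e-9)
  }

  # explicit range restricts the fit to those points
  f4 <- fit_dimension(sizes2, counts2, range_policy = c(2, 6))
  ref4 <- stats::lm(y ~ x, data = data.frame(x = log(1 / sizes2[2:6]),
                                             y = log(counts2[2:6])))
  expect_equal(f4$slope, unname(stats::coef(ref4)[2]), tolerance = 1e-9)
  expect_equal(f4$linear_range, c(2L, 6L))

  expect_error(fit_dimension(1:4, 1:4), "at least 5")
  expect_error(fit_dimension(2^(0:5), c(4, 2, 1, 0, 0, 0)), "at least 1")
})

test_that("curve counts match a simple covering argument on flat segments", {
  # horizontal segment spanning T index units needs about ceil(T / eps) cells
  x <- rep(5, 101)  # spans 100 index units
  for (eps in c(3.2, 6.4, 12.8)) {
    bc <- suppressWarnings(
      box_count_curve(x, grid_ladder(c(eps, 2 * eps, 4 * eps, 8 * eps,
                                       16 * eps)),
                      range_policy = "full"))
    expect_lte(abs(bc$counts[1] - ceiling(100 / eps)), 1)
  }
})

test_that("smooth curves have dimension about 1", {
  line <- caar_series(seq(1, 4096, length.out = 4096))
  expect_lt(abs(box_count_curve(line)$slope - 1), 0.1)
  sine <- caar_series(2048 + 2000 * sin(2 * pi * (1:4096) / 500))
  s <- box_count_curve(sine)$slope
  expect_gt(s, 0.9)
  expect_lt(s, 1.2)
})

test_that("the Weierstrass fixture recovers its closed-form dimension", {
  w <- gen_weierstrass(0.7, 3, length = 4096)
  bc <- expect_warning(box_count_curve(w, normalize = TRUE), NA)
  expect_lt(abs(bc$slope - (2 + log(0.7) / log(3))), 0.2)
})

test_that("fast curve counting equals the dense-sampling oracle", {
  set.seed(71)
  for (k in 1:6) {
    n <- sample(20:200, 1)
    x <- cumsum(stats::rnorm(n)) * stats::runif(1, 0.3, 25)
    for (eps in c(0.1, 0.4, 1, 3.2, 12.8)) {
      bc <- suppressWarnings(
        box_count_curve(x, grid_ladder(eps * c(1, 2, 4, 8, 16)),
                        range_policy = "full"))
      expect_identical(bc$counts[1], as.numeric(oracle_curve_count(x, eps)),
                       label = sprintf("n=%d eps=%g", n, eps))
    }
  }
  # exact-boundary fixture: integer ramp on an integer grid
  ramp_bc <- suppressWarnings(
    box_count_curve(as.numeric(1:20), grid_ladder(c(1, 2, 4, 8, 16)),
                    range_policy = "full"))
  expect_identical(ramp_bc$counts[1],
                   as.numeric(oracle_curve_count(as.numeric(1:20), 1)))
})

test_that("box counts are monotone and scale-invariant", {
  fixtures <- list(gen_weierstrass(0.7, 3, length = 512),
                   gen_random_walk(length = 500, seed = 3),
                   gen_sine(60, noise_sd = 0.1, length = 500, seed = 4))
  for (x in fixtures) {
    bc <- suppressWarnings(box_count_curve(x, normalize = TRUE))
    expect_true(all(diff(bc$counts) <= 0))
  }
  # rescaling both axes and the ladder together leaves counts unchanged
  y <- as.numeric(gen_random_walk(length = 300, seed = 9))
  t <- as.numeric(seq_along(y))
  for (s in c(0.01, 7, 1000)) {
    a <- caar:::count_cells_polyline((t - 1) / 1.3, (y - min(y)) / 1.3)
    b <- caar:::count_cells_polyline((t * s - s) / (1.3 * s),
                                     (y * s - min(y * s)) / (1.3 * s))
    expect_identical(a, b)
  }
})

test_that("phase-space occupancy counting behaves and matches brute force", {
  # all vectors identical: one occupied cell at every size, slope 0
  ps1 <- embed_delay(rep(2.5, 50), tau = 1, L = 2)
  bc1 <- box_count_points(ps1)
  expect_true(all(bc1$counts == 1))
  expect_equal(bc1$slope, 0)

  # 1-D embedding of uniform samples on an interval: dimension about 1
  set.seed(15)
  u <- caar_series(stats::runif(8000, 0, 100))
  bcu <- box_count_points(embed_delay(u, tau = 1, L = 0))
  expect_lt(abs(bcu$slope - 1), 0.15)

  # brute-force 2-D occupancy equality
  set.seed(16)
  pts <- caar_series(stats::runif(150, 0, 30))
  ps <- embed_delay(pts, tau = 1, L = 1)
  for (eps in c(0.8, 1.7, 3.2)) {
    bc <- box_count_points(ps, grid_ladder(eps * c(1, 2, 4, 8, 16)),
                           range_policy = "full")
    expect_identical(bc$counts[1],
                     as.numeric(brute_occupancy_2d(ps$vectors, eps)))
  }
})

test_that("embed_delay builds delay vectors by definition", {
  ps <- embed_delay(c(1, 2, 3, 4), tau = 1, L = 1)
  expect_equal(ps$vectors, cbind(c(2, 3, 4), c(1, 2, 3)))

  ps0 <- embed_delay(c(5, 6, 7), tau = 1, L = 0)
  expect_equal(as.numeric(ps0$vectors), c(5, 6, 7))

  expect_equal(nrow(embed_delay(1:10, tau = 2, L = 2)$vectors), 6)
  expect_error(embed_delay(1:10, tau = 5, L = 2), "L \\* tau")
})

test_that("order selection ceils the mean phase-space slope", {
  expect_equal(order_from_slopes(c(4.2, 4.6)), 5L)
  expect_equal(order_from_slopes(c(2, 2)), 2L)
  expect_equal(order_from_slopes(2.5), 3L)
  expect_equal(order_from_slopes(0.2), 1L)
  expect_error(select_order(list()), "at least one")

  sigs <- list(gen_random_walk(length = 400, seed = 1),
               gen_random_walk(length = 400, seed = 2))
  sel <- select_order(sigs, tau = 1, L = 3)
  expect_equal(sel$order, max(1L, as.integer(ceiling(mean(sel$slopes)))))
  expect_length(sel$slopes, 2)
})
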