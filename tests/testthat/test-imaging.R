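test_that("background subtraction uses the laser-off rows", {
  px <- matrix(7, 40, 10)
  ls <- linescan(px, line_period = 1 / 200, dark_line_rows = 1:5)
  out <- subtract_background(ls)
  expect_equal(out$pixels, matrix(0, 40, 10))

  ls0 <- linescan(px, line_period = 1 / 200)
  expect_error(subtract_background(ls0), "laser-off")
  expect_equal(subtract_background(ls0, background = 0)$pixels, px)

  # synthetic render: residual dark-row mean within 3 SE of zero
  geom <- imaging_geometry(n_dark_lines = 40, background_offset = 30)
  prof <- trace(rep(1, 400), dt = geom$line_period, units = "au")
  sc <- render_linescan(list(list(profile = prof, columns = 5:20)), geom,
                        seed = 8)
  sub <- subtract_background(sc$green)
  dark <- sub$pixels[sub$dark_line_rows, ]
  expect_lt(abs(mean(dark)), 3 * sqrt(30 / length(dark)))
})

test_that("line-scan profile is the per-line spatial mean", {
  px <- matrix(3, 20, 8)
  ls <- linescan(px, line_period = 1 / 150)
  expect_equal(linescan_profile(ls, 1:8)$values, rep(3, 20))

  px2 <- matrix(rnorm(160), 20, 8)
  ls2 <- linescan(px2, line_period = 1 / 150)
  expect_equal(linescan_profile(ls2, 4)$values, px2[, 4])
  # linearity: mean of per-column profiles
  cols <- c(2, 5, 7)
  stacked <- sapply(cols, function(j) linescan_profile(ls2, j)$values)
  expect_equal(linescan_profile(ls2, cols)$values, rowMeans(stacked))
  expect_error(linescan_profile(ls2, integer(0)), "empty")
})

test_that("sliding average: impulse response and convolution oracle", {
  p <- trace(rep(2, 50), dt = 0.01, units = "au")
  expect_equal(sliding_average(p, 5)$values, rep(2, 50))

  imp <- trace(c(numeric(20), 1, numeric(20)), dt = 0.01, units = "au")
  sm <- sliding_average(imp, 5)
  expect_equal(sm$values[19:23], rep(0.2, 5))

  set.seed(3)
  noisy <- trace(rnorm(100), dt = 0.01, units = "au")
  got <- sliding_average(noisy, 9)
  oracle <- stats::filter(noisy$values, rep(1 / 9, 9), sides = 2)
  interior <- 5:96
  expect_lt(max(abs(got$values[interior] - oracle[interior])), 1e-12)
  expect_error(sliding_average(p, 4), "odd")
  expect_error(sliding_average(p, 51), "longer")
})

test_that("separable Gaussian filter equals the full 2-D kernel oracle", {
  set.seed(21)
  px <- matrix(rpois(30 * 22, 50), 30, 22)
  ls <- linescan(px, line_period = 1 / 200)
  got <- gaussian_filter2d(ls, sigma_t_px = 2, sigma_x_px = 1)$pixels

  # oracle: explicit 2-D kernel, reflect padding, direct convolution
  r_t <- ceiling(4 * 2); r_x <- ceiling(4 * 1)
  kt <- exp(-((-r_t:r_t)^2) / (2 * 4)); kt <- kt / sum(kt)
  kx <- exp(-((-r_x:r_x)^2) / (2 * 1)); kx <- kx / sum(kx)
  k2 <- outer(kt, kx)
  reflect <- function(i, n) {
    i <- ifelse(i < 1L, 1L - i, i)
    ifelse(i > n, 2L * n + 1L - i, i)
  }
  oracle <- matrix(0, 30, 22)
  for (i in 1:30) for (j in 1:22) {
    ii <- reflect(i + (-r_t:r_t), 30)
    jj <- reflect(j + (-r_x:r_x), 22)
    oracle[i, j] <- sum(k2 * px[ii, jj])
  }
  expect_lt(max(abs(got - oracle)), 1e-9)

  # unit-sum kernel leaves a constant image unchanged
  const <- linescan(matrix(5, 25, 12), line_period = 1 / 200)
  expect_equal(gaussian_filter2d(const)$pixels, matrix(5, 25, 12))
})

test_that("dF/F window arithmetic matches the direct oracle", {
  dt <- 1 / 200
  n <- 400
  v <- rep(100, n)
  tt <- (seq_len(n) - 1L) * dt
  onset <- 1.0
  v[tt >= onset] <- 100 + 40 * exp(-(tt[tt >= onset] - onset) / 1.5)
  p <- trace(v, dt = dt, units = "au")

  got <- df_over_f(p, stim_onset = onset)
  eps <- dt / 2
  f0 <- mean(v[tt >= onset - 0.15 - eps & tt < onset - eps])
  fp <- mean(v[tt >= onset + 0.1 - eps & tt < onset + 0.25 - eps])
  expect_equal(got, (fp - f0) / f0, tolerance = 1e-9)

  # scale invariance
  p2 <- trace(v * 7.3, dt = dt, units = "au")
  expect_equal(df_over_f(p2, onset), got, tolerance = 1e-12)

  expect_equal(df_over_f(trace(rep(5, n), dt = dt, units = "au"), onset), 0)
  neg <- trace(v - 200, dt = dt, units = "au")
  expect_error(df_over_f(neg, onset), "F0")
})

test_that("worked dF/F example: 100 -> 120 gives 0.2", {
  dt <- 1 / 200
  v <- c(rep(100, 200), rep(120, 200))
  p <- trace(v, dt = dt, units = "au")
  expect_equal(df_over_f(p, stim_onset = 1.0), 0.2, tolerance = 1e-9)
})

test_that("dG/R matches the direct oracle and is red-homogeneous", {
  set.seed(6)
  g <- array(rpois(20 * 10 * 10, 80), c(20, 10, 10))
  g[11:20, 3:7, 3:7] <- g[11:20, 3:7, 3:7] + 30
  r <- array(rpois(20 * 10 * 10, 120), c(20, 10, 10))
  gs <- frame_series(g); rs <- frame_series(r)
  roi <- list(rows = 3:7, cols = 3:7)
  pre <- 1:10; post <- 11:20

  got <- dg_over_r(gs, rs, roi, pre, post)
  dg <- mean(g[post, 3:7, 3:7]) - mean(g[pre, 3:7, 3:7])
  rr <- mean(r[c(pre, post), 3:7, 3:7])
  expect_equal(got, dg / rr, tolerance = 1e-9)

  # doubling the red channel halves the ratio
  rs2 <- frame_series(2 * r)
  expect_equal(dg_over_r(gs, rs2, roi, pre, post), got / 2, tolerance = 1e-12)

  # identical pre/post green -> 0
  expect_equal(dg_over_r(frame_series(array(50, c(20, 10, 10))), rs, roi,
                         pre, post), 0)
  expect_error(dg_over_r(gs, rs, roi, 1:10, 10:20), "disjoint")
})

test_that("pipeline identity: render -> subtract -> profile -> dF/F", {
  geom <- imaging_geometry(line_period = 1 / 200, n_dark_lines = 60,
                           background_offset = 40)
  # true transient with known dF/F
  dt <- 1 / 200
  tt <- seq(0, 4, by = dt)
  onset <- 1.0
  f <- 1 + 0.3 * ifelse(tt >= onset, exp(-(tt - onset) / 2), 0) *
    (1 - exp(-pmax(tt - onset, 0) / 0.02))
  prof <- trace(f, dt = dt, units = "au")
  true_dff <- df_over_f(prof, onset)

  sc <- render_linescan(list(list(profile = prof, columns = 8:24)), geom,
                        noiseless = TRUE)
  rec <- linescan_profile(subtract_background(sc$green), 8:24)
  expect_equal(df_over_f(rec, onset), true_dff, tolerance = 1e-6)
})

test_that("decay fitting: model selection and weighted tau", {
  dt <- 0.01
  tt <- seq(0, 8, by = dt)
  mono <- trace(0.4 * exp(-tt / 3.16) + 1, dt = dt, units = "au")
  fm <- fit_decay(mono, 0)
  expect_equal(fm$model, "mono")
  expect_lt(abs(fm$taus - 3.16) / 3.16, 0.01)
  expect_equal(fm$weighted_tau, fm$taus)

  # degenerate bi-exponential: weighted tau collapses to tau1
  expect_equal(weighted_tau(c(2.5, 7), c(0.8, 0)), 2.5)

  # clear bi-exponential is promoted by the F-test
  set.seed(31)
  bi <- 0.5 * exp(-tt / 0.5) + 0.5 * exp(-tt / 4) + 1
  fb <- fit_decay(trace(bi + rnorm(length(tt), 0, 0.005), dt = dt,
                        units = "au"), 0)
  expect_equal(fb$model, "bi")
  expect_equal(sort(fb$taus), c(0.5, 4), tolerance = 0.15)

  expect_error(fit_decay(trace(exp(-(0:100) / 50), dt = 0.01, units = "au"),
                         0), "7 s")
})

test_that("bi-exponential selection is reliable under 1% noise", {
  dt <- 0.02
  tt <- seq(0, 8, by = dt)
  shape <- 0.5 * exp(-tt / 0.5) + 0.5 * exp(-tt / 4) + 1
  hits <- 0L
  n_rep <- 100L
  for (s in seq_len(n_rep)) {
    set.seed(1000 + s)
    y <- shape + rnorm(length(tt), 0, 0.01)
    f <- fit_decay(trace(y, dt = dt, units = "au"), 0)
    hits <- hits + (f$model == "bi")
  }
  expect_gte(hits / n_rep, 0.95)
})
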