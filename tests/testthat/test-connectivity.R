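fft_amplitude <- function(x, freq, dt) {
  n <- length(x)
  2 * abs(fft(x))[round(freq * n * dt) + 1] / n
}

test_that("band-pass keeps in-band and suppresses out-of-band sinusoids", {
  t <- seq(0, 4999)
  x_in <- sin(2 * pi * 0.1 * t)
  x_out <- sin(2 * pi * 0.4 * t)
  y <- bandpass(cbind(x_in, x_out), 0.008, 0.25, dt = 1)
  expect_gt(fft_amplitude(y[, 1], 0.1, 1) / fft_amplitude(x_in, 0.1, 1), 0.95)
  expect_lt(fft_amplitude(y[, 2], 0.4, 1) / fft_amplitude(x_out, 0.4, 1), 0.1)
})

test_that("band-pass removes the mean and rejects bad bands", {
  x <- cbind(rep(5, 200), rnorm(200))
  y <- bandpass(x, 0.008, 0.2, dt = 1)
  expect_equal(max(abs(y[, 1])), 0, tolerance = 1e-10)
  expect_lt(abs(mean(y[, 2])), 1e-10)
  expect_error(bandpass(x, 0.008, 0.6, dt = 1), "Nyquist")
  expect_error(bandpass(x, 0.3, 0.2, dt = 1), "low < high")
  expect_error(bandpass(x[1:5, ], 0.008, 0.2, dt = 1), "too short")
  # upper edge at Nyquist degrades gracefully to a high-pass
  expect_silent(y2 <- bandpass(x, 0.008, 0.25, dt = 2))
  expect_equal(dim(y2), dim(x))
})

test_that("static FC is the clipped Fisher z of Pearson correlation", {
  # constructed pair with exact r = 0.5: cor(x, 0.5 x + sqrt(0.75) y) for
  # orthonormal x, y
  n <- 400
  x <- rnorm(n); y <- rnorm(n)
  y <- residuals(lm(y ~ x))
  x <- (x - mean(x)) / sd(x); y <- y / sd(y)
  z <- compute_sfc(cbind(a = x, b = 0.5 * x + sqrt(0.75) * y))
  expect_equal(z["a", "b"], atanh(0.5), tolerance = 1e-10)
  # identical columns clip to a large finite z
  z2 <- compute_sfc(cbind(x, x, y))
  expect_equal(z2[1, 2], atanh(1 - 1e-7), tolerance = 1e-12)
  expect_lt(z2[1, 2], Inf)
  expect_true(all(diag(z2) == 0))
  expect_true(isSymmetric(unclass(z2)))
})

test_that("independent series give near-zero Fisher z", {
  set.seed(5)
  z <- compute_sfc(matrix(rnorm(2000 * 4), ncol = 4))
  expect_lt(max(abs(upper_vec <- z[upper.tri(z)])), 3 / sqrt(2000 - 3))
})

test_that("FC is invariant to column-wise affine rescaling", {
  set.seed(8)
  ts <- matrix(rnorm(300 * 5), ncol = 5)
  ts2 <- sweep(sweep(ts, 2, c(2, 3, 0.5, 10, 1), "*"), 2,
               c(1, 0, -5, 2, 7), "+")
  expect_equal(unclass(compute_sfc(ts)), unclass(compute_sfc(ts2)),
               tolerance = 1e-10)
})

test_that("degenerate FC inputs are rejected", {
  expect_error(compute_sfc(matrix(1, 10, 3)), "constant")
  expect_error(compute_sfc(matrix(c(rnorm(29), NA), 10, 3)), "NA")
  expect_error(compute_sfc(matrix(rnorm(4), 2, 2)), "3 time points")
})

test_that("window count follows floor((T dt - length)/step) + 1", {
  set.seed(2)
  ts300 <- matrix(rnorm(150 * 6), ncol = 6)   # 150 samples x 2 s = 300 s
  wf <- sliding_windows(ts300, dt = 2, length = 40, step = 20)
  expect_length(wf$windows, 14)
  expect_equal(wf$start_times, seq(0, 260, by = 20))
  wf2 <- sliding_windows(ts300, dt = 2, length = 50, step = 10)
  expect_length(wf2$windows, 26)
  expect_error(sliding_windows(matrix(rnorm(20 * 4), ncol = 4), dt = 2,
                               length = 40, step = 20), "fewer than 2")
  expect_error(sliding_windows(ts300, dt = 2, length = 41, step = 20),
               "multiple of dt")
})

test_that("step = length tiles the series without gap or overlap", {
  set.seed(3)
  ts <- matrix(rnorm(120 * 4), ncol = 4)
  wf <- sliding_windows(ts, dt = 1, length = 30, step = 30)
  expect_length(wf$windows, 4)
  # each window FC equals FC of the corresponding disjoint block
  for (i in 1:4) {
    rows <- ((i - 1) * 30 + 1):(i * 30)
    expect_equal(unclass(wf$windows[[i]]),
                 unclass(compute_sfc(ts[rows, ])), tolerance = 1e-12)
  }
})

test_that("fc_similarity is the upper-triangle Pearson r and is symmetric", {
  set.seed(4)
  a <- compute_sfc(matrix(rnorm(100 * 8), ncol = 8))
  b <- compute_sfc(matrix(rnorm(100 * 8), ncol = 8))
  expect_equal(fc_similarity(a, a), 1)
  expect_equal(fc_similarity(a, -unclass(a)), -1)
  expect_equal(fc_similarity(a, b), fc_similarity(b, a))
  expect_equal(fc_similarity(a, b),
               cor(a[upper.tri(a)], b[upper.tri(b)]), tolerance = 1e-12)
  expect_error(fc_similarity(a, b[1:4, 1:4]), "node set")
})

test_that("synthetic states sharing block structure have high edge similarity", {
  sc <- nr_scenario(4, rho_in = 0.5, rho_base = 0.05,
                    integration = c(rest = 0, task = 0.1),
                    sigma = 0, jitter_sd = 0)
  co <- generate_cohort(8, 40, 300, dt = 2, scenario = sc, seed = 31)
  group <- lapply(co$state_names, function(st) {
    Reduce(`+`, lapply(co$data, function(d) unclass(compute_sfc(d[[st]])))) /
      length(co$data)
  })
  expect_gt(fc_similarity(group[[1]], group[[2]]), 0.9)
})
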