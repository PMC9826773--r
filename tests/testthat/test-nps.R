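test_that("quadratic detrending removes polynomial surfaces exactly", {
  x <- outer(rep(1, 16), seq(-1, 1, length.out = 16))
  y <- t(x)
  quad <- 3 + 2 * x - y + 0.5 * x^2 - x * y + 2 * y^2
  expect_lt(max(abs(detrend_roi(quad))), 1e-9 * max(abs(quad)))
  ramp <- 5 + 4 * x + 2 * y
  expect_lt(max(abs(detrend_roi(ramp))), 1e-9 * max(abs(ramp)))
  expect_error(detrend_roi(matrix(0, 4, 4)), "at least 8")
})

test_that("detrending costs six degrees of freedom on white noise", {
  set.seed(21)
  n <- 16L
  vr <- replicate(400, stats::var(as.vector(detrend_roi(
    matrix(rnorm(n * n, sd = 10), n, n)))))
  expect_equal(mean(vr), 100 * (1 - 6 / n^2), tolerance = 0.02)
})

test_that("2D NPS matches the flat-spectrum value and a brute-force DFT", {
  st <- make_uniform_stack(size = 160, n_slices = 10, sigma = 10, seed = 2,
                           pixel = 0.5)
  rois <- default_nps_rois(st, 64L, 34L)
  nps <- compute_nps_2d(st, rois)
  expect_equal(mean(nps$values), 10^2 * 0.5 * 0.5, tolerance = 0.05)
  expect_true(all(nps$values >= 0))
  expect_equal(nps$freq_step_x, 1 / (64 * 0.5))

  # constant stack -> zero NPS
  s0 <- image_stack(array(7, dim = c(64, 64, 2)), 0.5)
  expect_equal(max(compute_nps_2d(s0, list(square_roi(32, 32, 16)))$values), 0)

  # brute-force discrete Fourier sum on one 16x16 ROI
  s1 <- make_uniform_stack(size = 64, n_slices = 1, sigma = 8, seed = 4, pixel = 0.7)
  roi <- square_roi(32, 32, 16)
  nps1 <- compute_nps_2d(s1, list(roi))
  patch <- detrend_roi(s1$voxels[25:40, 25:40, 1])
  n <- 16
  brute <- matrix(0, n, n)
  for (p in 0:(n - 1)) for (q in 0:(n - 1)) {
    acc <- 0 + 0i
    for (a in 0:(n - 1)) for (b in 0:(n - 1)) {
      acc <- acc + patch[a + 1, b + 1] * exp(-2i * pi * (p * a + q * b) / n)
    }
    brute[p + 1, q + 1] <- Mod(acc)^2
  }
  brute <- brute * 0.7 * 0.7 / (n * n)
  shift <- function(m) m[c(9:16, 1:8), c(9:16, 1:8)]
  expect_lt(max(abs(nps1$values - shift(brute))) / max(brute), 1e-10)
})

test_that("NPS is linear in generator variance", {
  s1 <- make_uniform_stack(size = 96, n_slices = 6, sigma = 5, seed = 31)
  s2 <- image_stack(s1$voxels * 2, 0.5)
  r1 <- compute_nps_2d(s1, list(square_roi(48, 48, 32)))
  r2 <- compute_nps_2d(s2, list(square_roi(48, 48, 32)))
  expect_equal(r2$values, 4 * r1$values, tolerance = 1e-12)
})

test_that("radial rebinning reproduces rotationally symmetric inputs", {
  st <- make_uniform_stack(size = 64, n_slices = 1, sigma = 1, seed = 1)
  tmpl <- compute_nps_2d(st, list(square_roi(32, 32, 32)))
  fr <- sqrt(outer(tmpl$freq_y^2, tmpl$freq_x^2, `+`))

  g <- function(f) exp(-3 * f)
  tmpl$values <- matrix(g(fr), nrow(fr))
  rad <- radial_rebin(tmpl)
  keep <- rad$freq < 0.9  # away from the Nyquist cap
  expect_equal(rad$values[keep], g(rad$freq[keep]), tolerance = 0.02)

  tmpl$values <- matrix(5, nrow(fr), ncol(fr))
  flat <- radial_rebin(tmpl)
  expect_true(all(flat$values == 5))

  # one huge bin equals the grand mean of retained samples
  one <- radial_rebin(tmpl, bin_width = 2)
  expect_equal(one$values, 5)
})

test_that("noise magnitude obeys Parseval and homogeneity", {
  st <- make_uniform_stack(size = 160, n_slices = 10, sigma = 10, seed = 6)
  rois <- default_nps_rois(st, 64L, 34L)
  nps <- compute_nps_2d(st, rois)
  nm <- noise_magnitude(nps)
  # ensemble variance of the detrended patches (Parseval identity)
  vr <- mean(vapply(seq_len(10), function(k) {
    mean(vapply(rois, function(r) {
      mean(detrend_roi(st$voxels[, , k][
        (r$center_row - 31):(r$center_row + 32),
        (r$center_col - 31):(r$center_col + 32)])^2)
    }, numeric(1)))
  }, numeric(1)))
  expect_equal(nm^2, vr, tolerance = 0.02)

  nps4 <- nps; nps4$values <- nps$values * 4
  expect_equal(noise_magnitude(nps4), 2 * nm)
  nps0 <- nps; nps0$values[] <- 0
  expect_equal(noise_magnitude(nps0), 0)
})

test_that("average frequency matches analytic integrals and is scale-free", {
  freq <- seq(0, 1, by = 0.01)
  flat <- structure(list(freq = freq, values = rep(2, length(freq)),
                         counts = rep(10L, length(freq))), class = "nps_radial")
  expect_equal(average_frequency(flat), 0.5, tolerance = 0.001)

  ramp <- flat; ramp$values <- freq
  expect_equal(average_frequency(ramp), 2 / 3, tolerance = 0.002)

  spike <- flat; spike$values <- rep(0, length(freq)); spike$values[30] <- 3
  expect_equal(average_frequency(spike), freq[30], tolerance = 0.02)

  scaled <- flat; scaled$values <- flat$values * 37
  expect_equal(average_frequency(scaled), average_frequency(flat))

  zero <- flat; zero$values[] <- 0
  expect_error(average_frequency(zero), "all-zero")
})
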