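flat_nps <- function(n0, fmax = 2) list(radial = list(freq = c(0, fmax),
                                                      values = c(n0, n0)))
unit_ttf <- function(fmax = 2) list(freq_mm_inv = c(0, fmax), ttf = c(1, 1))

test_that("disk task function has the right DC value and first zero", {
  grid <- frequency_grid(0.82, 256L)
  W <- task_function(task_spec(10, 42), grid)
  expect_equal(max(W), 42 * pi * 25)
  expect_true(all(task_function(task_spec(10, 0), grid) == 0))

  # radial profile crosses zero at 3.8317 / (2 pi R)
  rho <- seq(0.09, 0.16, by = 1e-4)
  g1 <- structure(list(u = rho, v = 0, step_u = 1e-4, step_v = 1e-4,
                       rho = matrix(rho, 1)), class = "frequency_grid")
  w1 <- as.numeric(task_function(task_spec(10, 42), g1))
  expect_equal(rho[which.min(w1)], 3.8317 / (2 * pi * 5), tolerance = 0.002)
})

test_that("eye filter peaks at 4 cycles/degree with unit maximum", {
  dm <- display_model()
  rho <- seq(0, 1.5, by = 1e-4)
  g1 <- structure(list(u = rho, v = 0, step_u = 1e-4, step_v = 1e-4,
                       rho = matrix(rho, 1)), class = "frequency_grid")
  E <- as.numeric(eye_filter(dm, g1))
  expect_equal(E[1], 0)
  expect_equal(max(E), 1, tolerance = 1e-5)
  peak_deg <- frequency_conversion(dm, rho[which.max(E)])
  expect_equal(peak_deg, 4, tolerance = 0.01)
})

test_that("frequency conversion follows the display geometry", {
  dm <- display_model(zoom = 1, viewing_distance_mm = 573,
                      display_fov_mm = 300, display_pixel_mm = 300 / 512,
                      matrix_size = 512)
  expect_equal(frequency_conversion(dm, 1), 573 * pi / 180, tolerance = 1e-9)
  expect_equal(frequency_conversion(dm, 0), 0)
  dm2 <- display_model(zoom = 2, viewing_distance_mm = 573,
                       display_fov_mm = 300, display_pixel_mm = 300 / 512,
                       matrix_size = 512)
  expect_equal(frequency_conversion(dm2, 1),
               frequency_conversion(dm, 1) / 2)
})

test_that("d' matches the closed form for a trivial observer", {
  grid <- frequency_grid(0.82, 256L)
  task <- task_spec(10, 42)
  W <- task_function(task, grid)
  n0 <- 5
  dp <- dprime_npwe(task, unit_ttf(), flat_nps(n0), display = NULL, grid = grid)
  closed <- sqrt(sum(W^2) * grid$step_u * grid$step_v / n0)
  expect_equal(dp$d_prime, closed, tolerance = 1e-9)
})

test_that("d' homogeneity laws hold", {
  grid <- frequency_grid(0.82, 256L)
  base <- dprime_npwe(task_spec(10, 42), unit_ttf(), flat_nps(5),
                      display = NULL, grid = grid)
  dbl <- dprime_npwe(task_spec(10, 84), unit_ttf(), flat_nps(5),
                     display = NULL, grid = grid)
  expect_equal(dbl$d_prime / base$d_prime, 2, tolerance = 0.005)
  noisier <- dprime_npwe(task_spec(10, 42), unit_ttf(), flat_nps(5 * 3),
                         display = NULL, grid = grid)
  expect_equal(noisier$d_prime / base$d_prime, 3^(-1 / 2), tolerance = 0.005)
})

test_that("d' responds monotonically to noise, contrast and resolution", {
  grid <- frequency_grid(0.82, 128L)
  dm <- display_model()
  f <- seq(0, 2, by = 0.05)
  ttf_good <- list(freq_mm_inv = f, ttf = exp(-2 * pi^2 * 0.3^2 * f^2))
  ttf_bad <- list(freq_mm_inv = f, ttf = exp(-2 * pi^2 * 0.8^2 * f^2))
  nps_lo <- list(radial = list(freq = f, values = 20 * f * exp(-f / 0.15)))
  nps_hi <- list(radial = list(freq = f, values = 60 * f * exp(-f / 0.15)))
  task <- task_spec(10, 42)
  d <- function(ttf, nps, tk = task) dprime_npwe(tk, ttf, nps, dm, grid)$d_prime
  expect_gt(d(ttf_good, nps_lo), d(ttf_bad, nps_lo))
  expect_gt(d(ttf_good, nps_lo), d(ttf_good, nps_hi))
  expect_gt(d(ttf_good, nps_lo, task_spec(10, 60)), d(ttf_good, nps_lo))
})

test_that("grid refinement changes d' by less than 1%", {
  task <- task_spec(10, 42)
  dm <- display_model()
  f <- seq(0, 2, by = 0.05)
  ttf <- list(freq_mm_inv = f, ttf = exp(-2 * pi^2 * 0.5^2 * f^2))
  nps <- list(radial = list(freq = f, values = 30 * f * exp(-f / 0.15)))
  d256 <- dprime_npwe(task, ttf, nps, dm, frequency_grid(0.82, 256L))$d_prime
  d512 <- dprime_npwe(task, ttf, nps, dm, frequency_grid(0.82, 512L))$d_prime
  expect_lt(abs(d512 / d256 - 1), 0.01)
})

test_that("degenerate noise input and the printed-exponent mode are handled", {
  grid <- frequency_grid(0.82, 64L)
  task <- task_spec(10, 42)
  expect_error(dprime_npwe(task, unit_ttf(), flat_nps(0), NULL, grid),
               "noise floor")
  d1 <- dprime_npwe(task, unit_ttf(), flat_nps(5), NULL, grid, nps_exponent = 1)
  d2 <- dprime_npwe(task, unit_ttf(), flat_nps(5), NULL, grid, nps_exponent = 2)
  expect_false(isTRUE(all.equal(d1$d_prime, d2$d_prime)))
  # squared-NPS mode: flat NPS of value N0 scales d' by sqrt(N0) relative
  expect_equal(d2$d_prime, d1$d_prime / sqrt(5), tolerance = 1e-9)
})
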