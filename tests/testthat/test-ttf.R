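test_that("insert centers are found to sub-pixel precision", {
  st <- make_disk_stack(size = 96, contrast = 120, diameter = 25)
  cen <- estimate_center(st, center_roi(st, 20))
  expect_lt(abs(cen$center_row - 48.5), 0.1)
  expect_lt(abs(cen$center_col - 48.5), 0.1)
  expect_lt(abs(cen$x_mm), 0.05)

  # shifted disk tracks the shift
  st2 <- make_disk_stack(size = 96, contrast = 120, diameter = 25,
                         center_x = 3.3 * 0.488, center_y = -2.1 * 0.488)
  cen2 <- estimate_center(st2, circular_roi(48.5 - 2.1, 48.5 + 3.3, 20))
  expect_lt(abs(cen2$center_col - (48.5 + 3.3)), 0.1)
  expect_lt(abs(cen2$center_row - (48.5 - 2.1)), 0.1)

  # zero contrast is a detection error
  flat <- make_uniform_stack(size = 96, n_slices = 1, sigma = 0, pixel = 0.488)
  expect_error(estimate_center(flat, center_roi(flat, 20)), "detection error")
})

test_that("radial ESF reproduces step and Gaussian-blurred edges", {
  st <- make_disk_stack(size = 96, contrast = 100, diameter = 25, background = 50)
  roi <- center_roi(st, 20)
  cen <- estimate_center(st, roi)
  esf <- extract_esf(st, roi, cen)
  r <- esf$radius_mm
  expect_true(all(diff(r) > 0))
  expect_true(all(esf$esf_hu[r < 11.5] == 150))
  expect_true(all(esf$esf_hu[r > 13.5] == 50))
  # pixel-center sampling of a sharp edge: at most the bin straddling the
  # disk radius mixes inside and outside pixels
  mixed <- which(esf$esf_hu > 50 + 1e-9 & esf$esf_hu < 150 - 1e-9)
  expect_lte(length(mixed), 2)
  if (length(mixed)) expect_lt(max(abs(r[mixed] - 12.5)), 0.1)

  # blurred edge follows C * Phi((R - r) / sigma); fine bins so that the
  # bin-quantization error stays below the 1D-approximation tolerance
  sb <- 0.5
  stb <- make_disk_stack(size = 96, contrast = 100, diameter = 25, psf_sigma = sb)
  esfb <- extract_esf(stb, roi, estimate_center(stb, roi),
                      bin_width_mm = 0.02 * 0.488)
  near <- abs(esfb$radius_mm - 12.5) < 3 * sb
  model <- 100 * pnorm((12.5 - esfb$radius_mm[near]) / sb)
  expect_lt(max(abs(esfb$esf_hu[near] - model)), 2)

  # refinement stability: halving the bin width agrees at common radii
  esf_h <- extract_esf(stb, roi, estimate_center(stb, roi),
                       bin_width_mm = 0.05 * 0.488)
  common <- stats::approx(esf_h$radius_mm, esf_h$esf_hu,
                          xout = esfb$radius_mm[near])$y
  expect_lt(max(abs(common - esfb$esf_hu[near]), na.rm = TRUE), 1.5)
})

test_that("LSF differentiation recovers width, sign and degenerate cases", {
  stb <- make_disk_stack(size = 96, contrast = 100, diameter = 25, psf_sigma = 0.5)
  roi <- center_roi(stb, 20)
  esf <- extract_esf(stb, roi, estimate_center(stb, roi))
  lsf <- esf_to_lsf(esf, smooth = FALSE)
  expect_gt(max(lsf$lsf), 0)  # peak positive despite decreasing edge
  # second-moment width of the LSF near the edge matches sigma_b
  sel <- abs(lsf$radius_mm - 12.5) < 2.5
  w <- lsf$lsf[sel]; r <- lsf$radius_mm[sel]
  mu <- sum(r * w) / sum(w)
  sig <- sqrt(sum((r - mu)^2 * w) / sum(w))
  expect_equal(sig, 0.5, tolerance = 0.05)

  # step ESF -> impulse LSF
  step_esf <- structure(list(radius_mm = seq(0.1, 5, by = 0.1),
                             esf_hu = c(rep(100, 25), rep(0, 25)),
                             counts = rep(10L, 50)), class = "edge_profile")
  il <- esf_to_lsf(step_esf, smooth = FALSE)
  expect_equal(sum(il$lsf != 0), 2)  # central difference spans the jump

  # constant ESF -> zero LSF, which cannot be normalized
  const_esf <- structure(list(radius_mm = seq(0.1, 2, by = 0.1),
                              esf_hu = rep(5, 20), counts = rep(10L, 20)),
                         class = "edge_profile")
  zl <- esf_to_lsf(const_esf, smooth = FALSE)
  expect_true(all(zl$lsf == 0))
  expect_error(lsf_to_ttf(zl), "normalization error")
  expect_error(esf_to_lsf(structure(list(radius_mm = 1:3, esf_hu = 1:3,
                                         counts = rep(1L, 3)),
                                    class = "edge_profile")), "too few")
})

test_that("TTF of analytic LSFs matches Fourier pairs", {
  r <- seq(0.05, 20, by = 0.05)
  gauss <- structure(list(radius_mm = r,
                          lsf = exp(-(r - 10)^2 / (2 * 0.5^2)),
                          counts = rep(100L, length(r))), class = "lsf_profile")
  ttf <- lsf_to_ttf(gauss)
  expect_equal(ttf$ttf[1], 1, tolerance = 1e-9)
  sel <- ttf$freq_mm_inv <= 1.2
  model <- exp(-2 * pi^2 * 0.25 * ttf$freq_mm_inv[sel]^2)
  keep <- model >= 0.2
  expect_lt(max(abs(ttf$ttf[sel][keep] - model[keep])), 0.02)

  # impulse LSF -> TTF identically 1
  imp <- gauss; imp$lsf <- as.numeric(abs(r - 10) < 0.026)
  ti <- lsf_to_ttf(imp, window = FALSE)
  expect_true(all(abs(ti$ttf - 1) < 1e-9))

  # normalization invariance under scaling
  sc <- gauss; sc$lsf <- gauss$lsf * 17.3
  expect_equal(lsf_to_ttf(sc)$ttf, ttf$ttf)
})

test_that("fractional TTF readout interpolates and handles edge cases", {
  f <- seq(0, 2, by = 0.01)
  tt <- structure(list(freq_mm_inv = f, ttf = exp(-2 * pi^2 * 0.25 * f^2),
                       insert_contrast_hu = NA, n_slices_used = 1L),
                  class = "ttf_result")
  expect_equal(ttf_at_fraction(tt, 0.5), gaussian_ttf50(0.5), tolerance = 0.002)
  expect_equal(ttf_at_fraction(tt, 1), 0)
  tt2 <- tt; tt2$ttf <- exp(-2 * pi^2 * 1^2 * f^2)  # sigma doubled
  expect_equal(ttf_at_fraction(tt2, 0.5) / ttf_at_fraction(tt, 0.5), 0.5,
               tolerance = 0.01)
  high <- tt; high$ttf <- rep(1, length(f))
  expect_error(ttf_at_fraction(high, 0.5), "out-of-range")
})

test_that("end-to-end TTF recovery is accurate without and with noise", {
  roi_r <- 20
  for (sb in c(0.3, 0.5, 0.8)) {
    st <- make_disk_stack(size = 128, contrast = 120, diameter = 25,
                          psf_sigma = sb)
    tt <- compute_ttf(st, center_roi(st, roi_r), smooth = FALSE)
    expect_equal(tt$ttf50, gaussian_ttf50(sb), tolerance = 0.03)
    expect_equal(tt$insert_contrast_hu, 120, tolerance = 1)
  }

  stn <- make_disk_stack(size = 128, n_slices = 20, contrast = 120,
                         diameter = 25, psf_sigma = 0.5, sigma = 20, seed = 2)
  ttn <- compute_ttf(stn, center_roi(stn, roi_r), smooth = TRUE)
  expect_equal(ttn$ttf50, gaussian_ttf50(0.5), tolerance = 0.10)
})

test_that("TTF is invariant to HU offset and contrast scaling", {
  st <- make_disk_stack(size = 128, contrast = 120, diameter = 25, psf_sigma = 0.5)
  roi <- center_roi(st, 20)
  base <- compute_ttf(st, roi, smooth = FALSE)

  shifted <- image_stack(st$voxels + 500, 0.488, meta = st$meta)
  ts <- compute_ttf(shifted, roi, smooth = FALSE)
  expect_equal(ts$ttf, base$ttf, tolerance = 1e-8)

  scaled <- image_stack(st$voxels * 3, 0.488, meta = st$meta)
  tc <- compute_ttf(scaled, roi, smooth = FALSE)
  expect_equal(tc$ttf, base$ttf, tolerance = 1e-8)
  expect_equal(tc$insert_contrast_hu, 3 * base$insert_contrast_hu, tolerance = 0.1)
})
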