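# Fixture builders shared across the suite; everything is generated in
# code so the repository stays text-only.

make_uniform_stack <- function(size = 128L, n_slices = 4L, sigma = 10,
                               shape = "white", f0 = 0.15, seed = 1L,
                               pixel = 0.5, background = 0) {
  generate_uniform_stack(scene_spec(
    size, pixel, n_slices, background_hu = background,
    noise = noise_model(sigma, shape, if (shape == "ramp_gauss") f0 else NULL,
                        seed = seed)))
}

make_disk_stack <- function(size = 128L, n_slices = 1L, contrast = 120,
                            diameter = 25, psf_sigma = 0, sigma = 0,
                            seed = 1L, pixel = 0.488, background = 0,
                            shape = "white", f0 = 0.15,
                            center_x = 0, center_y = 0) {
  generate_insert_stack(scene_spec(
    size, pixel, n_slices, background_hu = background,
    inserts = list(insert_spec(center_x, center_y, diameter, contrast,
                               psf_sigma_mm = psf_sigma)),
    noise = noise_model(sigma, shape, if (shape == "ramp_gauss") f0 else NULL,
                        seed = seed)))
}

center_roi <- function(stack, radius_mm) {
  d <- dim(stack)
  circular_roi(d[1] / 2 + 0.5, d[2] / 2 + 0.5, radius_mm)
}

gaussian_ttf50 <- function(sigma_b) sqrt(log(2) / (2 * pi^2 * sigma_b^2))

# Independent brute-force paired signed-rank oracle: enumerates every sign
# assignment of the nonzero differences (Pratt ranks) explicitly.
wilcoxon_brute <- function(x, y) {
  d <- y - x
  if (all(d == 0)) return(1)
  r <- rank(abs(d))
  rk <- r[d != 0]
  m <- length(rk)
  w_obs <- sum(rk[d[d != 0] > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  w_all <- as.numeric(signs %*% rk)
  eps <- 1e-9
  min(1, 2 * min(mean(w_all <= w_obs + eps), mean(w_all >= w_obs - eps)))
}

# Measurement records shaped like a study output, built from a table of
# per-condition values (one replicate).
records_from_noise_table <- function(t2) {
  data.frame(version = t2$version, level = t2$level, keV = t2$keV,
             replicate = 1L, metric = "noise_magnitude",
             concentration_mg_ml = NA_real_, value = t2$noise_hu)
}
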