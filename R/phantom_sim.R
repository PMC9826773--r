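#' Noise model for synthetic phantom images
#'
#' Describes a stationary, zero-mean Gaussian noise field by its magnitude
#' (standard deviation in HU) and its texture. `shape = "white"` gives a flat
#' power spectrum; `shape = "ramp_gauss"` gives a CT-like radial spectrum
#' rising then falling, `S(f) proportional to f * exp(-f / f0)`, whose scale
#' parameter `f0` tunes the average spatial frequency (smaller `f0` means
#' blotchier, lower-frequency noise).
#'
#' @param sigma_hu target noise magnitude (HU); standard deviation of the
#'   generated field.
#' @param shape `"white"` or `"ramp_gauss"`.
#' @param f0_mm_inv texture scale parameter in 1/mm; required for
#'   `"ramp_gauss"`.
#' @param seed optional integer seed; every stack generated from this model
#'   is reproducible given the seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_hu, shape = c("white", "ramp_gauss"),
                        f0_mm_inv = NULL, seed = NULL) {
  shape <- match.arg(shape)
  stopifnot(sigma_hu >= 0)
  if (shape == "ramp_gauss") {
    if (is.null(f0_mm_inv) || f0_mm_inv <= 0) {
      stop("f0_mm_inv must be positive for ramp_gauss noise")
    }
  }
  structure(list(sigma_hu = sigma_hu, shape = shape,
                 f0_mm_inv = f0_mm_inv, seed = seed),
            class = "noise_model")
}

noise_psd_shape <- function(noise, f) {
  switch(noise$shape,
         white = rep(1, length(f)),
         ramp_gauss = f * exp(-f / noise$f0_mm_inv))
}

#' Circular insert specification
#'
#' A disk of known contrast blurred by a Gaussian point spread function.
#' Coordinates are in mm relative to the image center (x along columns,
#' y along rows).
#'
#' @param center_x_mm,center_y_mm insert center, mm from the image center.
#' @param diameter_mm disk diameter, mm.
#' @param contrast_hu HU above the scene background.
#' @param psf_sigma_mm standard deviation of the Gaussian edge blur, mm
#'   (0 = sharp edge). The ground-truth task transfer function of the
#'   insert is `exp(-2 * pi^2 * psf_sigma_mm^2 * f^2)`.
#' @param label optional insert name.
#' @return An object of class `insert_spec`.
#' @export
insert_spec <- function(center_x_mm = 0, center_y_mm = 0, diameter_mm,
                        contrast_hu, psf_sigma_mm = 0, label = NULL) {
  stopifnot(diameter_mm > 0, psf_sigma_mm >= 0)
  structure(list(center_x_mm = center_x_mm, center_y_mm = center_y_mm,
                 diameter_mm = diameter_mm, contrast_hu = contrast_hu,
                 psf_sigma_mm = psf_sigma_mm, label = label),
            class = "insert_spec")
}

#' Scene specification for the phantom generator
#'
#' @param image_size_pixels image matrix size (square).
#' @param pixel_spacing_mm pixel size, mm.
#' @param n_slices number of slices; slices are independent noise
#'   realizations over a common noiseless scene.
#' @param background_hu background HU value.
#' @param inserts list of [insert_spec()]s; must be pairwise non-overlapping.
#' @param noise a [noise_model()].
#' @param meta named list merged into the generated stack's metadata.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_size_pixels, pixel_spacing_mm, n_slices = 1L,
                       background_hu = 0, inserts = list(),
                       noise = noise_model(0), meta = list()) {
  stopifnot(n_slices >= 1, image_size_pixels >= 2, pixel_spacing_mm > 0)
  if (length(inserts) > 1L) {
    for (i in seq_along(inserts)) for (j in seq_len(i - 1L)) {
      a <- inserts[[i]]; b <- inserts[[j]]
      d <- sqrt((a$center_x_mm - b$center_x_mm)^2 + (a$center_y_mm - b$center_y_mm)^2)
      if (d < (a$diameter_mm + b$diameter_mm) / 2) {
        stop("scene error: inserts overlap")
      }
    }
  }
  structure(list(image_size_pixels = as.integer(image_size_pixels),
                 pixel_spacing_mm = pixel_spacing_mm, n_slices = as.integer(n_slices),
                 background_hu = background_hu, inserts = inserts, noise = noise,
                 meta = meta),
            class = "scene_spec")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

fft_freqs <- function(n, spacing) {
  k <- 0:(n - 1L)
  k[k > n / 2] <- k[k > n / 2] - n
  k / (n * spacing)
}

#' Generate a 2D noise field with a prescribed power spectrum
#'
#' White Gaussian noise is shaped in the frequency domain by the filter
#' `sqrt(S(f))`, with `S` normalized over the discrete grid so that the
#' field variance equals `sigma_hu^2` in expectation. The DC component is
#' zeroed, so the field is exactly zero-mean.
#'
#' @param noise a [noise_model()].
#' @param size field size in pixels (scalar or `c(nrow, ncol)`); at least 64.
#' @param pixel_spacing pixel size, mm.
#' @return A `size`-shaped numeric matrix of HU values.
#' @export
shaped_noise_field <- function(noise, size, pixel_spacing) {
  if (length(size) == 1L) size <- c(size, size)
  stopifnot(all(size >= 64))
  if (noise$sigma_hu == 0) return(matrix(0, size[1], size[2]))
  with_seed(noise$seed, shaped_noise_field_(noise, size, pixel_spacing))
}

# unseeded core, used internally when one seed covers many fields
shaped_noise_field_ <- function(noise, size, pixel_spacing) {
  if (length(size) == 1L) size <- c(size, size)
  if (noise$sigma_hu == 0) return(matrix(0, size[1], size[2]))
  fy <- fft_freqs(size[1], pixel_spacing)
  fx <- fft_freqs(size[2], pixel_spacing)
  fr <- sqrt(outer(fy^2, fx^2, `+`))
  s <- matrix(noise_psd_shape(noise, fr), size[1], size[2])
  s[1, 1] <- 0  # zero-mean field
  h <- sqrt(s / mean(s)) * noise$sigma_hu
  w <- matrix(stats::rnorm(prod(size)), size[1], size[2])
  Re(stats::fft(stats::fft(w) * h, inverse = TRUE)) / prod(size)
}

# Radial profile of a unit-contrast disk of radius R convolved with an
# isotropic Gaussian of sd sigma:
#   A(r) = int_0^R s/sigma^2 exp(-(s - r)^2 / (2 sigma^2)) I0e(r s / sigma^2) ds
# (I0e = exponentially scaled modified Bessel I0; the form is numerically
# stable for r, R >> sigma). Returns a function of radius.
blurred_disk_profile <- function(radius_mm, sigma_mm) {
  if (sigma_mm == 0) return(function(r) as.numeric(r <= radius_mm))
  w <- 6.5 * sigma_mm
  r_lo <- max(0, radius_mm - w)
  r_hi <- radius_mm + w
  r_grid <- seq(r_lo, r_hi, by = sigma_mm / 10)
  ds <- sigma_mm / 20
  s_grid <- seq(max(0, r_lo - w) + ds / 2, radius_mm, by = ds)
  # quadrature restricted to the edge window; contributions beyond 6.5
  # sigma are below 1e-9 of the contrast
  integrand <- outer(r_grid, s_grid, function(r, s) {
    s / sigma_mm^2 * exp(-(s - r)^2 / (2 * sigma_mm^2)) *
      besselI(r * s / sigma_mm^2, 0, expon.scaled = TRUE)
  })
  vals <- as.numeric(integrand %*% rep(ds, length(s_grid)))
  f <- stats::splinefun(r_grid, vals, method = "monoH.FC")
  function(r) {
    out <- numeric(length(r))
    out[r <= r_lo] <- 1
    mid <- r > r_lo & r < r_hi
    out[mid] <- pmin(pmax(f(r[mid]), 0), 1)
    out
  }
}

noiseless_scene_slice <- function(scene) {
  n <- scene$image_size_pixels
  d <- scene$pixel_spacing_mm
  half <- n * d / 2
  x <- (seq_len(n) - 0.5) * d - half  # columns
  y <- (seq_len(n) - 0.5) * d - half  # rows
  img <- matrix(scene$background_hu, n, n)
  for (ins in scene$inserts) {
    rad <- ins$diameter_mm / 2
    margin <- rad + 3 * ins$psf_sigma_mm
    if (abs(ins$center_x_mm) + margin > half || abs(ins$center_y_mm) + margin > half) {
      stop("geometry error: insert extends outside the field")
    }
    prof <- blurred_disk_profile(rad, ins$psf_sigma_mm)
    rr <- sqrt(outer((y - ins$center_y_mm)^2, (x - ins$center_x_mm)^2, `+`))
    img <- img + ins$contrast_hu * prof(rr)
  }
  img
}

assemble_stack <- function(scene, noiseless) {
  n <- scene$image_size_pixels
  v <- array(0, dim = c(n, n, scene$n_slices))
  gen <- function() {
    for (k in seq_len(scene$n_slices)) {
      v[, , k] <<- noiseless + shaped_noise_field_(scene$noise, n, scene$pixel_spacing_mm)
    }
  }
  if (scene$noise$sigma_hu > 0) with_seed(scene$noise$seed, gen()) else {
    for (k in seq_len(scene$n_slices)) v[, , k] <- noiseless
  }
  meta <- utils::modifyList(list(
    sigma_hu = scene$noise$sigma_hu,
    noise_shape = scene$noise$shape,
    f0_mm_inv = scene$noise$f0_mm_inv,
    seed = scene$noise$seed,
    background_hu = scene$background_hu
  ), scene$meta)
  image_stack(v, pixel_spacing_x = scene$pixel_spacing_mm,
              pixel_spacing_y = scene$pixel_spacing_mm, meta = meta)
}

#' Generate a uniform phantom stack
#'
#' Emulates the uniform module of a QA phantom: each slice is the scene
#' background plus an independent shaped noise field. Ground-truth noise
#' parameters are recorded in the stack metadata.
#'
#' @param scene a [scene_spec()] without inserts.
#' @return An [image_stack()].
#' @export
generate_uniform_stack <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  if (length(scene$inserts)) stop("uniform scene must not contain inserts")
  n <- scene$image_size_pixels
  assemble_stack(scene, matrix(scene$background_hu, n, n))
}

#' Generate a phantom stack with circular inserts
#'
#' The noiseless scene is the background plus each insert's disk profile
#' convolved with its Gaussian PSF (computed analytically in the radial
#' coordinate and sampled at pixel centers); independent shaped noise is
#' then added per slice.
#'
#' @param scene a [scene_spec()].
#' @return An [image_stack()].
#' @export
generate_insert_stack <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  stk <- assemble_stack(scene, noiseless_scene_slice(scene))
  inserts <- scene$inserts
  names(inserts) <- vapply(seq_along(inserts), function(i) {
    lb <- inserts[[i]]$label
    if (is.null(lb)) paste0("insert_", i) else lb
  }, character(1))
  stk$meta$inserts <- inserts
  stk
}

#' Theoretical average spatial frequency of a noise model
#'
#' Computes `f_av = int(f * NPS(f) df) / int(NPS(f) df)` by numeric
#' quadrature of the model's radial spectrum truncated at the Nyquist
#' frequency. This is the analytic counterpart of [average_frequency()]
#' applied to a measured spectrum.
#'
#' @param noise a [noise_model()].
#' @param nyquist upper integration limit, 1/mm.
#' @return f_av in 1/mm.
#' @export
theoretical_fav <- function(noise, nyquist) {
  stopifnot(nyquist > 0)
  num <- stats::integrate(function(f) f * noise_psd_shape(noise, f), 0, nyquist,
                          rel.tol = 1e-9)$value
  den <- stats::integrate(function(f) noise_psd_shape(noise, f), 0, nyquist,
                          rel.tol = 1e-9)$value
  num / den
}
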