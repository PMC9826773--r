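#' Remove a second-order polynomial trend from an ROI patch
#'
#' Least-squares fit of `a0 + a1*x + a2*y + a3*x^2 + a4*x*y + a5*y^2`
#' (coordinates centered and scaled to \[-1, 1\] for conditioning),
#' subtracted from the patch. Removes DC, linear gradients and slow bowl
#' artifacts before periodogram estimation.
#'
#' @param patch 2D numeric matrix, at least 8x8.
#' @return Residual matrix of the same shape; sums to ~0.
#' @export
detrend_roi <- function(patch) {
  stopifnot(is.matrix(patch))
  if (nrow(patch) < 8 || ncol(patch) < 8) {
    stop("input error: patch must be at least 8x8")
  }
  ny <- nrow(patch); nx <- ncol(patch)
  x <- rep((seq_len(nx) - (nx + 1) / 2) / ((nx - 1) / 2), each = ny)
  y <- rep((seq_len(ny) - (ny + 1) / 2) / ((ny - 1) / 2), times = nx)
  X <- cbind(1, x, y, x^2, x * y, y^2)
  qrX <- qr(X)
  if (qrX$rank < 6L) stop("numerical error: rank-deficient quadratic fit")
  fit <- qr.fitted(qrX, as.vector(patch))
  patch - matrix(fit, ny, nx)
}

fftshift2 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  iy <- c(seq(ny %/% 2 + 1L, ny), seq_len(ny %/% 2))
  ix <- c(seq(nx %/% 2 + 1L, nx), seq_len(nx %/% 2))
  m[iy, ix]
}

shifted_freqs <- function(n, spacing) sort(fft_freqs(n, spacing))

#' Estimate the 2D noise power spectrum of a uniform stack
#'
#' Averages detrended periodograms over all (ROI x slice) instances:
#' `NPS2D = dx*dy / (Nx*Ny) * mean_i |FFT2(ROI_i - FIT_i)|^2`, where
#' `Nx`, `Ny` are the ROI side lengths in pixels and `FIT_i` is the
#' second-order polynomial fit of [detrend_roi()]. The grid is centered on
#' zero frequency.
#'
#' @param stack an [image_stack()] of a uniform region.
#' @param rois list of [square_roi()]s, all of the same side length.
#' @param slice_range integer vector of slice indices (default: all).
#' @return An object of class `nps_2d` with fields `values` (HU^2 mm^2),
#'   `freq_x`, `freq_y` (1/mm, ascending, centered on 0), `freq_step_x`,
#'   `freq_step_y`, and `n_instances`.
#' @export
compute_nps_2d <- function(stack, rois, slice_range = seq_len(n_slices(stack))) {
  stopifnot(inherits(stack, "image_stack"), length(rois) >= 1L)
  if (inherits(rois, "square_roi")) rois <- list(rois)
  sides <- vapply(rois, function(r) r$side_pixels, integer(1))
  if (length(unique(sides)) != 1L) stop("input error: ROIs must share one side length")
  stopifnot(all(slice_range >= 1), all(slice_range <= n_slices(stack)))
  if (length(rois) * length(slice_range) < 1L) stop("input error: no ROI instances")
  for (r in rois) check_square_roi_inside(stack, r)

  n <- sides[1]
  dx <- stack$pixel_spacing_x; dy <- stack$pixel_spacing_y
  acc <- matrix(0, n, n)
  count <- 0L
  for (k in slice_range) {
    sl <- stack$voxels[, , k]
    for (r in rois) {
      patch <- sl[roi_rows(r), roi_cols(r)]
      res <- detrend_roi(patch)
      acc <- acc + Mod(stats::fft(res))^2
      count <- count + 1L
    }
  }
  values <- fftshift2(acc / count) * (dx * dy) / (n * n)
  structure(list(values = values,
                 freq_x = shifted_freqs(n, dx),
                 freq_y = shifted_freqs(n, dy),
                 freq_step_x = 1 / (n * dx),
                 freq_step_y = 1 / (n * dy),
                 n_instances = count),
            class = "nps_2d")
}

#' Radially rebin a 2D NPS
#'
#' Each bin's value is the mean of 2D NPS samples whose radial frequency
#' falls in the bin; the zero-frequency sample goes to the first bin and
#' empty bins are dropped. Samples beyond `max_freq` (default: the axis
#' Nyquist, excluding corner frequencies) are excluded so that flat-spectrum
#' checks stay exact.
#'
#' @param nps2d an `nps_2d` from [compute_nps_2d()].
#' @param bin_width bin width in 1/mm; defaults to one 2D frequency step.
#' @param max_freq radial cutoff in 1/mm.
#' @return An object of class `nps_radial` with `freq` (the mean radial
#'   frequency of the samples in each bin), `values`, `counts`.
#' @export
radial_rebin <- function(nps2d, bin_width = nps2d$freq_step_x,
                         max_freq = min(max(nps2d$freq_x), max(nps2d$freq_y)) +
                           nps2d$freq_step_x / 2) {
  stopifnot(inherits(nps2d, "nps_2d"), bin_width > 0)
  fr <- sqrt(outer(nps2d$freq_y^2, nps2d$freq_x^2, `+`))
  keep <- fr <= max_freq
  fr <- fr[keep]; v <- nps2d$values[keep]
  idx <- pmax(floor(fr / bin_width), 0)
  agg_v <- tapply(v, idx, mean)
  agg_f <- tapply(fr, idx, mean)   # empirical bin frequency, not nominal center
  agg_n <- tapply(v, idx, length)
  bins <- as.numeric(names(agg_v))
  ord <- order(bins)
  structure(list(freq = as.numeric(agg_f[ord]),
                 values = as.numeric(agg_v[ord]),
                 counts = as.integer(agg_n[ord])),
            class = "nps_radial")
}

#' Noise magnitude implied by a 2D NPS
#'
#' The standard deviation (HU) of the detrended noise: the square root of
#' the discrete integral of the 2D NPS over frequency, `sqrt(sum(NPS) *
#' df_x * df_y)` (Parseval). This is the convention used by task-based
#' image-quality tools and is recorded as such in results.
#'
#' @param nps2d an `nps_2d`.
#' @return Noise magnitude in HU.
#' @export
noise_magnitude <- function(nps2d) {
  stopifnot(inherits(nps2d, "nps_2d"))
  sqrt(sum(nps2d$values) * nps2d$freq_step_x * nps2d$freq_step_y)
}

#' Average spatial frequency of a radial NPS
#'
#' `f_av = int(f * NPS(f) df) / int(NPS(f) df)` by trapezoidal quadrature
#' over the binned radial profile. A low f_av indicates a blotchy,
#' low-frequency noise texture.
#'
#' @param radial an `nps_radial` from [radial_rebin()].
#' @return f_av in 1/mm.
#' @export
average_frequency <- function(radial) {
  stopifnot(inherits(radial, "nps_radial"), length(radial$freq) >= 2L)
  if (all(radial$values == 0)) stop("undefined: all-zero radial NPS")
  trapz(radial$freq, radial$freq * radial$values) /
    trapz(radial$freq, radial$values)
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Full NPS analysis of a uniform stack
#'
#' Convenience wrapper: 2D NPS, radial rebinning, noise magnitude and
#' average spatial frequency in one result.
#'
#' @inheritParams compute_nps_2d
#' @inheritParams radial_rebin
#' @return An object of class `nps_result` with fields `nps2d`, `radial`,
#'   `noise_magnitude`, `f_av`, `n_rois_total`.
#' @export
compute_nps <- function(stack, rois, slice_range = seq_len(n_slices(stack)),
                        bin_width = NULL) {
  nps2d <- compute_nps_2d(stack, rois, slice_range)
  if (is.null(bin_width)) bin_width <- nps2d$freq_step_x
  radial <- radial_rebin(nps2d, bin_width)
  structure(list(nps2d = nps2d, radial = radial,
                 noise_magnitude = noise_magnitude(nps2d),
                 f_av = average_frequency(radial),
                 n_rois_total = nps2d$n_instances),
            class = "nps_result")
}

#' @export
print.nps_result <- function(x, ...) {
  cat(sprintf("<nps_result> noise magnitude %.3g HU, f_av %.4g 1/mm (%d ROI instances)\n",
              x$noise_magnitude, x$f_av, x$n_rois_total))
  invisible(x)
}

#' Default four-ROI layout for a uniform module
#'
#' Places four square ROIs north, south, east and west of the image
#' center, mirroring the usual uniform-module layout.
#'
#' @param stack an [image_stack()].
#' @param side_pixels ROI side length.
#' @param offset_pixels center-to-ROI-center distance; default puts the
#'   ROIs adjacent to the image center.
#' @return List of four [square_roi()]s.
#' @export
default_nps_rois <- function(stack, side_pixels = 128L,
                             offset_pixels = side_pixels %/% 2L + 2L) {
  d <- dim(stack$voxels)
  cr <- d[1] %/% 2L; cc <- d[2] %/% 2L
  list(
    square_roi(cr - offset_pixels, cc, side_pixels),
    square_roi(cr + offset_pixels, cc, side_pixels),
    square_roi(cr, cc - offset_pixels, side_pixels),
    square_roi(cr, cc + offset_pixels, side_pixels)
  )
}
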