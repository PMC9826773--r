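#' Image stack of CT slices in Hounsfield units
#'
#' The substrate of all measurements in this package: a 3D array of HU
#' values with its pixel geometry. Voxels are indexed `[row, col, slice]`
#' (row runs along y, col along x). Pixel centers sit at
#' `(index - 0.5) * spacing` so that pixel `[1, 1]` is centered half a pixel
#' from the image edge; all modules share this convention.
#'
#' @param voxels 3D numeric array `[row, col, slice]` of HU values, or a
#'   matrix for a single slice.
#' @param pixel_spacing_x,pixel_spacing_y pixel size in mm along x (columns)
#'   and y (rows); both must be positive.
#' @param slice_thickness,slice_increment slice geometry in mm.
#' @param meta named list of free-form provenance (energy_keV, recon_level,
#'   version_tag, seed, ...).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, pixel_spacing_x, pixel_spacing_y = pixel_spacing_x,
                        slice_thickness = 0.5, slice_increment = slice_thickness,
                        meta = list()) {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  if (!all(is.finite(voxels))) stop("HU values must be finite")
  if (!(is.numeric(pixel_spacing_x) && pixel_spacing_x > 0 &&
        is.numeric(pixel_spacing_y) && pixel_spacing_y > 0)) {
    stop("pixel spacings must be positive")
  }
  structure(list(
    voxels = voxels,
    pixel_spacing_x = as.numeric(pixel_spacing_x),
    pixel_spacing_y = as.numeric(pixel_spacing_y),
    slice_thickness = as.numeric(slice_thickness),
    slice_increment = as.numeric(slice_increment),
    meta = meta
  ), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d pixels, %d slice(s), %.4g x %.4g mm pixels\n",
              d[1], d[2], d[3], x$pixel_spacing_x, x$pixel_spacing_y))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

n_slices <- function(stack) dim(stack$voxels)[3]

#' Square region of interest
#'
#' An axis-aligned square patch of `side_pixels` x `side_pixels` pixels,
#' identified by its center pixel. The patch spans rows
#' `center_row - floor(side/2) + 1` through `center_row + ceiling(side/2)`
#' (likewise for columns), so for even sides the named center is the
#' lower-right pixel of the central 2x2 block.
#'
#' @param center_row,center_col integer pixel indices (1-based).
#' @param side_pixels integer side length in pixels, at least 2.
#' @return An object of class `square_roi`.
#' @export
square_roi <- function(center_row, center_col, side_pixels) {
  stopifnot(side_pixels >= 2, side_pixels == round(side_pixels),
            center_row == round(center_row), center_col == round(center_col))
  structure(list(center_row = as.integer(center_row),
                 center_col = as.integer(center_col),
                 side_pixels = as.integer(side_pixels)),
            class = "square_roi")
}

roi_rows <- function(roi) {
  r0 <- roi$center_row - roi$side_pixels %/% 2L + 1L
  r0:(r0 + roi$side_pixels - 1L)
}
roi_cols <- function(roi) {
  c0 <- roi$center_col - roi$side_pixels %/% 2L + 1L
  c0:(c0 + roi$side_pixels - 1L)
}

#' Circular region of interest
#'
#' @param center_row,center_col pixel coordinates of the center; fractional
#'   values are allowed.
#' @param radius_mm radius in mm; must be positive.
#' @return An object of class `circular_roi`.
#' @export
circular_roi <- function(center_row, center_col, radius_mm) {
  stopifnot(radius_mm > 0)
  structure(list(center_row = as.numeric(center_row),
                 center_col = as.numeric(center_col),
                 radius_mm = as.numeric(radius_mm)),
            class = "circular_roi")
}

check_square_roi_inside <- function(stack, roi) {
  d <- dim(stack$voxels)
  rr <- roi_rows(roi); cc <- roi_cols(roi)
  if (min(rr) < 1L || max(rr) > d[1] || min(cc) < 1L || max(cc) > d[2]) {
    stop("geometry error: square ROI extends outside the image")
  }
  invisible(TRUE)
}

check_circular_roi_inside <- function(stack, roi) {
  d <- dim(stack$voxels)
  rx <- roi$radius_mm / stack$pixel_spacing_x
  ry <- roi$radius_mm / stack$pixel_spacing_y
  if (roi$center_row - ry < 0 || roi$center_row + ry > d[1] ||
      roi$center_col - rx < 0 || roi$center_col + rx > d[2]) {
    stop("geometry error: circular ROI extends outside the image")
  }
  invisible(TRUE)
}

# Logical mask of pixels whose centers lie within radius_mm of the ROI center.
circular_mask <- function(stack, roi) {
  d <- dim(stack$voxels)
  dx <- (seq_len(d[2]) - roi$center_col) * stack$pixel_spacing_x
  dy <- (seq_len(d[1]) - roi$center_row) * stack$pixel_spacing_y
  outer(dy^2, dx^2, `+`) <= roi$radius_mm^2
}

#' Mean HU inside a circular ROI
#'
#' Arithmetic mean of HU over pixels whose centers lie within `radius_mm`
#' of the ROI center (pixel-center rule, no area weighting).
#'
#' @param stack an [image_stack()].
#' @param roi a [circular_roi()].
#' @param slice_index slice to measure (default: central slice).
#' @return Mean HU value (scalar).
#' @export
mean_hu <- function(stack, roi, slice_index = (n_slices(stack) + 1L) %/% 2L) {
  stopifnot(inherits(stack, "image_stack"), inherits(roi, "circular_roi"))
  check_circular_roi_inside(stack, roi)
  stopifnot(slice_index >= 1, slice_index <= n_slices(stack))
  m <- circular_mask(stack, roi)
  if (!any(m)) stop("geometry error: no pixel centers inside the ROI")
  mean(stack$voxels[, , slice_index][m])
}

# ---------------------------------------------------------------------------
# Native stack format: one binary voxel block (int16, little endian, written
# in R array order row-fastest within slice) plus a YAML sidecar header with
# dims, spacings, rescale slope/intercept and meta. HU = stored * slope +
# intercept; slope/intercept are chosen so the stored range fits int16, with
# slope 1 (round to nearest HU, max error 0.5 HU) whenever the HU range
# allows it.
# ---------------------------------------------------------------------------

native_paths <- function(path) {
  stem <- sub("\\.(yml|yaml|hdr)$", "", path)
  list(header = paste0(stem, ".yml"), raw = paste0(stem, ".raw"))
}

#' Write an image stack to disk
#'
#' @param stack an [image_stack()].
#' @param path destination. For `native_stack`, the path stem: `<stem>.yml`
#'   (text header) and `<stem>.raw` (int16 voxel block) are written. For
#'   `dicom_series`, a directory receiving one single-frame CT file per slice.
#' @param format `"native_stack"` or `"dicom_series"`.
#' @return Invisibly, the path written.
#' @seealso [read_stack()]
#' @export
write_stack <- function(stack, path, format = c("native_stack", "dicom_series")) {
  format <- match.arg(format)
  stopifnot(inherits(stack, "image_stack"))
  if (!all(is.finite(stack$voxels))) stop("validation error: non-finite HU values")
  if (format == "dicom_series") return(write_dicom_series(stack, path))

  p <- native_paths(path)
  v <- stack$voxels
  lo <- min(v); hi <- max(v)
  if (lo >= -32767 && hi <= 32767) {
    slope <- 1; intercept <- 0
  } else {
    intercept <- (hi + lo) / 2
    slope <- max((hi - lo) / 65534, .Machine$double.eps)
  }
  stored <- as.integer(round((v - intercept) / slope))
  hdr <- list(
    format = "ctiq_native_stack_v1",
    dims = as.integer(dim(v)),
    pixel_spacing_x = stack$pixel_spacing_x,
    pixel_spacing_y = stack$pixel_spacing_y,
    slice_thickness = stack$slice_thickness,
    slice_increment = stack$slice_increment,
    rescale_slope = slope,
    rescale_intercept = intercept,
    raw_file = basename(p$raw),
    meta = stack$meta
  )
  yaml::write_yaml(hdr, p$header)
  con <- file(p$raw, "wb")
  on.exit(close(con))
  writeBin(stored, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an image stack from disk
#'
#' For DICOM series, RescaleSlope/RescaleIntercept are applied to yield HU
#' and slices are sorted by position along the scan axis.
#'
#' @param path header file or stem (native) or directory of files (DICOM).
#' @param format `"native_stack"` or `"dicom_series"`.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, format = c("native_stack", "dicom_series")) {
  format <- match.arg(format)
  if (format == "dicom_series") return(read_dicom_series(path))

  p <- native_paths(path)
  if (!file.exists(p$header)) stop("I/O error: header file not found: ", p$header)
  hdr <- yaml::read_yaml(p$header)
  if (!identical(hdr$format, "ctiq_native_stack_v1")) {
    stop("format error: not a ctiq native stack header")
  }
  dims <- as.integer(hdr$dims)
  raw_path <- file.path(dirname(p$header), hdr$raw_file)
  if (!file.exists(raw_path)) stop("I/O error: raw voxel file not found: ", raw_path)
  n <- prod(dims)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  stored <- readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                    endian = "little")
  if (length(stored) != n) stop("format error: voxel block truncated")
  v <- array(stored * hdr$rescale_slope + hdr$rescale_intercept, dim = dims)
  image_stack(v,
              pixel_spacing_x = hdr$pixel_spacing_x,
              pixel_spacing_y = hdr$pixel_spacing_y,
              slice_thickness = hdr$slice_thickness,
              slice_increment = hdr$slice_increment,
              meta = if (is.null(hdr$meta)) list() else hdr$meta)
}
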