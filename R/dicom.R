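# Minimal DICOM codec for single-frame, uncompressed, little-endian CT
# slices: enough to round-trip the geometry and HU content this package
# needs (Rows/Columns, PixelSpacing, RescaleSlope/Intercept, slice position)
# and to ingest series exported by standard tools in Explicit or Implicit VR
# Little Endian. Compressed transfer syntaxes are out of scope.

uint16_bytes <- function(x) {
  x <- as.integer(x)
  as.raw(c(bitwAnd(x, 255L), bitwAnd(bitwShiftR(x, 8L), 255L)))
}
uint32_bytes <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

# One explicit-VR little-endian data element.
dcm_element <- function(group, element, vr, value) {
  if (vr %in% c("UI", "CS", "DS", "IS", "LO", "SH")) {
    bytes <- charToRaw(as.character(value))
    if (length(bytes) %% 2L == 1L) {
      pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
      bytes <- c(bytes, pad)
    }
  } else if (vr == "US") {
    bytes <- uint16_bytes(value)
  } else if (vr == "UL") {
    bytes <- uint32_bytes(value)
  } else if (vr == "OW") {
    bytes <- value  # already raw
  } else {
    stop("unsupported VR in writer: ", vr)
  }
  head <- c(uint16_bytes(group), uint16_bytes(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    head <- c(head, as.raw(c(0L, 0L)), uint32_bytes(length(bytes)))
  } else {
    head <- c(head, uint16_bytes(length(bytes)))
  }
  c(head, bytes)
}

dcm_ds <- function(x) {
  paste(vapply(x, function(v) sprintf("%.10g", v), character(1)), collapse = "\\")
}

write_dicom_slice <- function(mat, path, stack, index) {
  lo <- min(mat); hi <- max(mat)
  if (lo >= -32767 && hi <= 32767) {
    slope <- 1; intercept <- 0
  } else {
    intercept <- (hi + lo) / 2
    slope <- max((hi - lo) / 65534, .Machine$double.eps)
  }
  stored <- round((mat - intercept) / slope)
  # DICOM pixel order is row-major (leftmost pixel of the top row first)
  pix <- writeBin(as.integer(t(stored)), raw(), size = 2L, endian = "little")

  z <- (index - 1L) * stack$slice_increment
  uid_root <- "1.2.826.0.1.3680043.10.1457"
  sop_uid <- sprintf("%s.%d.%d", uid_root, as.integer(Sys.time()) %% 100000L, index)

  ds <- c(
    dcm_element(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    dcm_element(0x0008, 0x0018, "UI", sop_uid),
    dcm_element(0x0008, 0x0060, "CS", "CT"),
    dcm_element(0x0018, 0x0050, "DS", dcm_ds(stack$slice_thickness)),
    dcm_element(0x0018, 0x0088, "DS", dcm_ds(stack$slice_increment)),
    dcm_element(0x0020, 0x0013, "IS", as.character(index)),
    dcm_element(0x0020, 0x0032, "DS", dcm_ds(c(0, 0, z))),
    dcm_element(0x0028, 0x0002, "US", 1L),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0010, "US", nrow(mat)),
    dcm_element(0x0028, 0x0011, "US", ncol(mat)),
    dcm_element(0x0028, 0x0030, "DS", dcm_ds(c(stack$pixel_spacing_y, stack$pixel_spacing_x))),
    dcm_element(0x0028, 0x0100, "US", 16L),
    dcm_element(0x0028, 0x0101, "US", 16L),
    dcm_element(0x0028, 0x0102, "US", 15L),
    dcm_element(0x0028, 0x0103, "US", 1L),
    dcm_element(0x0028, 0x1052, "DS", dcm_ds(intercept)),
    dcm_element(0x0028, 0x1053, "DS", dcm_ds(slope)),
    dcm_element(0x7FE0, 0x0010, "OW", pix)
  )
  meta <- c(
    dcm_element(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    dcm_element(0x0002, 0x0003, "UI", sop_uid),
    dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", length(meta)), meta)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, ds), con)
  invisible(path)
}

write_dicom_series <- function(stack, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  nz <- dim(stack$voxels)[3]
  width <- max(4L, nchar(as.character(nz)))
  for (k in seq_len(nz)) {
    write_dicom_slice(stack$voxels[, , k],
                      file.path(path, sprintf(paste0("slice_%0", width, "d.dcm"), k)),
                      stack, k)
  }
  invisible(path)
}

# --- reader -----------------------------------------------------------------

rd_uint16 <- function(bytes, off) {
  as.integer(bytes[off + 1L]) + 256L * as.integer(bytes[off + 2L])
}
rd_uint32 <- function(bytes, off) {
  as.numeric(bytes[off + 1L]) + 256 * as.numeric(bytes[off + 2L]) +
    65536 * as.numeric(bytes[off + 3L]) + 16777216 * as.numeric(bytes[off + 4L])
}

long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

parse_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 140L || rawToChar(bytes[129:132]) != "DICM") {
    stop("format error: not a DICOM part-10 file: ", path)
  }
  off <- 132L
  explicit <- TRUE
  tsuid <- NULL
  tags <- list()
  while (off + 8L <= length(bytes)) {
    group <- rd_uint16(bytes, off)
    element <- rd_uint16(bytes, off + 2L)
    in_meta <- group == 2L
    use_explicit <- in_meta || explicit
    if (use_explicit) {
      vr <- rawToChar(bytes[(off + 5L):(off + 6L)])
      if (vr %in% long_vrs) {
        len <- rd_uint32(bytes, off + 8L)
        voff <- off + 12L
      } else if (grepl("^[A-Z]{2}$", vr)) {
        len <- rd_uint16(bytes, off + 6L)
        voff <- off + 8L
      } else {
        # implicit VR after all
        vr <- "UN"; len <- rd_uint32(bytes, off + 4L); voff <- off + 8L
      }
    } else {
      vr <- "UN"; len <- rd_uint32(bytes, off + 4L); voff <- off + 8L
    }
    if (len < 0 || voff + len > length(bytes)) {
      stop("format error: truncated DICOM element in ", path)
    }
    key <- sprintf("%04x,%04x", group, element)
    tags[[key]] <- bytes[seq.int(voff + 1L, length.out = len)]
    if (key == "0002,0010") {
      tsuid <- raw_to_string(tags[[key]])
      if (tsuid == "1.2.840.10008.1.2") explicit <- FALSE
      else if (tsuid != "1.2.840.10008.1.2.1") {
        stop("format error: unsupported transfer syntax ", tsuid)
      }
    }
    off <- voff + len
    if (key == "7fe0,0010") break
  }
  tags
}

raw_to_string <- function(v) sub("\\s+$", "", rawToChar(v[v != as.raw(0L)]))

tag_string <- function(tags, key) {
  v <- tags[[key]]
  if (is.null(v)) return(NULL)
  raw_to_string(v)
}
tag_numbers <- function(tags, key) {
  s <- tag_string(tags, key)
  if (is.null(s) || s == "") return(NULL)
  as.numeric(strsplit(s, "\\", fixed = TRUE)[[1]])
}
tag_uint16 <- function(tags, key) {
  v <- tags[[key]]
  if (is.null(v)) return(NULL)
  rd_uint16(v, 0L)
}

read_dicom_series <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, full.names = TRUE)
    files <- files[!dir.exists(files)]
  } else if (file.exists(path)) {
    files <- path
  } else {
    stop("I/O error: path not found: ", path)
  }
  parsed <- list()
  for (f in files) {
    ok <- tryCatch({
      b <- readBin(f, "raw", n = 132L)
      length(b) == 132L && rawToChar(b[129:132]) == "DICM"
    }, error = function(e) FALSE)
    if (ok) parsed[[length(parsed) + 1L]] <- parse_dicom_file(f)
  }
  if (length(parsed) == 0L) stop("format error: no readable DICOM slices in ", path)

  geom <- lapply(parsed, function(tg) {
    rows <- tag_uint16(tg, "0028,0010"); cols <- tag_uint16(tg, "0028,0011")
    spacing <- tag_numbers(tg, "0028,0030")
    if (is.null(spacing) || length(spacing) != 2L || any(!is.finite(spacing)) ||
        any(spacing <= 0)) {
      stop("geometry error: missing or invalid PixelSpacing")
    }
    if (is.null(rows) || is.null(cols)) stop("format error: missing Rows/Columns")
    list(rows = rows, cols = cols, spacing = spacing)
  })
  ref <- geom[[1]]
  for (g in geom) {
    if (g$rows != ref$rows || g$cols != ref$cols) {
      stop("format error: mixed image dimensions in series")
    }
    if (max(abs(g$spacing - ref$spacing)) > 1e-6) {
      stop("geometry error: inconsistent pixel spacing in series")
    }
  }

  zpos <- vapply(parsed, function(tg) {
    ipp <- tag_numbers(tg, "0020,0032")
    if (!is.null(ipp) && length(ipp) == 3L) return(ipp[3])
    inst <- tag_numbers(tg, "0020,0013")
    if (!is.null(inst)) return(inst[1])
    NA_real_
  }, numeric(1))
  ord <- order(zpos)
  parsed <- parsed[ord]; zpos <- zpos[ord]

  slices <- lapply(parsed, function(tg) {
    pix <- tg[["7fe0,0010"]]
    if (is.null(pix)) stop("format error: missing PixelData")
    signed <- isTRUE(tag_uint16(tg, "0028,0103") == 1L)
    stored <- readBin(pix, "integer", n = length(pix) %/% 2L, size = 2L,
                      signed = signed, endian = "little")
    slope <- tag_numbers(tg, "0028,1053"); if (is.null(slope)) slope <- 1
    icpt <- tag_numbers(tg, "0028,1052"); if (is.null(icpt)) icpt <- 0
    rows <- tag_uint16(tg, "0028,0010"); cols <- tag_uint16(tg, "0028,0011")
    # stored row-major -> fill by row
    matrix(stored * slope + icpt, nrow = rows, ncol = cols, byrow = TRUE)
  })
  v <- array(unlist(slices), dim = c(ref$rows, ref$cols, length(slices)))
  thick <- tag_numbers(parsed[[1]], "0018,0050")
  incr <- if (length(zpos) > 1L && all(is.finite(zpos))) {
    stats::median(diff(zpos))
  } else {
    tag_numbers(parsed[[1]], "0018,0088")
  }
  if (is.null(thick)) thick <- 0.5
  if (is.null(incr) || !is.finite(incr) || incr <= 0) incr <- thick
  image_stack(v,
              pixel_spacing_x = ref$spacing[2], pixel_spacing_y = ref$spacing[1],
              slice_thickness = thick, slice_increment = incr,
              meta = list(source = path, n_files = length(parsed)))
}
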