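#' Default noise-texture parameters of the study emulation
#'
#' The published study reports its noise texture only through average-NPS-
#' frequency trends (no raw images are deposited), so the `ramp_gauss`
#' scale parameter `f0` per (version, level, keV) is a package choice,
#' fixed once to reproduce those trends qualitatively: f_av decreases as
#' the reconstruction level increases; the newer algorithm version (V2)
#' has a higher f_av than V1 at the same level (about +25-40% at 40-50
#' keV); V2's f_av falls by roughly a quarter from 40 to 60 keV while V1's
#' is nearly flat; both rise slightly at 70 keV.
#'
#' @return data.frame with columns `version`, `level`, `keV`, `f0_mm_inv`.
#' @export
default_texture_table <- function() {
  base <- c(V1.mild = 0.16, V1.standard = 0.13, V1.strong = 0.105,
            V2.mild = 0.205, V2.standard = 0.15, V2.strong = 0.135)
  fac <- list(V1 = c("40" = 1.00, "50" = 0.97, "60" = 0.89, "70" = 0.92),
              V2 = c("40" = 1.10, "50" = 1.00, "60" = 0.82, "70" = 0.84))
  grid <- expand.grid(version = c("V1", "V2"),
                      level = c("mild", "standard", "strong"),
                      keV = c(40, 50, 60, 70),
                      stringsAsFactors = FALSE)
  grid$f0_mm_inv <- base[paste(grid$version, grid$level, sep = ".")] *
    vapply(seq_len(nrow(grid)),
           function(i) fac[[grid$version[i]]][as.character(grid$keV[i])],
           numeric(1))
  rownames(grid) <- NULL
  grid
}

#' Default edge-blur parameters of the study emulation
#'
#' The insert edge blur per (version, level, keV) is set from the
#' published TTF50 values (interpolated across keV where only endpoints
#' are printed) through the Gaussian closed form
#' `sigma_b = sqrt(log(2) / (2 pi^2)) / TTF50`.
#'
#' @return data.frame with columns `version`, `level`, `keV`,
#'   `ttf50_mm_inv`, `psf_sigma_mm`.
#' @export
default_ttf50_table <- function() {
  vals <- rbind(
    data.frame(version = "V1", level = "mild",     keV = c(40, 50, 60, 70),
               ttf50_mm_inv = c(0.300, 0.293, 0.287, 0.280)),
    data.frame(version = "V1", level = "standard", keV = c(40, 50, 60, 70),
               ttf50_mm_inv = c(0.290, 0.277, 0.263, 0.250)),
    data.frame(version = "V1", level = "strong",   keV = c(40, 50, 60, 70),
               ttf50_mm_inv = c(0.220, 0.230, 0.220, 0.210)),
    data.frame(version = "V2", level = "mild",     keV = c(40, 50, 60, 70),
               ttf50_mm_inv = c(0.510, 0.487, 0.463, 0.440)),
    data.frame(version = "V2", level = "standard", keV = c(40, 50, 60, 70),
               ttf50_mm_inv = c(0.350, 0.333, 0.317, 0.300)),
    data.frame(version = "V2", level = "strong",   keV = c(40, 50, 60, 70),
               ttf50_mm_inv = c(0.270, 0.270, 0.270, 0.300))
  )
  vals$psf_sigma_mm <- sigma_b_from_ttf50(vals$ttf50_mm_inv)
  vals
}

#' Convert between Gaussian edge blur and TTF50
#'
#' For a Gaussian transfer function `exp(-2 pi^2 sigma^2 f^2)`,
#' `TTF50 = sqrt(log(2) / (2 pi^2 sigma^2))`; the relation is its own
#' inverse up to the constant.
#'
#' @param ttf50_mm_inv TTF50 in 1/mm.
#' @param sigma_mm blur SD in mm.
#' @return The corresponding blur SD (or TTF50).
#' @export
sigma_b_from_ttf50 <- function(ttf50_mm_inv) {
  sqrt(log(2) / (2 * pi^2)) / ttf50_mm_inv
}

#' @rdname sigma_b_from_ttf50
#' @export
ttf50_from_sigma_b <- function(sigma_mm) {
  sqrt(log(2) / (2 * pi^2)) / sigma_mm
}

lookup_row <- function(df, version, level, keV) {
  i <- which(df$version == version & df$level == level & df$keV == keV)
  if (length(i) != 1L) {
    stop("configuration error: no parameters for (", version, ", ", level,
         ", ", keV, " keV)")
  }
  df[i, , drop = FALSE]
}

#' Generate the full synthetic study
#'
#' For every requested (version, level, keV, replicate) the generator
#' produces: a uniform ACR-like stack whose noise magnitude targets the
#' published noise table and whose texture follows
#' [default_texture_table()]; an acrylic-like insert stack (25 mm diameter,
#' contrast rising toward low keV as acrylic does on virtual monoenergetic
#' images) with edge blur from [default_ttf50_table()] for TTF estimation;
#' and a
#' multi-energy stack with a solid-water insert and three iodine inserts
#' whose contrasts target the published contrast table. Defaults mirror
#' the study geometry (512 matrix, 0.488 mm ACR pixels / 0.82 mm
#' multi-energy pixels, 40 NPS slices, 20 TTF slices); smaller sizes can
#' be requested for quick runs.
#'
#' @param versions,levels,kevs study conditions to generate.
#' @param replicates number of repeat acquisitions per condition.
#' @param seed_base integer; replicate r of condition i uses a seed derived
#'   deterministically from `seed_base`, i and r.
#' @param table1,table2,texture,ttf50 parameter tables (defaults: the
#'   shipped study tables and package defaults).
#' @param components subset of `c("uniform", "acrylic", "multienergy")`.
#' @param acrylic_contrast named vector of acrylic insert contrast (HU)
#'   per keV.
#' @param uniform_size,uniform_slices,acrylic_size,acrylic_slices,me_size,me_slices
#'   geometry of the three scene types.
#' @param acr_pixel_mm,me_pixel_mm pixel sizes (250 mm / 420 mm FOV on a
#'   512 matrix).
#' @return List of entries keyed `"version|level|keV|replicate"`, each with
#'   the condition labels, the ground-truth parameters, and the generated
#'   stacks.
#' @export
generate_study <- function(versions = c("V1", "V2"),
                           levels = c("mild", "standard", "strong"),
                           kevs = c(40, 50, 60, 70),
                           replicates = 3L, seed_base = 20230109L,
                           table1 = study_contrast_table(),
                           table2 = study_noise_table(),
                           texture = default_texture_table(),
                           ttf50 = default_ttf50_table(),
                           components = c("uniform", "acrylic", "multienergy"),
                           acrylic_contrast = c("40" = 220, "50" = 170,
                                                "60" = 140, "70" = 120),
                           uniform_size = 512L, uniform_slices = 40L,
                           acrylic_size = 512L, acrylic_slices = 20L,
                           me_size = 512L, me_slices = 3L,
                           acr_pixel_mm = 250 / 512, me_pixel_mm = 420 / 512) {
  components <- match.arg(components, several.ok = TRUE)
  out <- list()
  idx <- 0L
  for (ver in versions) for (lv in levels) for (kv in kevs) {
    sigma <- noise_at(table2, ver, kv, lv)
    if (length(sigma) != 1L) stop("configuration error: no noise entry for (",
                                  ver, ", ", lv, ", ", kv, " keV)")
    f0 <- lookup_row(texture, ver, lv, kv)$f0_mm_inv
    sb <- lookup_row(ttf50, ver, lv, kv)$psf_sigma_mm
    concs <- c(2, 1, 0.5)
    ctr <- vapply(concs, function(cc) {
      v <- contrast_at(table1, cc, kv, ver, lv)
      if (length(v) != 1L) stop("configuration error: no contrast entry for ",
                                cc, " mg/mL (", ver, ", ", lv, ", ", kv, " keV)")
      v
    }, numeric(1))
    for (r in seq_len(replicates)) {
      idx <- idx + 1L
      key <- paste(ver, lv, kv, r, sep = "|")
      seed0 <- (seed_base + 7919 * idx) %% 2147483629L
      meta <- list(version_tag = ver, recon_level = lv, energy_keV = kv,
                   replicate = r)
      entry <- list(version = ver, level = lv, keV = kv, replicate = r,
                    sigma_hu = sigma, f0_mm_inv = f0, psf_sigma_mm = sb,
                    contrasts_hu = stats::setNames(ctr, paste0("c", concs)))
      if ("uniform" %in% components) {
        entry$uniform <- generate_uniform_stack(scene_spec(
          uniform_size, acr_pixel_mm, uniform_slices, background_hu = 0,
          noise = noise_model(sigma, "ramp_gauss", f0, seed = seed0),
          meta = meta))
      }
      if ("acrylic" %in% components) {
        entry$acrylic <- generate_insert_stack(scene_spec(
          acrylic_size, acr_pixel_mm, acrylic_slices, background_hu = 0,
          inserts = list(insert_spec(0, 0, diameter_mm = 25,
                                     contrast_hu = acrylic_contrast[[as.character(kv)]],
                                     psf_sigma_mm = sb, label = "acrylic")),
          noise = noise_model(sigma, "ramp_gauss", f0, seed = seed0 + 1L),
          meta = meta))
      }
      if ("multienergy" %in% components) {
        half_span <- me_size * me_pixel_mm / 4
        pos <- list(c(-1, -1), c(1, -1), c(-1, 1), c(1, 1))
        labels <- c("solid_water", "iodine_2", "iodine_1", "iodine_0.5")
        contrasts <- c(0, ctr)
        inserts <- lapply(seq_along(labels), function(i) {
          insert_spec(pos[[i]][1] * half_span * 0.62, pos[[i]][2] * half_span * 0.62,
                      diameter_mm = 28, contrast_hu = contrasts[i],
                      psf_sigma_mm = sb, label = labels[i])
        })
        entry$multienergy <- generate_insert_stack(scene_spec(
          me_size, me_pixel_mm, me_slices, background_hu = 0,
          inserts = inserts,
          noise = noise_model(sigma, "ramp_gauss", f0, seed = seed0 + 2L),
          meta = meta))
      }
      out[[key]] <- entry
    }
  }
  out
}

#' Measure a generated study with the full analysis pipeline
#'
#' Runs the NPS analysis on each uniform stack, the circular-edge TTF
#' analysis on each acrylic stack, and the iodine contrast measurement
#' (2-cm ROI on each insert of the central slice) on each multi-energy
#' stack. Returns both a flat table of measurement records and the per-key
#' NPS/TTF result objects needed downstream by [study_dprime()].
#'
#' @param study output of [generate_study()].
#' @param nps_roi_side side of the four square NPS ROIs, pixels.
#' @param ttf_roi_radius_mm radius of the circular TTF analysis region.
#' @param contrast_roi_radius_mm radius of the contrast ROIs (2-cm
#'   diameter ROI by default).
#' @param smooth_esf smooth the ESF before differencing.
#' @return List with `records` (data.frame: version, level, keV,
#'   replicate, metric, concentration_mg_ml, value), `nps` and `ttf`
#'   (result objects keyed like the study).
#' @export
measure_study <- function(study, nps_roi_side = 128L, ttf_roi_radius_mm = 20,
                          contrast_roi_radius_mm = 10, smooth_esf = TRUE) {
  records <- list()
  nps_results <- list()
  ttf_results <- list()
  add <- function(entry, metric, value, conc = NA_real_) {
    if (!is.finite(value)) return(invisible(NULL))
    records[[length(records) + 1L]] <<- data.frame(
      version = entry$version, level = entry$level, keV = entry$keV,
      replicate = entry$replicate, metric = metric,
      concentration_mg_ml = conc, value = value)
  }
  for (key in names(study)) {
    entry <- study[[key]]
    if (!is.null(entry$uniform)) {
      res <- compute_nps(entry$uniform,
                         default_nps_rois(entry$uniform, nps_roi_side))
      nps_results[[key]] <- res
      add(entry, "noise_magnitude", res$noise_magnitude)
      add(entry, "f_av", res$f_av)
    }
    if (!is.null(entry$acrylic)) {
      d <- dim(entry$acrylic$voxels)
      roi <- circular_roi(d[1] / 2 + 0.5, d[2] / 2 + 0.5, ttf_roi_radius_mm)
      res <- compute_ttf(entry$acrylic, roi, smooth = smooth_esf)
      ttf_results[[key]] <- res
      add(entry, "ttf50", res$ttf50)
    }
    if (!is.null(entry$multienergy)) {
      st <- entry$multienergy
      centers <- scene_insert_centers(st)
      hu <- vapply(centers, function(cen) {
        mean_hu(st, circular_roi(cen[["row"]], cen[["col"]], contrast_roi_radius_mm))
      }, numeric(1))
      sw <- hu[["solid_water"]]
      for (cc in c(2, 1, 0.5)) {
        add(entry, "contrast", iodine_contrast(hu[[paste0("iodine_", cc)]], sw),
            conc = cc)
      }
    }
  }
  list(records = do.call(rbind, records), nps = nps_results, ttf = ttf_results)
}

# Pixel coordinates of the insert centers recorded in a generated
# multi-energy stack's metadata.
scene_insert_centers <- function(stack) {
  ins <- stack$meta$inserts
  if (is.null(ins)) stop("input error: stack carries no insert metadata")
  d <- dim(stack$voxels)
  lapply(ins, function(s) {
    c(row = (s$center_y_mm + d[1] * stack$pixel_spacing_y / 2) /
        stack$pixel_spacing_y + 0.5,
      col = (s$center_x_mm + d[2] * stack$pixel_spacing_x / 2) /
        stack$pixel_spacing_x + 0.5)
  })
}

#' NPWE detectability indices for a measured study
#'
#' For every study key and iodine concentration, computes the d' of a
#' 10-mm disk task whose contrast is the measured insert contrast for
#' that (concentration, keV, version, level) averaged over replicates,
#' using the replicate's measured TTF and NPS.
#'
#' @param measured output of [measure_study()].
#' @param task_diameter_mm lesion diameter.
#' @param display a [display_model()].
#' @param grid a [frequency_grid()]; defaults to the multi-energy pixel.
#' @param nps_exponent see [dprime_npwe()].
#' @return data.frame with columns version, level, keV, replicate,
#'   concentration_mg_ml, contrast_hu, d_prime.
#' @export
study_dprime <- function(measured, task_diameter_mm = 10,
                         display = display_model(),
                         grid = frequency_grid(420 / 512, 256L),
                         nps_exponent = 1) {
  rec <- measured$records
  ctr <- rec[rec$metric == "contrast", , drop = FALSE]
  mean_contrast <- stats::aggregate(
    value ~ version + level + keV + concentration_mg_ml, data = ctr, FUN = mean)
  rows <- list()
  for (key in names(measured$nps)) {
    if (is.null(measured$ttf[[key]])) next
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    ver <- parts[1]; lv <- parts[2]; kv <- as.numeric(parts[3]); r <- as.integer(parts[4])
    for (cc in unique(mean_contrast$concentration_mg_ml)) {
      ci <- mean_contrast$value[mean_contrast$version == ver &
                                mean_contrast$level == lv &
                                mean_contrast$keV == kv &
                                mean_contrast$concentration_mg_ml == cc]
      if (length(ci) != 1L) next
      task <- task_spec(task_diameter_mm, ci,
                        label = sprintf("%g mg/mL @ %g keV", cc, kv))
      dp <- dprime_npwe(task, measured$ttf[[key]], measured$nps[[key]],
                        display = display, grid = grid,
                        nps_exponent = nps_exponent)
      rows[[length(rows) + 1L]] <- data.frame(
        version = ver, level = lv, keV = kv, replicate = r,
        concentration_mg_ml = cc, contrast_hu = ci, d_prime = dp$d_prime)
    }
  }
  do.call(rbind, rows)
}
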