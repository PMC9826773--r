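#' Iodine contrast relative to solid water
#'
#' `Contrast = HU_iodine - HU_solid_water`.
#'
#' @param hu_iodine,hu_solid_water mean HU values measured in the iodine
#'   and solid-water insert ROIs.
#' @return Contrast in HU.
#' @export
iodine_contrast <- function(hu_iodine, hu_solid_water) {
  stopifnot(all(is.finite(hu_iodine)), all(is.finite(hu_solid_water)))
  hu_iodine - hu_solid_water
}

#' Signed percent difference
#'
#' `100 * (b - a) / a`: the percent change from the reference condition `a`
#' to the comparator `b` (the first-named condition is the denominator).
#'
#' @param a reference value(s); must be nonzero.
#' @param b comparator value(s).
#' @return Percent difference.
#' @export
percent_difference <- function(a, b) {
  if (any(a == 0)) stop("undefined: zero reference in percent difference")
  100 * (b - a) / a
}

#' Mean and sample standard deviation
#'
#' @param values numeric vector, length at least 1. For a single value the
#'   SD is reported as 0 by convention.
#' @return Named vector `c(mean, sd)`.
#' @export
aggregate_mean_sd <- function(values) {
  if (length(values) < 1L) stop("input error: empty value list")
  c(mean = mean(values), sd = if (length(values) < 2L) 0 else stats::sd(values))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired data. Zero differences are handled
#' by the Pratt method (ranked with the rest, then dropped). For up to 15
#' nonzero differences the null distribution is enumerated exactly
#' (conditional on the observed absolute differences, so ties are handled
#' exactly too); beyond that a normal approximation with tie and zero
#' corrections and continuity correction is used.
#'
#' @param x,y paired samples of equal length (at least 2).
#' @return Two-sided p-value. All-zero differences give p = 1 with a
#'   warning.
#' @export
wilcoxon_paired <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- y - x
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  r <- rank(abs(d))           # Pratt: zeros participate in ranking
  nz <- d != 0
  rk <- r[nz]                 # ...then their ranks are dropped
  w_obs <- sum(rk[d[nz] > 0])
  m <- sum(nz)
  if (m <= 15L) {
    sums <- 0
    for (ri in rk) sums <- c(sums, sums + ri)
    eps <- 1e-9
    p <- 2 * min(mean(sums <= w_obs + eps), mean(sums >= w_obs - eps))
    return(min(1, p))
  }
  n <- length(d); z <- n - m
  mu <- (n * (n + 1) / 2 - z * (z + 1) / 2) / 2
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - z * (z + 1) * (2 * z + 1) / 24
  ties <- table(r[nz])
  sigma2 <- sigma2 - sum(ties^3 - ties) / 48
  zstat <- (w_obs - mu - sign(w_obs - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(zstat)))
}

study_key_cols <- c("version", "level", "keV", "concentration_mg_ml", "replicate")

#' Build a table of paired comparisons from measurement records
#'
#' Records follow the study schema: columns `version`, `level`, `keV`,
#' `replicate`, `metric`, optional `concentration_mg_ml`, `value`. Each
#' plan entry names a metric, a variable to compare (with reference and
#' comparator values) and an optional filter; all remaining key columns
#' define the matched pairs. Percent differences are computed per matched
#' pair (reference as denominator), summarized as mean and SD, and tested
#' with [wilcoxon_paired()].
#'
#' @param records data.frame of measurement records.
#' @param plan list of entries `list(label =, metric =, compare =, ref =,
#'   cmp =, filter = list(...))`.
#' @return data.frame with one row per plan entry (`label`, `metric`,
#'   `contrast_pair`, `n_pairs`, `percent_diff_mean`, `percent_diff_sd`,
#'   `p_value`); pairs missing from the records are listed in the `gaps`
#'   attribute and their plan rows are skipped.
#' @export
build_comparison_table <- function(records, plan) {
  stopifnot(is.data.frame(records), all(c("metric", "value") %in% names(records)))
  if (!"concentration_mg_ml" %in% names(records)) records$concentration_mg_ml <- NA
  if (!"replicate" %in% names(records)) records$replicate <- 1L
  rows <- list(); gaps <- list()
  for (p in plan) {
    sub <- records[records$metric == p$metric, , drop = FALSE]
    for (f in names(p$filter)) sub <- sub[sub[[f]] %in% p$filter[[f]], , drop = FALSE]
    key_cols <- setdiff(study_key_cols, p$compare)
    key_cols <- key_cols[key_cols %in% names(sub)]
    ref <- sub[sub[[p$compare]] == p$ref, , drop = FALSE]
    cmp <- sub[sub[[p$compare]] == p$cmp, , drop = FALSE]
    key_of <- function(df) do.call(paste, c(df[key_cols], sep = "|"))
    ref_keys <- key_of(ref); cmp_keys <- key_of(cmp)
    common <- intersect(ref_keys, cmp_keys)
    missing <- union(setdiff(ref_keys, cmp_keys), setdiff(cmp_keys, ref_keys))
    if (length(missing)) {
      gaps[[length(gaps) + 1L]] <- data.frame(label = p$label, missing = missing)
    }
    if (length(common) == 0L) next
    a <- ref$value[match(common, ref_keys)]
    b <- cmp$value[match(common, cmp_keys)]
    pd <- percent_difference(a, b)
    ms <- aggregate_mean_sd(pd)
    pv <- if (length(common) >= 2L) wilcoxon_paired(a, b) else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      label = p$label, metric = p$metric,
      contrast_pair = paste(p$cmp, "vs", p$ref),
      n_pairs = length(common),
      percent_diff_mean = ms[["mean"]], percent_diff_sd = ms[["sd"]],
      p_value = pv
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(), metric = character(), contrast_pair = character(),
               n_pairs = integer(), percent_diff_mean = numeric(),
               percent_diff_sd = numeric(), p_value = numeric())
  attr(out, "gaps") <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(label = character(), missing = character())
  out
}
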