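# Tidal recruitment, intratidal aeration-category mass changes and
# vertical (iso-gravitational) ROI analysis. ROI 1 is the most dorsal slab,
# ROI n the most ventral, matching the supine gravitational axis (+y).

#' Vertical iso-gravitational ROI partition
#'
#' Splits the mask's dorso-ventral (y) extent into `n` contiguous slabs of
#' equal height; when the extent does not divide evenly, remainder rows are
#' assigned one per slab starting from the most dorsal slab. ROI 1 is the
#' most dorsal, ROI `n` the most ventral.
#'
#' @param mask A [lung_mask()].
#' @param n Number of ROIs (default 10).
#' @return A list of class `roi_partition` with `slabs` (data frame: roi,
#'   y_lo, y_hi voxel rows, height) and `masks` (list of logical arrays).
#' @export
vertical_rois <- function(mask, n = 10L) {
  stopifnot(inherits(mask, "lung_mask"), n >= 1L)
  n <- as.integer(n)
  rows <- which(apply(mask$data, 2, any))
  y_min <- min(rows); y_max <- max(rows)
  h_total <- y_max - y_min + 1L
  if (n > h_total)
    stop(sprintf("n = %d exceeds the mask's y-extent of %d rows", n, h_total))
  base <- h_total %/% n
  rem <- h_total %% n
  heights <- rep(base, n) + c(rep(1L, rem), rep(0L, n - rem))
  # ROI 1 occupies the dorsal-most (highest y) rows
  y_hi <- y_max - c(0L, cumsum(heights))[seq_len(n)]
  y_lo <- y_hi - heights + 1L
  slabs <- data.frame(roi = seq_len(n), y_lo = y_lo, y_hi = y_hi,
                      height = heights)
  masks <- lapply(seq_len(n), function(k) {
    m <- array(FALSE, dim = dim(mask$data))
    m[, y_lo[k]:y_hi[k], ] <- mask$data[, y_lo[k]:y_hi[k], ]
    m
  })
  structure(list(slabs = slabs, masks = masks, spacing = mask$spacing),
            class = "roi_partition")
}

#' Whole-lung tidal recruitment
#'
#' The difference between end-expiratory and end-inspiratory whole-lung
#' non-aerated mass divided by the whole-lung (end-expiratory) mass.
#'
#' @param masses_ee,masses_ei [mass_summary()] results for the
#'   end-expiratory and end-inspiratory images of the same subject.
#' @param denominator `"ee"` (default) uses the end-expiratory total mass;
#'   `"mean"` the mean of the two phases.
#' @return Scalar fraction of lung mass (positive = recruitment).
#' @export
tidal_recruitment <- function(masses_ee, masses_ei,
                              denominator = c("ee", "mean")) {
  denominator <- match.arg(denominator)
  m_tot <- switch(denominator,
                  ee = masses_ee$total_mass_g,
                  mean = (masses_ee$total_mass_g + masses_ei$total_mass_g) / 2)
  if (m_tot <= 0) stop("zero total lung mass")
  unname((masses_ee$mass_g["non"] - masses_ei$mass_g["non"]) / m_tot)
}

#' Regional (per-ROI) tidal recruitment
#'
#' Computes, for each iso-gravitational ROI, the non-aerated mass change
#' from end-expiration to end-inspiration divided by the ROI's
#' end-expiratory mass (`denominator = "roi"`, default) or by the whole-lung
#' end-expiratory mass (`"whole"`). The partitions are computed
#' independently on each image's own mask (the two lungs differ in extent).
#'
#' @param fgas_ee,fgas_ei [aeration_map()]s of the two phases.
#' @param mask_ee,mask_ei Matching [lung_mask()]s.
#' @param n Number of ROIs.
#' @param denominator `"roi"` or `"whole"`.
#' @return Data frame with roi, mass_ee_g, non_ee_g, non_ei_g, recruitment.
#' @export
regional_recruitment <- function(fgas_ee, fgas_ei, mask_ee, mask_ei,
                                 n = 10L, denominator = c("roi", "whole")) {
  denominator <- match.arg(denominator)
  part_ee <- vertical_rois(mask_ee, n)
  part_ei <- vertical_rois(mask_ei, n)
  sum_roi <- function(fgas, masks) {
    vox <- prod(fgas$spacing) / 1000
    t(vapply(masks, function(m) {
      f <- fgas$data[m & !is.na(fgas$data)]
      c(mass = sum(1 - f) * vox, non = sum((1 - f)[f < 0.1]) * vox)
    }, numeric(2)))
  }
  ee <- sum_roi(fgas_ee, part_ee$masks)
  ei <- sum_roi(fgas_ei, part_ei$masks)
  den <- switch(denominator, roi = ee[, "mass"], whole = sum(ee[, "mass"]))
  data.frame(roi = seq_len(n),
             mass_ee_g = ee[, "mass"],
             non_ee_g = ee[, "non"],
             non_ei_g = ei[, "non"],
             recruitment = (ee[, "non"] - ei[, "non"]) / den)
}

#' Intratidal aeration-category mass changes
#'
#' Per aeration category: end-expiratory mass, end-inspiratory mass and the
#' change (end-inspiration minus end-expiration) in grams and as percent of
#' the end-expiratory total lung mass.
#'
#' @param masses_ee,masses_ei [mass_summary()] results of the two phases.
#' @return Data frame with category, mass_ee_g, mass_ei_g, delta_g,
#'   delta_pct.
#' @export
intratidal_change <- function(masses_ee, masses_ei) {
  data.frame(category = .AERATION_LEVELS,
             mass_ee_g = unname(masses_ee$mass_g),
             mass_ei_g = unname(masses_ei$mass_g),
             delta_g = unname(masses_ei$mass_g - masses_ee$mass_g),
             delta_pct = unname(100 * (masses_ei$mass_g - masses_ee$mass_g) /
                                  masses_ee$total_mass_g))
}

#' Per-ROI aeration (and strain) profile
#'
#' Mean and 95th percentile gas fraction per iso-gravitational ROI and,
#' when a strain map is supplied, mean, 95th percentile and median strain.
#' Empty ROI rows are flagged with NA.
#'
#' @param partition A [vertical_rois()] partition.
#' @param fgas An [aeration_map()] on the partition geometry.
#' @param strain Optional [strain_map()].
#' @return Data frame with roi, n, mean_fgas, p95_fgas (+ mean_strain,
#'   p95_strain, median_strain).
#' @export
roi_profile <- function(partition, fgas, strain = NULL) {
  stopifnot(inherits(partition, "roi_partition"))
  out <- lapply(seq_along(partition$masks), function(k) {
    m <- partition$masks[[k]]
    f <- fgas$data[m & !is.na(fgas$data)]
    row <- data.frame(roi = k, n = length(f),
                      mean_fgas = if (length(f)) mean(f) else NA_real_,
                      p95_fgas = if (length(f))
                        unname(stats::quantile(f, 0.95, type = 7))
                      else NA_real_)
    if (!is.null(strain)) {
      s <- strain$data[m & !is.na(strain$data)]
      row$mean_strain <- if (length(s)) mean(s) else NA_real_
      row$p95_strain <- if (length(s))
        unname(stats::quantile(s, 0.95, type = 7)) else NA_real_
      row$median_strain <- if (length(s)) stats::median(s) else NA_real_
    }
    row
  })
  do.call(rbind, out)
}
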