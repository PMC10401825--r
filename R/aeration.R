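# Aeration densitometry: HU -> gas fraction, aeration categories, mass
# fractions, gas volume (EELV at end-expiration), percentiles and spatial
# heterogeneity.

.AERATION_LEVELS <- c("non", "poor", "normal", "hyper")

#' Convert Hounsfield units to voxel gas fraction
#'
#' F_gas = HU / -1000, with air = -1000 HU (F_gas = 1) and tissue = 0 HU
#' (F_gas = 0). HU are clamped to `[-1000, 0]` first so residual dense or
#' very lucent voxels inside the mask stay within the defined range.
#'
#' @param vol A [ct_volume()].
#' @param mask A [lung_mask()] on the same geometry.
#' @return An [aeration_map()] (NA outside the mask).
#' @export
hu_to_fgas <- function(vol, mask) {
  .stop_geometry(vol, mask, "volume and mask")
  hu <- pmin(pmax(vol$data, -1000), 0)
  f <- hu / -1000
  f[!mask$data] <- NA_real_
  aeration_map(f, vol$spacing)
}

#' Classify voxels into aeration categories
#'
#' Non-aerated F_gas < 0.1; poorly aerated 0.1 <= F_gas < 0.5; normally
#' aerated 0.5 <= F_gas < 0.9; hyper-aerated F_gas >= 0.9. Bounds are
#' half-open with each boundary belonging to the higher category.
#'
#' @param fgas An [aeration_map()].
#' @return Integer array (1 = non, ..., 4 = hyper; NA outside the mask)
#'   with attribute `levels`.
#' @export
classify_aeration <- function(fgas) {
  f <- fgas$data
  cat <- array(NA_integer_, dim = dim(f))
  ok <- !is.na(f)
  cat[ok] <- 1L + (f[ok] >= 0.1) + (f[ok] >= 0.5) + (f[ok] >= 0.9)
  attr(cat, "levels") <- .AERATION_LEVELS
  cat
}

#' Aeration category masses, total mass and gas volume
#'
#' Per-voxel tissue mass is (1 - F_gas) x voxel volume x 1 g/ml
#' (water-equivalent tissue density). Category masses are reported in grams
#' and as percent of total lung mass; total gas volume (ml) equals the
#' end-expiratory lung volume when applied to the end-expiratory image.
#'
#' @param fgas An [aeration_map()].
#' @param mask Optional [lung_mask()]; defaults to the map's non-NA voxels.
#' @return A list of class `aeration_masses` with `mass_g` (named, per
#'   category), `percent`, `total_mass_g`, `gas_volume_ml`, `voxel_ml`.
#' @export
mass_summary <- function(fgas, mask = NULL) {
  f <- fgas$data
  sel <- if (is.null(mask)) !is.na(f) else {
    .stop_geometry(fgas, mask, "map and mask")
    mask$data & !is.na(f)
  }
  if (!any(sel)) stop("empty mask")
  voxel_ml <- prod(fgas$spacing) / 1000
  fv <- f[sel]
  cat <- 1L + (fv >= 0.1) + (fv >= 0.5) + (fv >= 0.9)
  tissue <- (1 - fv) * voxel_ml            # grams at 1 g/ml
  mass <- vapply(1:4, function(k) sum(tissue[cat == k]), numeric(1))
  names(mass) <- .AERATION_LEVELS
  total <- sum(mass)
  structure(list(mass_g = mass,
                 percent = 100 * mass / total,
                 total_mass_g = total,
                 gas_volume_ml = sum(fv) * voxel_ml,
                 voxel_ml = voxel_ml),
            class = "aeration_masses")
}

#' Spatial heterogeneity (coefficient of variation)
#'
#' Normalized variance of aeration or strain, equivalent to the coefficient
#' of variation: in-mask SD divided by in-mask mean after in-plane Gaussian
#' filtering to an effective in-plane resolution equal to the slice
#' thickness. The added in-plane FWHM is `sqrt(fwhm_mm^2 - d^2)` for native
#' in-plane spacing d (no through-plane smoothing); smoothing is
#' mask-normalized so values outside the lung do not bleed in.
#'
#' @param map An [aeration_map()] or [strain_map()].
#' @param mask A [lung_mask()] on the same geometry.
#' @param fwhm_mm Target effective in-plane resolution (mm); default 2.5.
#' @return A list of class `heterogeneity_result` with `cov`, `mean`, `sd`
#'   and `fwhm_mm`.
#' @export
heterogeneity <- function(map, mask, fwhm_mm = 2.5) {
  .stop_geometry(map, mask, "map and mask")
  m <- mask$data & !is.na(map$data)
  if (!any(m)) stop("empty mask")
  kernels <- lapply(1:3, function(ax) {
    d <- map$spacing[ax]
    if (ax == 3L || d >= fwhm_mm) return(NULL)
    add_fwhm <- sqrt(fwhm_mm^2 - d^2)
    .gauss_kernel(add_fwhm / 2.3548 / d)
  })
  sm <- .smooth_masked(map$data, m, kernels)
  v <- sm[m]
  mu <- mean(v)
  if (abs(mu) < 1e-12)
    stop("coefficient of variation undefined: in-mask mean is zero")
  structure(list(cov = stats::sd(v) / mu, mean = mu, sd = stats::sd(v),
                 fwhm_mm = fwhm_mm),
            class = "heterogeneity_result")
}

#' 95th percentile of in-mask voxel values
#'
#' Linear interpolation between closest order statistics (the default
#' sample-quantile definition), stated so results are bit-reproducible.
#'
#' @param map An [aeration_map()] or [strain_map()] (or any `lung_grid`).
#' @param mask Optional [lung_mask()]; defaults to the map's non-NA voxels.
#' @param p Probability; default 0.95.
#' @return Scalar percentile.
#' @export
percentile95 <- function(map, mask = NULL, p = 0.95) {
  v <- if (is.null(mask)) map$data[!is.na(map$data)] else {
    .stop_geometry(map, mask, "map and mask")
    map$data[mask$data & !is.na(map$data)]
  }
  if (!length(v)) stop("empty mask")
  unname(stats::quantile(v, p, type = 7))
}
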