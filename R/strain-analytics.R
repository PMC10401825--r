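# Whole-lung and conditional strain statistics, strain-aeration joint
# structure, and strain-colored parametric response maps. All maps live on
# the end-expiratory grid; end-inspiratory aeration is pulled back to that
# grid with the registration transform.

#' Whole-lung strain summary
#'
#' In-mask mean, 95th percentile (linear-interpolation order statistic) and
#' coefficient of variation normalized by the global mean strain.
#'
#' @param strain A [strain_map()].
#' @param mask Optional [lung_mask()]; defaults to the map's non-NA voxels.
#' @return A list with `mean`, `p95`, `cov` (NA with a warning when the mean
#'   strain is zero), `n`.
#' @export
strain_summary <- function(strain, mask = NULL) {
  v <- if (is.null(mask)) strain$data[!is.na(strain$data)] else {
    .stop_geometry(strain, mask, "strain and mask")
    strain$data[mask$data & !is.na(strain$data)]
  }
  if (!length(v)) stop("empty mask")
  mu <- mean(v)
  cov <- if (abs(mu) < 1e-12) {
    warning("mean strain is zero: coefficient of variation undefined")
    NA_real_
  } else stats::sd(v) / mu
  list(mean = mu, p95 = unname(stats::quantile(v, 0.95, type = 7)),
       cov = cov, n = length(v))
}

#' Regional median strain
#'
#' The strain of a lung region is the median volumetric strain of the
#' voxels within the regional mask.
#'
#' @param strain A [strain_map()].
#' @param region A [lung_mask()] (or logical array) selecting the region.
#' @return Scalar median strain.
#' @export
regional_strain <- function(strain, region) {
  r <- if (inherits(region, "lung_mask")) {
    .stop_geometry(strain, region, "strain and region")
    region$data
  } else region
  v <- strain$data[r & !is.na(strain$data)]
  if (!length(v)) stop("empty region")
  stats::median(v)
}

#' Pull end-inspiratory aeration back to the end-expiratory grid
#'
#' Value at end-expiratory voxel x is the linear interpolation of the
#' end-inspiratory gas fraction at T(x) = x + u(x). Gas fraction outside the
#' end-inspiratory mask is taken as 0 (non-aerated tissue) for
#' interpolation. Points mapped outside the grid take the nearest-edge value
#' and are counted with a warning.
#'
#' @param fgas_ei End-inspiratory [aeration_map()].
#' @param field [displacement_field()] on the end-expiratory grid.
#' @param mask_ee Optional end-expiratory [lung_mask()] restricting the
#'   output (NA elsewhere).
#' @return An [aeration_map()] on the end-expiratory grid.
#' @export
ei_aeration_on_ee_grid <- function(fgas_ei, field, mask_ee = NULL) {
  .stop_geometry(fgas_ei, field, "EI aeration and field")
  if (!is.null(mask_ee)) .stop_geometry(fgas_ei, mask_ee, "map and mask")
  d <- .grid_dim(fgas_ei)
  sp <- fgas_ei$spacing
  f <- fgas_ei$data
  f[is.na(f)] <- 0
  ix <- array(rep(seq_len(d[1]), times = d[2] * d[3]), dim = d)
  iy <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), dim = d)
  iz <- array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d)
  xi <- ix + field$data[, , , 1] / sp[1]
  yi <- iy + field$data[, , , 2] / sp[2]
  zi <- iz + field$data[, , , 3] / sp[3]
  out_of_grid <- xi < 1 | xi > d[1] | yi < 1 | yi > d[2] | zi < 1 | zi > d[3]
  if (!is.null(mask_ee)) out_of_grid <- out_of_grid & mask_ee$data
  n_out <- sum(out_of_grid)
  if (n_out > 0)
    warning(sprintf(
      "%d voxels mapped outside the EI grid; nearest-edge values used",
      n_out))
  out <- array(.interp3(f, xi, yi, zi), dim = d)
  if (!is.null(mask_ee)) out[!mask_ee$data] <- NA_real_
  aeration_map(out, sp)
}

.AERATION_INTERVALS <- data.frame(
  interval = c("0.1-0.3", "0.3-0.5", "0.5-0.7", "0.7-0.9", ">0.9"),
  lo = c(0.1, 0.3, 0.5, 0.7, 0.9),
  hi = c(0.3, 0.5, 0.7, 0.9, Inf))

#' Joint strain-aeration structure in aerated lung
#'
#' For voxels in aerated lung (end-inspiratory F_gas > 0.1), summarizes the
#' strain distribution in the aeration intervals 0.1-0.3, 0.3-0.5, 0.5-0.7,
#' 0.7-0.9 and > 0.9 (median, interquartile range, count, mean aeration),
#' and builds a 2-D histogram (50 strain bins spanning the 5th-95th strain
#' percentile range x the 5 aeration intervals) of the fraction of aerated
#' lung volume.
#'
#' @param strain [strain_map()] on the end-expiratory grid.
#' @param fgas_ei_on_ee End-inspiratory aeration pulled back to the
#'   end-expiratory grid ([ei_aeration_on_ee_grid()]).
#' @param mask [lung_mask()] on the end-expiratory grid.
#' @param n_strain_bins Number of strain bins of the 2-D histogram.
#' @return A list of class `strain_aeration_joint` with `intervals` (data
#'   frame: interval, n, median, q25, q75, mean_fgas), `hist2d` (matrix
#'   strain bins x intervals, volume fractions), `strain_breaks`,
#'   `n_aerated`.
#' @export
strain_vs_aeration <- function(strain, fgas_ei_on_ee, mask,
                               n_strain_bins = 50L) {
  .stop_geometry(strain, fgas_ei_on_ee, "strain and aeration")
  .stop_geometry(strain, mask, "strain and mask")
  sel <- mask$data & !is.na(strain$data) & !is.na(fgas_ei_on_ee$data) &
    fgas_ei_on_ee$data > 0.1
  s <- strain$data[sel]
  f <- fgas_ei_on_ee$data[sel]
  if (!length(s)) stop("no aerated voxels (F_gas > 0.1) in the mask")
  iv <- .AERATION_INTERVALS
  idx <- findInterval(f, c(iv$lo, Inf), rightmost.closed = FALSE)
  rows <- lapply(seq_len(nrow(iv)), function(k) {
    sk <- s[idx == k]
    if (!length(sk))
      return(data.frame(interval = iv$interval[k], n = 0L,
                        median = NA_real_, q25 = NA_real_, q75 = NA_real_,
                        mean_fgas = NA_real_))
    q <- unname(stats::quantile(sk, c(0.25, 0.5, 0.75), type = 7))
    data.frame(interval = iv$interval[k], n = length(sk), median = q[2],
               q25 = q[1], q75 = q[3], mean_fgas = mean(f[idx == k]))
  })
  intervals <- do.call(rbind, rows)
  p <- unname(stats::quantile(s, c(0.05, 0.95), type = 7))
  keep <- s >= p[1] & s <= p[2]
  breaks <- seq(p[1], p[2], length.out = n_strain_bins + 1L)
  h <- matrix(0, nrow = n_strain_bins, ncol = nrow(iv),
              dimnames = list(NULL, iv$interval))
  if (any(keep) && p[2] > p[1]) {
    sb <- pmin(pmax(findInterval(s[keep], breaks, rightmost.closed = TRUE),
                    1L), n_strain_bins)
    tab <- table(factor(sb, levels = seq_len(n_strain_bins)),
                 factor(idx[keep], levels = seq_len(nrow(iv))))
    h[] <- as.numeric(tab) / length(s)
  }
  structure(list(intervals = intervals, hist2d = h, strain_breaks = breaks,
                 n_aerated = length(s)),
            class = "strain_aeration_joint")
}

#' Strain-colored parametric response map
#'
#' Bins in-mask voxels on a 100 x 100 grid of end-expiratory versus
#' end-inspiratory gas fraction in `[0, 1]` (half-open bins, last bin closed
#' at 1) and records per bin the fraction of lung volume and the mean
#' strain. Bins holding less than the occupancy threshold (default 0.05\% of
#' the lung volume) are suppressed in the reported map.
#'
#' @param fgas_ee End-expiratory [aeration_map()].
#' @param fgas_ei_on_ee End-inspiratory aeration on the end-expiratory grid.
#' @param strain [strain_map()].
#' @param mask [lung_mask()].
#' @param n_bins Bins per axis (default 100).
#' @param threshold Minimum reported bin volume fraction (default 0.0005).
#' @return A list of class `parametric_response_map` with `volume_fraction`
#'   and `mean_strain` (n_bins x n_bins matrices, EE bins in rows;
#'   suppressed/empty bins NA in the reported matrices), `volume_fraction_all`
#'   (pre-suppression), `breaks`, `threshold`.
#' @export
prm <- function(fgas_ee, fgas_ei_on_ee, strain, mask, n_bins = 100L,
                threshold = 5e-4) {
  .stop_geometry(fgas_ee, fgas_ei_on_ee, "EE and EI aeration")
  .stop_geometry(fgas_ee, strain, "aeration and strain")
  .stop_geometry(fgas_ee, mask, "aeration and mask")
  sel <- mask$data & !is.na(fgas_ee$data) & !is.na(fgas_ei_on_ee$data) &
    !is.na(strain$data)
  fe <- fgas_ee$data[sel]
  fi <- fgas_ei_on_ee$data[sel]
  s <- strain$data[sel]
  n <- length(fe)
  if (!n) stop("empty mask")
  bin <- function(x) pmin(pmax(floor(x * n_bins) + 1L, 1L), n_bins)
  be <- bin(fe); bi <- bin(fi)
  key <- (be - 1L) * n_bins + bi
  cnt <- tabulate(key, nbins = n_bins * n_bins)
  ssum <- rep(0, n_bins * n_bins)
  agg <- tapply(s, key, sum)
  ssum[as.integer(names(agg))] <- agg
  volfrac <- matrix(cnt / n, nrow = n_bins, byrow = TRUE)
  msmat <- matrix(ifelse(cnt > 0, ssum / pmax(cnt, 1L), NA_real_),
                  nrow = n_bins, byrow = TRUE)
  vrep <- volfrac; vrep[vrep < threshold] <- NA_real_
  msrep <- msmat; msrep[is.na(vrep)] <- NA_real_
  structure(list(volume_fraction = vrep, mean_strain = msrep,
                 volume_fraction_all = volfrac,
                 breaks = seq(0, 1, length.out = n_bins + 1L),
                 threshold = threshold, n = n),
            class = "parametric_response_map")
}

#' Delta aeration
#'
#' Mean aeration at end-inspiration minus mean aeration at end-expiration.
#'
#' @param mean_ei,mean_ee Whole-lung mean gas fractions.
#' @return Scalar difference.
#' @export
delta_aeration <- function(mean_ei, mean_ee) {
  stopifnot(is.finite(mean_ei), is.finite(mean_ee))
  mean_ei - mean_ee
}
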