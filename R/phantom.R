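# Synthetic deformable lung phantom.
#
# The phantom emulates a surfactant-depleted, partly atelectatic supine lung:
# an ellipsoidal parenchyma with a linear ventral-to-dorsal aeration
# gradient, a dorsal non-aerated (atelectatic) slab, smooth parenchymal
# texture (vascular/tissue heterogeneity that real CT shows and that
# registration needs), a known diffeomorphic end-expiratory to
# end-inspiratory warp with closed-form Jacobian, mass-consistent density
# transport, optional tidal recruitment of a tracked dorsal block, and
# additive Hounsfield noise. Every downstream stage can therefore be
# validated against exact ground truth.

#' Phantom specification
#'
#' Parameters of the synthetic lung phantom. Defaults produce a
#' 96 x 96 x 48 grid at 1 x 1 x 2.5 mm with an aeration gradient from
#' F_gas 0.75 (ventral) to 0.15 (dorsal), a dorsal atelectatic slab covering
#' 25\% of the lung height, and a warp combining mild anisotropic expansion
#' with a dorsally decaying axial stretch whose peak local volumetric strain
#' is about 0.3.
#'
#' @param shape Grid dimensions (voxels), length 3.
#' @param spacing Voxel spacing (mm), length 3.
#' @param center_mm Lung ellipsoid center (mm); default grid center.
#' @param semiaxes_mm Ellipsoid semi-axes (mm), length 3.
#' @param fgas_ventral,fgas_dorsal Gas fraction at the ventral and dorsal
#'   lung boundary; the gradient between them is linear in y.
#' @param atelectasis_fraction Fraction of the lung's dorso-ventral height
#'   occupied by the dorsal atelectatic slab (0 disables it).
#' @param atelectasis_fgas Gas fraction inside the atelectatic slab
#'   (non-aerated, must be < 0.1).
#' @param atelectasis_curve_mm Bowl-shaped curvature (mm) of the slab's
#'   ventral boundary: the boundary sits this much more dorsally at the
#'   lateral/axial lung periphery than at the center, emulating dependent
#'   atelectasis following the dorsal lung surface (0 = flat plane).
#' @param scale Per-axis expansion factors of the warp about the lung center.
#' @param stretch_amp Peak extra linear strain of the smooth axial stretch
#'   (a Gaussian strain bump along y; 0 disables it).
#' @param stretch_sigma Width (SD, mm) of the axial strain bump.
#' @param stretch_center_frac Position of the strain-bump peak as a fraction
#'   of the lung height from the ventral boundary.
#' @param recruit_fraction Target fraction of whole-lung tissue mass placed
#'   in the recruited dorsal block (0 disables recruitment). The block is a
#'   dorsal sub-slab sized on the noise-free end-expiratory image; the
#'   fraction actually achieved is recorded as ground truth.
#' @param recruit_fgas_ei End-inspiratory gas fraction written into the
#'   recruited block.
#' @param texture_sd Standard deviation of the smooth parenchymal texture,
#'   in gas-fraction units (applied only in aerated tissue).
#' @param texture_len_mm Correlation length (FWHM, mm) of the texture.
#' @param hu_noise_sd Additive Gaussian HU noise SD applied independently to
#'   both volumes (HU clipped to `[-1024, 100]`).
#' @param seed Integer random seed; recorded and reused so identical specs
#'   give bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 48L),
                         spacing = c(1, 1, 2.5),
                         center_mm = NULL,
                         semiaxes_mm = c(35, 38, 50),
                         fgas_ventral = 0.75,
                         fgas_dorsal = 0.15,
                         atelectasis_fraction = 0.25,
                         atelectasis_fgas = 0.02,
                         atelectasis_curve_mm = 4,
                         scale = c(1.02, 1.02, 1.012),
                         stretch_amp = 0.24,
                         stretch_sigma = 7,
                         stretch_center_frac = 0.45,
                         recruit_fraction = 0,
                         recruit_fgas_ei = 0.4,
                         texture_sd = 0.04,
                         texture_len_mm = 4,
                         hu_noise_sd = 10,
                         seed = 1L) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(shape) == 3L, all(shape >= 8L),
            length(spacing) == 3L, all(spacing > 0),
            length(semiaxes_mm) == 3L, all(semiaxes_mm > 0),
            length(scale) == 3L, all(scale > 0),
            stretch_sigma > 0, texture_len_mm > 0)
  extent <- (shape - 1) * spacing
  if (is.null(center_mm)) center_mm <- extent / 2
  if (fgas_ventral < 0 || fgas_ventral > 1 || fgas_dorsal < 0 ||
      fgas_dorsal > 1)
    stop("aeration gradient endpoints must lie in [0, 1]")
  if (atelectasis_fraction < 0 || atelectasis_fraction > 1)
    stop("atelectasis_fraction must lie in [0, 1]")
  if (atelectasis_fgas >= 0.1)
    stop("atelectasis_fgas must be < 0.1 (non-aerated)")
  if (recruit_fraction < 0 || recruit_fraction > 0.5)
    stop("recruit_fraction must lie in [0, 0.5]")
  # closed-form positivity of the Jacobian: the strain bump keeps the
  # per-axis map strictly monotone iff its peak slope exceeds -1
  if (1 + stretch_amp <= 0)
    stop("warp parameters produce a non-positive Jacobian")
  # the warped ellipsoid must stay inside the grid (total axial shift is
  # amp * sigma * sqrt(2*pi))
  shift <- abs(stretch_amp) * stretch_sigma * sqrt(2 * pi)
  lo <- center_mm - scale * semiaxes_mm - c(0, shift, 0)
  hi <- center_mm + scale * semiaxes_mm + c(0, shift, 0)
  if (any(lo < 0) || any(hi > extent))
    stop("lung ellipsoid (after warping) does not fit inside the grid")
  structure(list(shape = shape, spacing = spacing, center_mm = center_mm,
                 semiaxes_mm = semiaxes_mm, fgas_ventral = fgas_ventral,
                 fgas_dorsal = fgas_dorsal,
                 atelectasis_fraction = atelectasis_fraction,
                 atelectasis_fgas = atelectasis_fgas,
                 atelectasis_curve_mm = atelectasis_curve_mm, scale = scale,
                 stretch_amp = stretch_amp,
                 stretch_sigma = stretch_sigma,
                 stretch_center_frac = stretch_center_frac,
                 recruit_fraction = recruit_fraction,
                 recruit_fgas_ei = recruit_fgas_ei,
                 texture_sd = texture_sd, texture_len_mm = texture_len_mm,
                 hu_noise_sd = hu_noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

.phantom_geom <- function(spec) {
  cy <- spec$center_mm[2]
  by <- spec$semiaxes_mm[2]
  list(y_vent = cy - by, y_dors = cy + by, height = 2 * by,
       y_atel = cy + by - spec$atelectasis_fraction * 2 * by,
       ym = cy - by + spec$stretch_center_frac * 2 * by)
}

# World-mm coordinates of all voxel centers, as three expanded arrays.
.phantom_coords <- function(spec) {
  n <- spec$shape; sp <- spec$spacing
  gx <- (seq_len(n[1]) - 1) * sp[1]
  gy <- (seq_len(n[2]) - 1) * sp[2]
  gz <- (seq_len(n[3]) - 1) * sp[3]
  list(x = array(rep(gx, times = n[2] * n[3]), dim = n),
       y = array(rep(rep(gy, each = n[1]), times = n[3]), dim = n),
       z = array(rep(gz, each = n[1] * n[2]), dim = n))
}

.phantom_inside <- function(spec, x, y, z) {
  c0 <- spec$center_mm; ax <- spec$semiaxes_mm
  ((x - c0[1]) / ax[1])^2 + ((y - c0[2]) / ax[2])^2 +
    ((z - c0[3]) / ax[3])^2 <= 1
}

# Gravitational depth coordinate: y corrected for the bowl-shaped curvature
# of iso-atelectasis surfaces (boundary more dorsal at the lung periphery).
.phantom_depth <- function(spec, x, y, z) {
  cv <- spec$atelectasis_curve_mm
  if (cv == 0) return(y)
  c0 <- spec$center_mm; ax <- spec$semiaxes_mm
  y - cv * (((x - c0[1]) / ax[1])^2 + ((z - c0[3]) / ax[3])^2)
}

# Noise-free aeration before texture: linear ventral-to-dorsal gradient
# with the atelectatic slab overwritten below the curved depth threshold.
.phantom_base_fgas <- function(spec, x, y, z) {
  g <- .phantom_geom(spec)
  f <- spec$fgas_ventral +
    (spec$fgas_dorsal - spec$fgas_ventral) * (y - g$y_vent) / g$height
  f <- pmin(pmax(f, min(spec$fgas_ventral, spec$fgas_dorsal)),
            max(spec$fgas_ventral, spec$fgas_dorsal))
  if (spec$atelectasis_fraction > 0) {
    q <- .phantom_depth(spec, x, y, z)
    f[q >= g$y_atel] <- spec$atelectasis_fgas
  }
  f
}

# Texture weight: ramps in smoothly above the non-aerated range so the
# atelectatic slab and its neighbourhood stay homogeneous (fluid-like).
.phantom_texture_weight <- function(base) {
  pmin(pmax((base - 0.1) / 0.15, 0), 1)
}

# Smooth random texture field on the end-expiratory grid; deterministic in
# the phantom-spec seed.
.phantom_texture <- function(spec) {
  if (spec$texture_sd <= 0) return(array(0, dim = spec$shape))
  set.seed(spec$seed)
  w <- array(stats::rnorm(prod(spec$shape)), dim = spec$shape)
  sig <- spec$texture_len_mm / 2.3548 / spec$spacing
  ker <- lapply(1:3, function(ax) .gauss_kernel(sig[ax]))
  sm <- .conv_sep(w, ker)
  sm <- sm / stats::sd(sm)
  sm * spec$texture_sd
}

# Full end-expiratory gas fraction at arbitrary world points (mm).
# `tex` is the texture array on the phantom grid (interpolated trilinearly).
.phantom_fgas_at <- function(spec, tex, x, y, z) {
  base <- .phantom_base_fgas(spec, x, y, z)
  w <- .phantom_texture_weight(base)
  ti <- .interp3(tex, x / spec$spacing[1] + 1, y / spec$spacing[2] + 1,
                 z / spec$spacing[3] + 1)
  pmin(pmax(base + w * ti, 0), 1)
}

.phantom_noise <- function(hu, sd, seed) {
  if (sd > 0) {
    set.seed(seed)
    hu <- hu + stats::rnorm(length(hu), sd = sd)
  }
  array(pmin(pmax(hu, -1024), 100), dim = dim(hu))
}

#' Generate the end-expiratory reference image
#'
#' Builds the end-expiratory CT (HU = -1000 F_gas inside the lung, 0 HU
#' soft tissue outside) and its lung mask from a phantom specification.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `ct` ([ct_volume()], with HU noise), `mask`
#'   ([lung_mask()]) and `fgas` (noise-free [aeration_map()]).
#' @export
make_reference <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  co <- .phantom_coords(spec)
  inside <- .phantom_inside(spec, co$x, co$y, co$z)
  if (!any(inside)) stop("degenerate ellipsoid: no in-grid lung voxels")
  tex <- .phantom_texture(spec)
  f <- .phantom_fgas_at(spec, tex, co$x, co$y, co$z)
  hu <- array(0, dim = spec$shape)
  hu[inside] <- -1000 * f[inside]
  hu <- .phantom_noise(hu, spec$hu_noise_sd, spec$seed + 1L)
  f[!inside] <- NA_real_
  list(ct = ct_volume(hu, spec$spacing),
       mask = lung_mask(inside, spec$spacing),
       fgas = aeration_map(f, spec$spacing))
}

#' Analytic diffeomorphic warp of the phantom
#'
#' The end-expiratory to end-inspiratory map is the composition of an
#' anisotropic expansion about the lung center (factors `scale`) with a
#' smooth axial stretch whose linear strain is a Gaussian bump along y:
#' `y -> y + A sigma sqrt(2 pi) Phi((y - ym)/sigma)` with
#' `Phi` the standard normal CDF, so the stretch derivative is
#' `1 + A exp(-(y - ym)^2 / (2 sigma^2))`. Both parts are strictly monotone
#' with closed-form Jacobian
#' `J = s_x s_y s_z (1 + A exp(-(y_s - ym)^2 / (2 sigma^2)))`
#' (`y_s` the scaled y-coordinate), so the warp is an analytic
#' diffeomorphism whenever `A > -1`; the inverse solves the monotone axial
#' map by Newton iteration.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_warp` with elements `forward`,
#'   `inverse` (n x 3 mm matrices in/out), `jacobian` (J at end-expiratory
#'   points) and `spec`.
#' @export
analytic_warp <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- .phantom_geom(spec)
  c0 <- spec$center_mm; s <- spec$scale
  a <- spec$stretch_amp; sig <- spec$stretch_sigma; ym <- g$ym
  if (1 + a <= 0)
    stop("warp parameters produce a non-positive Jacobian")
  stretch <- function(y) {
    y + a * sig * sqrt(2 * pi) * stats::pnorm((y - ym) / sig)
  }
  dstretch <- function(y) 1 + a * exp(-((y - ym)^2) / (2 * sig^2))
  stretch_inv <- function(Y) {
    yi <- Y - a * sig * sqrt(2 * pi) * stats::pnorm((Y - ym) / sig)
    for (i in 1:50) {
      r <- stretch(yi) - Y
      if (max(abs(r)) < 1e-12) break
      yi <- yi - r / dstretch(yi)
    }
    if (max(abs(stretch(yi) - Y)) > 1e-8)
      stop("warp inversion failed to converge")
    yi
  }
  forward <- function(p) {
    p <- cbind(c0[1] + s[1] * (p[, 1] - c0[1]),
               c0[2] + s[2] * (p[, 2] - c0[2]),
               c0[3] + s[3] * (p[, 3] - c0[3]))
    p[, 2] <- stretch(p[, 2])
    p
  }
  inverse <- function(p) {
    y <- stretch_inv(p[, 2])
    cbind(c0[1] + (p[, 1] - c0[1]) / s[1],
          c0[2] + (y - c0[2]) / s[2],
          c0[3] + (p[, 3] - c0[3]) / s[3])
  }
  jacobian <- function(p) {
    ys <- c0[2] + s[2] * (p[, 2] - c0[2])
    prod(s) * dstretch(ys)
  }
  structure(list(forward = forward, inverse = inverse, jacobian = jacobian,
                 spec = spec), class = "phantom_warp")
}

# Dorsal recruitment block: the dorsal-most shell of constant gravitational
# depth accumulating the requested fraction of noise-free end-expiratory
# tissue mass. Returns the depth threshold (mm) and the achieved fraction.
.recruit_block <- function(spec, co, inside, fgas_ee) {
  q <- .phantom_depth(spec, co$x, co$y, co$z)[inside]
  tissue <- (1 - fgas_ee[inside])
  total <- sum(tissue)
  target <- spec$recruit_fraction * total
  ord <- order(q, decreasing = TRUE)
  cum <- cumsum(tissue[ord])
  k <- which(cum >= target)[1]
  if (is.na(k) || k == length(ord))
    stop("recruitment block outside mask or larger than the lung")
  list(q_rec = q[ord][k], fraction = cum[k] / total)
}

#' Generate the end-inspiratory image by mass-consistent transport
#'
#' Transports tissue through the analytic warp with local mass conservation,
#' `1 - F_gas_EI(T(x)) = (1 - F_gas_EE(x)) / J(x)`, evaluating the
#' end-inspiratory image at each voxel y through the closed-form inverse
#' `x = T^-1(y)`. The end-inspiratory mask is the image of the lung
#' ellipsoid under the warp. An optional dorsal recruitment block is
#' overwritten at end-inspiration with its target gas fraction and its
#' end-expiratory tissue mass recorded as the recruited mass fraction.
#' HU noise is then added with the stored seed.
#'
#' @param ee End-expiratory [ct_volume()] from [make_reference()] (used for
#'   geometry; the transported density is evaluated in closed form).
#' @param mask End-expiratory [lung_mask()].
#' @param warp A [analytic_warp()] object.
#' @param spec The matching [phantom_spec()].
#' @return A list with `ct` (end-inspiratory [ct_volume()]), `mask`
#'   (end-inspiratory [lung_mask()]), `fgas` (noise-free end-inspiratory
#'   [aeration_map()]) and `truth` (class `phantom_truth`: `field`
#'   ([displacement_field()] on the EE grid), `jacobian` (closed-form J on
#'   the EE grid), `strain` (truth [strain_map()] inside the EE mask),
#'   `recruited_fraction`, `spec`).
#' @export
make_inspiratory <- function(ee, mask, warp, spec) {
  stopifnot(inherits(warp, "phantom_warp"), inherits(spec, "phantom_spec"))
  .stop_geometry(ee, mask, "EE volume and mask")
  co <- .phantom_coords(spec)
  n <- spec$shape
  pts <- cbind(as.vector(co$x), as.vector(co$y), as.vector(co$z))
  tex <- .phantom_texture(spec)

  # ground truth on the EE grid
  fwd <- warp$forward(pts)
  u <- array(0, dim = c(n, 3L))
  for (k in 1:3) u[, , , k] <- array(fwd[, k] - pts[, k], dim = n)
  jac_ee <- array(warp$jacobian(pts), dim = n)

  # end-inspiratory voxels: pull back through the inverse map
  inv <- warp$inverse(pts)
  inside_ei <- array(.phantom_inside(spec, inv[, 1], inv[, 2], inv[, 3]),
                     dim = n)
  if (!any(inside_ei)) stop("warped lung fell outside the grid")
  f_ee_at_inv <- .phantom_fgas_at(spec, tex, inv[, 1], inv[, 2], inv[, 3])
  j_at_inv <- warp$jacobian(inv)
  f_ei <- 1 - (1 - f_ee_at_inv) / j_at_inv
  f_ei <- array(pmin(pmax(f_ei, 0), 1), dim = n)

  recruited_fraction <- 0
  if (spec$recruit_fraction > 0) {
    inside_ee <- array(.phantom_inside(spec, co$x, co$y, co$z), dim = n)
    f_ee_grid <- array(.phantom_fgas_at(spec, tex, co$x, co$y, co$z), dim = n)
    blk <- .recruit_block(spec, co, inside_ee, f_ee_grid)
    recruited_fraction <- blk$fraction
    q_inv <- .phantom_depth(spec, inv[, 1], inv[, 2], inv[, 3])
    in_block_ei <- inside_ei & array(q_inv >= blk$q_rec, dim = n)
    f_ei[in_block_ei] <- spec$recruit_fgas_ei
  }

  hu <- array(0, dim = n)
  hu[inside_ei] <- -1000 * f_ei[inside_ei]
  hu <- .phantom_noise(hu, spec$hu_noise_sd, spec$seed + 2L)

  f_ei_map <- f_ei
  f_ei_map[!inside_ei] <- NA_real_

  strain_true <- jac_ee - 1
  strain_true[!mask$data] <- NA_real_

  truth <- structure(
    list(field = displacement_field(u, spec$spacing),
         jacobian = jac_ee,
         strain = strain_map(strain_true, spec$spacing),
         recruited_fraction = recruited_fraction,
         spec = spec),
    class = "phantom_truth")
  list(ct = ct_volume(hu, spec$spacing),
       mask = lung_mask(inside_ei, spec$spacing),
       fgas = aeration_map(f_ei_map, spec$spacing),
       truth = truth)
}

#' Generate a complete phantom case
#'
#' Convenience wrapper running [make_reference()], [analytic_warp()] and
#' [make_inspiratory()].
#'
#' @param spec A [phantom_spec()].
#' @return A list with `ee` (list `ct`, `mask`, `fgas`), `ei` (list `ct`,
#'   `mask`, `fgas`), `warp` and `truth`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  ref <- make_reference(spec)
  warp <- analytic_warp(spec)
  ei <- make_inspiratory(ref$ct, ref$mask, warp, spec)
  list(ee = ref[c("ct", "mask", "fgas")],
       ei = ei[c("ct", "mask", "fgas")],
       warp = warp, truth = ei$truth)
}
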