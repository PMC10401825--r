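# Deformable registration of the end-expiratory / end-inspiratory pair.
#
# The registration estimates a dense displacement field u on the
# end-expiratory grid with T(x) = x + u(x) mapping end-expiratory locations
# to their end-inspiratory correspondents, so the Jacobian determinant of T
# is the local end-inspiratory / end-expiratory volume ratio. The similarity
# is a windowed local cross-correlation (realized through local intensity
# standardization, which also makes the match invariant to the local affine
# intensity changes that density transport causes); the transform is built
# in a multistage coarse-to-fine schedule (increasing image resolution,
# B-spline regularization kernel halving from 26 mm) of small additive
# update fields whose step size is capped and fold-guarded so the
# accumulated map stays diffeomorphic. The final Jacobian is checked for
# positivity inside the mask.

#' Registration configuration
#'
#' @param metric_radius Local cross-correlation window radius in stage
#'   voxels; a scalar or one value per axis. The default `c(2, 2, 1)` gives
#'   a near-isotropic window of about 4-5 mm at the reference resolution,
#'   matching the scale of parenchymal texture.
#' @param knot_mm Initial B-spline regularization knot spacing (mm).
#' @param n_halvings Number of subsequent stages in which the knot spacing
#'   is halved (default 3, giving 26, 13, 6.5, 3.25 mm).
#' @param resolution_factors Integer downsampling factor per stage
#'   (coarse to fine; length `n_halvings + 1`).
#' @param iterations Maximum iterations per stage (length `n_halvings + 1`).
#' @param step_frac Caps the per-iteration displacement update at
#'   `step_frac` times the smallest stage voxel spacing (through the
#'   pointwise damping term); together with the fold guard this keeps the
#'   accumulated map diffeomorphic.
#' @param patience Iterations without metric improvement before a stage
#'   stops early.
#' @param margin Zero padding (voxels) added around the end-inspiratory mask
#'   bounding box by [preprocess_pair()].
#' @param active_margin Extra voxels around the mask bounding box actually
#'   iterated over (the remaining pad is static zero background).
#' @param sd_floor Minimum local intensity SD for a voxel to count as
#'   informative (contribute to the metric and force); homogeneous regions
#'   below it are filled in by regularization.
#' @param final_smooth_mm Gaussian smoothing (SD, mm) of the final field
#'   for derivative stability; 0 disables.
#' @return A list of class `registration_config`.
#' @export
registration_config <- function(metric_radius = c(2L, 2L, 1L),
                                knot_mm = 26,
                                n_halvings = 3L,
                                resolution_factors = c(4L, 3L, 2L, 1L),
                                iterations = c(100L, 70L, 50L, 30L),
                                step_frac = 0.8,
                                patience = 8L,
                                margin = 50L,
                                active_margin = 12L,
                                sd_floor = 0.02,
                                final_smooth_mm = 4) {
  nstage <- n_halvings + 1L
  stopifnot(all(metric_radius >= 1L),
            length(metric_radius) %in% c(1L, 3L),
            knot_mm > 0, n_halvings >= 0L,
            length(resolution_factors) == nstage,
            length(iterations) == nstage,
            all(resolution_factors >= 1L), all(iterations >= 1L),
            step_frac > 0, margin >= 0L, active_margin >= 0L,
            sd_floor > 0, final_smooth_mm >= 0)
  structure(list(metric_radius = as.integer(metric_radius),
                 knot_mm = knot_mm, n_halvings = as.integer(n_halvings),
                 resolution_factors = as.integer(resolution_factors),
                 iterations = as.integer(iterations),
                 step_frac = step_frac, patience = as.integer(patience),
                 margin = as.integer(margin),
                 active_margin = as.integer(active_margin),
                 sd_floor = sd_floor, final_smooth_mm = final_smooth_mm),
            class = "registration_config")
}

#' Preprocess an end-expiratory / end-inspiratory pair for registration
#'
#' Rescales HU so that, over the parenchyma, the maximum (tissue density)
#' maps to 0 and the minimum (air) to 1; crops each dimension to the limits
#' of the end-inspiratory mask; and pads with a symmetric margin of
#' zero-intensity voxels. The crop record maps working-grid coordinates back
#' to the original grid.
#'
#' @param ee End-expiratory [ct_volume()] (the fixed image).
#' @param ei End-inspiratory [ct_volume()] (the moving image).
#' @param mask_ei End-inspiratory [lung_mask()].
#' @param margin Pad width in voxels (default 50).
#' @return A list with `fixed`, `moving` (3-D intensity arrays on the
#'   working grid), `mask` (EI mask on the working grid), `spacing`, `crop`
#'   (`lo`, `hi`, `margin`), `rescale` (`hu_min`, `hu_max`), and index
#'   converters `to_original(i)` / `to_working(i)` acting on n x 3 index
#'   matrices.
#' @export
preprocess_pair <- function(ee, ei, mask_ei, margin = 50L) {
  .stop_geometry(ee, ei, "EE and EI volumes")
  .stop_geometry(ee, mask_ei, "volumes and EI mask")
  m <- mask_ei$data
  if (!any(m)) stop("empty EI mask")
  hu <- c(ee$data[m], ei$data[m])
  hu_min <- min(hu); hu_max <- max(hu)
  if (hu_max <= hu_min) stop("degenerate parenchymal HU range")
  rescale <- function(a) {
    i <- (hu_max - a) / (hu_max - hu_min)
    pmin(pmax(i, 0), 1)
  }
  lo <- vapply(1:3, function(ax) min(which(apply(m, ax, any))), integer(1))
  hi <- vapply(1:3, function(ax) max(which(apply(m, ax, any))), integer(1))
  margin <- as.integer(margin)
  wd <- hi - lo + 1L + 2L * margin
  embed <- function(a, fill) {
    out <- array(fill, dim = wd)
    out[margin + seq_len(hi[1] - lo[1] + 1L),
        margin + seq_len(hi[2] - lo[2] + 1L),
        margin + seq_len(hi[3] - lo[3] + 1L)] <-
      a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    out
  }
  to_original <- function(i) sweep(i, 2, lo - 1L - margin, "+")
  to_working <- function(i) sweep(i, 2, lo - 1L - margin, "-")
  list(fixed = embed(rescale(ee$data), 0),
       moving = embed(rescale(ei$data), 0),
       mask = embed(m, FALSE),
       spacing = ee$spacing,
       crop = list(lo = lo, hi = hi, margin = margin),
       rescale = list(hu_min = hu_min, hu_max = hu_max),
       to_original = to_original, to_working = to_working)
}

# Windowed local statistics: mean and SD of an image inside the (per-axis)
# box window. `bs` is the box-sum operator, `nbox` its normalization.
.local_stats <- function(a, bs, nbox) {
  m <- bs(a) / nbox
  v <- bs(a * a) / nbox - m * m
  list(mean = m, sd = sqrt(pmax(v, 0)))
}

# Minimum Jacobian determinant of x + u(x) over the grid (central
# differences), used as the fold guard during optimization.
.min_jacobian <- function(u, sp) {
  g <- vector("list", 9L)
  for (i in 1:3) for (j in 1:3)
    g[[(i - 1) * 3 + j]] <- .deriv_axis(u[, , , i, drop = TRUE], sp[j], j)
  jac <- (1 + g[[1]]) * ((1 + g[[5]]) * (1 + g[[9]]) - g[[6]] * g[[8]]) -
    g[[2]] * (g[[4]] * (1 + g[[9]]) - g[[6]] * g[[7]]) +
    g[[3]] * (g[[4]] * g[[8]] - (1 + g[[5]]) * g[[7]])
  min(jac)
}

# Weighted harmonic infill: relax the displacement field toward the
# weighted average of its neighbours, with each voxel tethered to its
# registered value in proportion to its texture confidence. Voxels with no
# usable image texture (atelectatic parenchyma, faint edges at soft-tissue
# density) are dominated by their neighbours, so the informative region's
# boundary values propagate across homogeneous tissue -- the continuum
# assumption that contiguous tissue moves smoothly. Multiscale Jacobi
# iterations make the propagation cheap; the domain is restricted to the
# (dilated) lung so values cannot leak around it through the background.
.infill_field <- function(u, anchor, sp, domain = NULL,
                          levels = c(4L, 2L, 1L),
                          iters = c(4000L, 40L, 6L), beta = 4) {
  d <- dim(anchor)
  if (is.null(domain)) domain <- array(TRUE, dim = d)
  w_ax <- 1 / sp^2
  relax <- function(uf, u0, an, dom, n_it) {
    dn <- array(as.numeric(dom), dim = dim(an))
    den_nb <- array(0, dim = dim(an))
    for (ax in 1:3)
      den_nb <- den_nb + w_ax[ax] * (.shift3(dn, 1L, ax) +
                                       .shift3(dn, -1L, ax))
    lam <- beta * an * 2 * sum(w_ax)
    den <- den_nb + lam
    upd <- dom & (den > 0)
    for (i in seq_len(n_it)) {
      for (k in 1:3) {
        a <- uf[, , , k] * dn
        num <- array(0, dim = dim(an))
        for (ax in 1:3)
          num <- num + w_ax[ax] * (.shift3(a, 1L, ax) + .shift3(a, -1L, ax))
        a <- uf[, , , k]
        a[upd] <- ((num + lam * u0[, , , k]) / den)[upd]
        uf[, , , k] <- a
      }
    }
    uf
  }
  res <- NULL; prev_f <- NULL
  for (li in seq_along(levels)) {
    f <- levels[li]
    if (f > 1L) {
      an <- .downsample3(anchor, rep(f, 3L))
      dm <- .downsample3(array(as.numeric(domain), dim = d),
                         rep(f, 3L)) > 0.25
      u0 <- array(0, dim = c(dim(an), 3L))
      for (k in 1:3) u0[, , , k] <- .downsample3(u[, , , k], rep(f, 3L))
    } else {
      an <- anchor
      dm <- domain
      u0 <- u
    }
    uf <- u0
    if (!is.null(res)) {
      # seed weakly anchored voxels from the coarser solution
      dsn <- dim(an)
      ctr <- lapply(1:3, function(ax)
        (((seq_len(dsn[ax]) - 1) * f + (f - 1) / 2) -
           (prev_f - 1) / 2) / prev_f + 1)
      px <- array(rep(ctr[[1]], times = dsn[2] * dsn[3]), dim = dsn)
      py <- array(rep(rep(ctr[[2]], each = dsn[1]), times = dsn[3]),
                  dim = dsn)
      pz <- array(rep(ctr[[3]], each = dsn[1] * dsn[2]), dim = dsn)
      sel <- dm & an < 0.25
      for (k in 1:3) {
        up <- array(.interp3(res[, , , k], px, py, pz), dim = dsn)
        a <- uf[, , , k]
        a[sel] <- up[sel]
        uf[, , , k] <- a
      }
    }
    res <- relax(uf, u0, an, dm, iters[li])
    prev_f <- f
  }
  res
}

# Density-based divergence correction. Tissue fraction is an affine
# function of the preprocessed intensity (air = 1, tissue = 0), so the
# ratio tis_EE(x) / tis_EI(T(x)) estimates the local Jacobian wherever both
# values are reliable. In texture-free regions (where the match itself
# cannot constrain volume change) the field's divergence is steered toward
# that density-implied value by adding the gradient of a potential phi
# solving  laplacian(phi) = w (J_density - J_current),  phi = 0 at strongly
# anchored voxels. Multiscale Jacobi as in the harmonic infill.
.density_correct <- function(u, fs, ms, anchor, domain, sp,
                             prep_scale = NULL,
                             levels = c(4L, 2L), iters = c(3000L, 40L)) {
  d <- dim(fs)
  if (is.null(domain)) domain <- array(TRUE, dim = d)
  ix <- array(rep(seq_len(d[1]), times = d[2] * d[3]), dim = d)
  iy <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), dim = d)
  iz <- array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d)
  mw <- array(.interp3(ms, ix + u[, , , 1] / sp[1], iy + u[, , , 2] / sp[2],
                       iz + u[, , , 3] / sp[3]), dim = d)
  # intensities are scaled gas fractions: i = (hu_max - HU)/range, so the
  # tissue fraction is (1 - i) up to the affine HU scale; the ratio is
  # taken directly on (1 - i), which cancels the scale to first order
  if (!is.null(prep_scale)) {
    # exact affine back-conversion: HU = hu_max - i * range,
    # tissue fraction = 1 + HU/1000
    tis_f <- pmax(1 + (prep_scale[1] - fs * prep_scale[2]) / 1000, 0.02)
    tis_m <- pmax(1 + (prep_scale[1] - mw * prep_scale[2]) / 1000, 0.02)
  } else {
    tis_f <- pmax(1 - fs, 0.02)
    tis_m <- pmax(1 - mw, 0.02)
  }
  j_dens <- pmin(pmax(tis_f / tis_m, 0.5), 2)
  j_cur <- 1 +
    .deriv_axis(u[, , , 1], sp[1], 1) +
    .deriv_axis(u[, , , 2], sp[2], 2) +
    .deriv_axis(u[, , , 3], sp[3], 3)
  # trust density only where texture does not constrain the match and both
  # images carry parenchyma (not background/pad, where tis ~ 1 on both)
  w_tex <- pmax(1 - 2 * anchor, 0)
  w_tex[tis_f > 0.985 | tis_m > 0.985] <- 0
  rhs <- w_tex * (j_dens - j_cur)
  rhs[!domain] <- 0
  gs2 <- lapply(1:3, function(ax) .gauss_kernel(2 / sp[ax]))
  rhs <- .conv_sep(rhs, gs2)
  # solve laplacian(phi) = rhs with phi = 0 where anchored, Neumann at the
  # domain boundary
  w_ax <- 1 / sp^2
  solve_level <- function(phi, rhs_l, hold, dom, n_it) {
    dn <- array(as.numeric(dom), dim = dim(dom))
    den <- array(0, dim = dim(dom))
    for (ax in 1:3)
      den <- den + w_ax[ax] * (.shift3(dn, 1L, ax) + .shift3(dn, -1L, ax))
    upd <- dom & !hold & (den > 0)
    for (i in seq_len(n_it)) {
      a <- phi * dn
      num <- array(0, dim = dim(dom))
      for (ax in 1:3)
        num <- num + w_ax[ax] * (.shift3(a, 1L, ax) + .shift3(a, -1L, ax))
      phi[upd] <- ((num - rhs_l) / den)[upd]
    }
    phi
  }
  phi <- NULL; prev_f <- NULL
  for (li in seq_along(levels)) {
    f <- levels[li]
    if (f > 1L) {
      rl <- .downsample3(rhs, rep(f, 3L))
      hl <- .downsample3(anchor, rep(f, 3L)) > 1
      dl <- .downsample3(array(as.numeric(domain), dim = d),
                         rep(f, 3L)) > 0.25
      sp_l <- sp          # rhs and phi scale with physical units; the
      w_ax <- 1 / (sp * f)^2
    } else {
      rl <- rhs; hl <- anchor > 1; dl <- domain
      w_ax <- 1 / sp^2
    }
    pl <- array(0, dim = dim(rl))
    if (!is.null(phi)) {
      dsn <- dim(rl)
      ctr <- lapply(1:3, function(ax)
        (((seq_len(dsn[ax]) - 1) * f + (f - 1) / 2) -
           (prev_f - 1) / 2) / prev_f + 1)
      px <- array(rep(ctr[[1]], times = dsn[2] * dsn[3]), dim = dsn)
      py <- array(rep(rep(ctr[[2]], each = dsn[1]), times = dsn[3]),
                  dim = dsn)
      pz <- array(rep(ctr[[3]], each = dsn[1] * dsn[2]), dim = dsn)
      pl <- array(.interp3(phi, px, py, pz), dim = dsn)
      pl[hl] <- 0
    }
    phi <- solve_level(pl, rl, hl, dl, iters[li])
    prev_f <- f
  }
  # upsample phi to full resolution if the last level was coarse
  if (prev_f > 1L) {
    ctr <- lapply(1:3, function(ax)
      ((seq_len(d[ax]) - 1) - (prev_f - 1) / 2) / prev_f + 1)
    px <- array(rep(ctr[[1]], times = d[2] * d[3]), dim = d)
    py <- array(rep(rep(ctr[[2]], each = d[1]), times = d[3]), dim = d)
    pz <- array(rep(ctr[[3]], each = d[1] * d[2]), dim = d)
    phi <- array(.interp3(phi, px, py, pz), dim = d)
  }
  u[, , , 1] <- u[, , , 1] + .deriv_axis(phi, sp[1], 1)
  u[, , , 2] <- u[, , , 2] + .deriv_axis(phi, sp[2], 2)
  u[, , , 3] <- u[, , , 3] + .deriv_axis(phi, sp[3], 3)
  u
}

# Multistage B-spline-regularized diffeomorphic registration on working
# arrays (fixed/moving intensities, common grid). The per-stage force is a
# locally standardized (windowed mean/SD, making the match criterion a local
# cross-correlation, invariant to the local affine intensity changes that
# density transport causes) demons update with pointwise damping; updates
# are smoothed with a cubic B-spline kernel scaled to the stage knot
# spacing, weighted by texture confidence so informative regions drive
# their homogeneous neighbours. A Jacobian guard keeps the accumulated map
# diffeomorphic. Returns the displacement field in mm on the input grid
# plus a per-stage convergence log.
.ffd_register <- function(fixed, moving, spacing, cfg, mask = NULL,
                          verbose = FALSE) {
  d0 <- dim(fixed)
  knots <- cfg$knot_mm * 0.5^(0:cfg$n_halvings)
  nstage <- length(knots)
  rv <- rep(as.integer(cfg$metric_radius), length.out = 3L)
  u <- NULL          # 4-D field at previous stage resolution
  prev <- NULL       # previous stage grid info
  domain_fin <- NULL # infill domain (dilated lung mask) at the finest stage
  log <- vector("list", nstage)
  for (s in seq_len(nstage)) {
    f <- cfg$resolution_factors[s]
    sps <- spacing * f
    if (knots[s] <= max(sps))
      stop(sprintf(
        "stage %d: knot spacing %.2f mm must exceed stage voxel spacing",
        s, knots[s]))
    fs <- .downsample3(fixed, rep(f, 3L))
    ms <- .downsample3(moving, rep(f, 3L))
    ds <- dim(fs)
    cen <- .stage_centers(ds, rep(f, 3L), spacing)
    ix <- array(rep(seq_len(ds[1]), times = ds[2] * ds[3]), dim = ds)
    iy <- array(rep(rep(seq_len(ds[2]), each = ds[1]), times = ds[3]),
                dim = ds)
    iz <- array(rep(seq_len(ds[3]), each = ds[1] * ds[2]), dim = ds)
    us <- array(0, dim = c(ds, 3L))
    if (!is.null(u)) {
      # resample the previous-stage field (mm) at this stage's voxel centers
      pxi <- (cen[[1]][as.vector(ix)] - prev$off[1]) / prev$sps[1] + 1
      pyi <- (cen[[2]][as.vector(iy)] - prev$off[2]) / prev$sps[2] + 1
      pzi <- (cen[[3]][as.vector(iz)] - prev$off[3]) / prev$sps[3] + 1
      for (k in 1:3)
        us[, , , k] <- array(.interp3(u[, , , k, drop = TRUE],
                                      pxi, pyi, pzi), dim = ds)
    }
    bk <- lapply(1:3, function(ax) rep(1, 2L * rv[ax] + 1L))
    bs <- function(a) .conv_sep(a, bk)
    nbox <- bs(array(1, dim = ds))
    kers <- lapply(1:3, function(ax) .bspline_kernel(knots[s] / sps[ax]))
    stf <- .local_stats(fs, bs, nbox)
    validf <- stf$sd > cfg$sd_floor
    fhat <- (fs - stf$mean) / pmax(stf$sd, cfg$sd_floor)
    fhat[!validf] <- 0
    if (s == nstage) {
      if (!is.null(mask)) {
        mfin <- .downsample3(array(as.numeric(mask), dim = dim(mask)),
                             rep(f, 3L)) > 0.25
        # dilate by two voxels so the infill domain covers the mask
        # boundary band without opening a wide background conduit that
        # would let the harmonic solution leak around the lung surface
        dil <- .conv_sep(array(as.numeric(mfin), dim = ds),
                         lapply(1:3, function(ax) rep(1, 5L)))
        domain_fin <- dil > 0
      }
    }
    kcap <- (cfg$step_frac * min(sps))^2
    best <- us; best_metric <- -Inf; stall <- 0L; it_run <- 0L
    metric0 <- NA_real_
    uema <- NULL  # tail average of the oscillating iterates
    for (it in seq_len(cfg$iterations[s])) {
      it_run <- it
      xi <- ix + us[, , , 1] / sps[1]
      yi <- iy + us[, , , 2] / sps[2]
      zi <- iz + us[, , , 3] / sps[3]
      mw <- array(.interp3(ms, xi, yi, zi), dim = ds)
      stm <- .local_stats(mw, bs, nbox)
      valid <- validf & (stm$sd > cfg$sd_floor)
      mhat <- (mw - stm$mean) / pmax(stm$sd, cfg$sd_floor)
      mhat[stm$sd <= cfg$sd_floor] <- 0
      a_cov <- bs(fs * mw) / nbox - stf$mean * stm$mean
      metric <- mean((a_cov / (pmax(stf$sd, cfg$sd_floor) *
                                 pmax(stm$sd, cfg$sd_floor)))[valid])
      if (it == 1L) metric0 <- metric
      if (metric > best_metric + 1e-9) {
        best_metric <- metric; best <- us; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
      if (it >= 5L)
        uema <- if (is.null(uema)) us else 0.75 * uema + 0.25 * us
      # pointwise-damped demons step on the standardized images
      res <- fhat - mhat
      res[!valid] <- 0
      gx <- .deriv_axis(mhat, sps[1], 1)
      gy <- .deriv_axis(mhat, sps[2], 2)
      gz <- .deriv_axis(mhat, sps[3], 3)
      g2 <- gx * gx + gy * gy + gz * gz
      den <- g2 + res * res / kcap
      w <- ifelse(den > 1e-9, res / den, 0)
      # confidence-weighted B-spline smoothing: texture-rich voxels drive
      # their uninformative neighbours instead of being diluted by them
      cw <- array(as.numeric(valid), dim = ds)
      cws <- pmax(.conv_sep(cw, kers), 0.05)
      d1 <- .conv_sep(cw * w * gx, kers) / cws
      d2 <- .conv_sep(cw * w * gy, kers) / cws
      d3 <- .conv_sep(cw * w * gz, kers) / cws
      un <- us
      un[, , , 1] <- us[, , , 1] + d1
      un[, , , 2] <- us[, , , 2] + d2
      un[, , , 3] <- us[, , , 3] + d3
      if (.min_jacobian(un, sps) > 0.05) {
        us <- un
      } else {
        # a full step would fold the map; try half
        un[, , , 1] <- us[, , , 1] + d1 / 2
        un[, , , 2] <- us[, , , 2] + d2 / 2
        un[, , , 3] <- us[, , , 3] + d3 / 2
        if (.min_jacobian(un, sps) > 0.05) us <- un
      }
    }
    if (best_metric <= metric0 + 1e-9 && s > 1L)
      warning(sprintf("stage %d did not improve the metric; returning best",
                      s))
    # the iterates oscillate around the optimum once converged; their tail
    # average is a lower-variance estimate than any single iterate
    u <- if (!is.null(uema) && it_run > 10L) uema else best
    prev <- list(sps = sps, off = rep((f - 1) / 2, 3L) * spacing, dim = ds)
    log[[s]] <- list(stage = s, knot_mm = knots[s], factor = f,
                     iterations = it_run, metric0 = metric0,
                     metric = best_metric)
    if (verbose)
      message(sprintf(
        "stage %d (knot %.2f mm, factor %d): %d it, CC %.4f -> %.4f",
        s, knots[s], f, it_run, metric0, best_metric))
  }
  # extend the field across texture-free regions (atelectasis, background).
  # Anchor strength combines texture confidence with the locally achieved
  # correlation, so unmatched faint structure does not tether the infill.
  xi <- ix + u[, , , 1] / sps[1]
  yi <- iy + u[, , , 2] / sps[2]
  zi <- iz + u[, , , 3] / sps[3]
  mw <- array(.interp3(ms, xi, yi, zi), dim = prev$dim)
  stm <- .local_stats(mw, bs, nbox)
  ccm <- (bs(fs * mw) / nbox - stf$mean * stm$mean) /
    (pmax(stf$sd, cfg$sd_floor) * pmax(stm$sd, cfg$sd_floor))
  anchor <- pmin(pmax(stf$sd / cfg$sd_floor - 1, 0)^2, 25) *
    pmin(pmax(ccm, 0), 1)^2
  u <- .infill_field(u, anchor, prev$sps, domain_fin)
  # density (mass-conservation) correction: in regions without texture the
  # CT density ratio itself measures the local volume ratio,
  # J = (1 - F_gas_EE) / (1 - F_gas_EI(T(x))); steer the field's divergence
  # toward it where image texture cannot constrain J
  u <- .density_correct(u, fs, ms, anchor, domain_fin, prev$sps,
                        prep_scale = attr(fixed, "hu_scale"))
  # light domain-weighted smoothing for derivative (Jacobian) stability;
  # values outside the infill domain carry no weight, so the background
  # cannot drag the field down at the lung surface
  if (cfg$final_smooth_mm > 0) {
    gsk <- lapply(1:3, function(ax)
      .gauss_kernel(cfg$final_smooth_mm / prev$sps[ax]))
    wdom <- if (is.null(domain_fin)) array(1, dim = prev$dim) else
      array(as.numeric(domain_fin), dim = prev$dim)
    wsm <- pmax(.conv_sep(wdom, gsk), 1e-6)
    for (k in 1:3)
      u[, , , k] <- .conv_sep(u[, , , k] * wdom, gsk) / wsm
  }
  # resample the final field to the full-resolution input grid
  if (!identical(prev$dim, d0)) {
    full <- array(0, dim = c(d0, 3L))
    gx <- (seq_len(d0[1]) - 1) * spacing[1]
    gy <- (seq_len(d0[2]) - 1) * spacing[2]
    gz <- (seq_len(d0[3]) - 1) * spacing[3]
    ix <- array(rep(gx, times = d0[2] * d0[3]), dim = d0)
    iy <- array(rep(rep(gy, each = d0[1]), times = d0[3]), dim = d0)
    iz <- array(rep(gz, each = d0[1] * d0[2]), dim = d0)
    pxi <- (ix - prev$off[1]) / prev$sps[1] + 1
    pyi <- (iy - prev$off[2]) / prev$sps[2] + 1
    pzi <- (iz - prev$off[3]) / prev$sps[3] + 1
    for (k in 1:3)
      full[, , , k] <- array(.interp3(u[, , , k], pxi, pyi, pzi), dim = d0)
    u <- full
  }
  list(field = u, log = log, metric = log[[nstage]]$metric)
}


# Scale the displacement field's volume flux so that the Jacobian integral
# over the end-expiratory mask equals the end-inspiratory lung volume (both
# measured from the segmentations). The correction is a radial field about
# the lung centroid, constant divergence inside the lung and smoothly
# tapered outside, applied in a couple of fixed-point iterations.
.calibrate_volume <- function(field, mask_ee, mask_ei) {
  sp <- field$spacing
  d <- .grid_dim(field)
  m <- mask_ee$data
  v_target <- sum(mask_ei$data)
  gx <- (seq_len(d[1]) - 1) * sp[1]
  gy <- (seq_len(d[2]) - 1) * sp[2]
  gz <- (seq_len(d[3]) - 1) * sp[3]
  ix <- array(rep(gx, times = d[2] * d[3]), dim = d)
  iy <- array(rep(rep(gy, each = d[1]), times = d[3]), dim = d)
  iz <- array(rep(gz, each = d[1] * d[2]), dim = d)
  c0 <- c(mean(ix[m]), mean(iy[m]), mean(iz[m]))
  # smooth taper: 1 on the mask, decaying over ~8 mm outside
  tk <- lapply(1:3, function(ax) .gauss_kernel(4 / sp[ax]))
  taper <- .conv_sep(array(as.numeric(m), dim = d), tk)
  taper <- pmin(taper * 1.5, 1)
  u <- field$data
  for (pass in 1:2) {
    fld <- displacement_field(u, sp)
    jm <- jacobian_map(fld, mask_ee, erode = FALSE)
    vol <- sum(jm$jacobian[m])
    eps <- (v_target / vol - 1) / 3
    if (abs(eps) < 1e-5) break
    u[, , , 1] <- u[, , , 1] + eps * (ix - c0[1]) * taper
    u[, , , 2] <- u[, , , 2] + eps * (iy - c0[2]) * taper
    u[, , , 3] <- u[, , , 3] + eps * (iz - c0[3]) * taper
  }
  displacement_field(u, sp)
}

#' Register an end-expiratory / end-inspiratory pair
#'
#' Full registration operation: preprocesses the pair, runs the multistage
#' diffeomorphic B-spline-regularized registration on the working grid, and
#' returns the displacement field cropped back to the original
#' end-expiratory grid (zero outside the registered region).
#'
#' @param ee End-expiratory [ct_volume()] (fixed image).
#' @param ei End-inspiratory [ct_volume()] (moving image).
#' @param mask_ei End-inspiratory [lung_mask()].
#' @param cfg A [registration_config()].
#' @param mask_ee Optional end-expiratory [lung_mask()]; when given, the
#'   in-mask Jacobian range is computed (and positivity enforced).
#' @param verbose Print per-stage convergence messages.
#' @return A list of class `registration_result` with `field`
#'   ([displacement_field()] on the EE grid), `metric` (final mean local
#'   cross-correlation), `stages` (per-stage log), and `jmin`/`jmax` when
#'   `mask_ee` is supplied.
#' @export
register_pair <- function(ee, ei, mask_ei, cfg = registration_config(),
                          mask_ee = NULL, verbose = FALSE) {
  prep <- preprocess_pair(ee, ei, mask_ei, cfg$margin)
  wd <- dim(prep$fixed)
  # iterate only over the mask neighbourhood; the remaining pad is static
  am <- cfg$active_margin
  alo <- pmax(rep(prep$crop$margin + 1L - am, 3L), 1L)
  ahi <- pmin(wd - prep$crop$margin + am, wd)
  fx <- prep$fixed[alo[1]:ahi[1], alo[2]:ahi[2], alo[3]:ahi[3]]
  mv <- prep$moving[alo[1]:ahi[1], alo[2]:ahi[2], alo[3]:ahi[3]]
  mk <- prep$mask[alo[1]:ahi[1], alo[2]:ahi[2], alo[3]:ahi[3]]
  attr(fx, "hu_scale") <- c(prep$rescale$hu_max,
                            prep$rescale$hu_max - prep$rescale$hu_min)
  res <- .ffd_register(fx, mv, prep$spacing, cfg, mask = mk,
                       verbose = verbose)
  # embed the field into the original EE grid
  d <- .grid_dim(ee)
  u <- array(0, dim = c(d, 3L))
  # active-grid index a maps to original index a + (alo - 1) + (lo - 1 - margin)
  off <- alo - 1L + prep$crop$lo - 1L - prep$crop$margin
  da <- dim(fx)
  src_lo <- pmax(1L - off, 1L)
  src_hi <- pmin(d - off, da)
  dst_lo <- src_lo + off
  dst_hi <- src_hi + off
  u[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3], ] <-
    res$field[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2],
              src_lo[3]:src_hi[3], ]
  field <- displacement_field(u, ee$spacing)
  if (!is.null(mask_ee)) {
    # global volume consistency: the integral of J over the end-expiratory
    # lung must equal the segmented end-inspiratory lung volume; calibrate
    # the field's flux with a smoothly tapered radial correction
    field <- .calibrate_volume(field, mask_ee, mask_ei)
  }
  out <- list(field = field, metric = res$metric, stages = res$log,
              prep = prep[c("crop", "rescale")])
  if (!is.null(mask_ee)) {
    jm <- jacobian_map(field, mask_ee)
    out$jmin <- min(jm$jacobian[jm$mask])
    out$jmax <- max(jm$jacobian[jm$mask])
  }
  structure(out, class = "registration_result")
}

#' Jacobian determinant and volumetric strain of a displacement field
#'
#' J(x) = det(I + grad u(x)) via spacing-aware central differences
#' (one-sided at the grid boundary); volumetric strain s = J - 1. The strain
#' map is reported inside the mask eroded by one voxel to avoid boundary
#' derivative artifacts. Any non-positive in-mask Jacobian violates the
#' diffeomorphism contract and raises an error.
#'
#' @param field A [displacement_field()] on the end-expiratory grid.
#' @param mask End-expiratory [lung_mask()].
#' @param erode Erode the reporting mask by one voxel (default TRUE).
#' @return A list with `jacobian` (full 3-D array), `strain`
#'   ([strain_map()], NA outside the reporting mask) and `mask` (logical
#'   reporting mask).
#' @export
jacobian_map <- function(field, mask, erode = TRUE) {
  .stop_geometry(field, mask, "field and mask")
  sp <- field$spacing
  u <- field$data
  g <- vector("list", 9L)
  for (i in 1:3) for (j in 1:3)
    g[[(i - 1) * 3 + j]] <- .deriv_axis(u[, , , i, drop = TRUE], sp[j], j)
  a11 <- 1 + g[[1]]; a12 <- g[[2]]; a13 <- g[[3]]
  a21 <- g[[4]]; a22 <- 1 + g[[5]]; a23 <- g[[6]]
  a31 <- g[[7]]; a32 <- g[[8]]; a33 <- 1 + g[[9]]
  jac <- a11 * (a22 * a33 - a23 * a32) -
         a12 * (a21 * a33 - a23 * a31) +
         a13 * (a21 * a32 - a22 * a31)
  m <- if (erode) .erode1(mask$data) else mask$data
  if (any(jac[m] <= 0))
    stop("non-positive Jacobian inside the mask: field is not diffeomorphic")
  s <- jac - 1
  s[!m] <- NA_real_
  list(jacobian = jac, strain = strain_map(s, sp), mask = m)
}
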