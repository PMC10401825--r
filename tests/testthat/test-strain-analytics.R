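flat_grid <- function(d = c(12, 12, 6), sp = c(1, 1, 2.5)) {
  list(d = d, sp = sp, mask = lung_mask(array(TRUE, dim = d), sp))
}

test_that("strain summary reports mean, p95 and CoV", {
  g <- flat_grid()
  s <- strain_map(array(0.2, dim = g$d), g$sp)
  ss <- strain_summary(s, g$mask)
  expect_equal(ss$mean, 0.2)
  expect_equal(ss$p95, 0.2)
  expect_equal(ss$cov, 0)
  z <- strain_map(array(0, dim = g$d), g$sp)
  expect_warning(sz <- strain_summary(z, g$mask), "undefined")
  expect_true(is.na(sz$cov))
})

test_that("regional strain is the in-region median", {
  g <- flat_grid()
  a <- array(NA_real_, dim = g$d)
  a[1:3] <- c(0.1, 0.2, 0.9)
  s <- strain_map(a, g$sp)
  r <- array(FALSE, dim = g$d); r[1:3] <- TRUE
  expect_equal(regional_strain(s, r), 0.2)
  expect_error(regional_strain(s, array(FALSE, dim = g$d)), "empty")
  # whole-mask call is consistent with the summary's input set
  set.seed(2)
  b <- array(rnorm(prod(g$d), 0.1, 0.05), dim = g$d)
  sb <- strain_map(b, g$sp)
  expect_equal(regional_strain(sb, g$mask), stats::median(b))
})

test_that("pull-back of EI aeration respects the field", {
  g <- flat_grid(c(16, 16, 8))
  set.seed(9)
  f <- array(runif(prod(g$d), 0.1, 0.9), dim = g$d)
  fmap <- aeration_map(f, g$sp)
  u0 <- displacement_field(array(0, dim = c(g$d, 3)), g$sp)
  out <- ei_aeration_on_ee_grid(fmap, u0)
  expect_equal(out$data, f)
  # uniform translation by one voxel along x: shifted input in the interior
  u1 <- array(0, dim = c(g$d, 3)); u1[, , , 1] <- g$sp[1]
  out1 <- suppressWarnings(
    ei_aeration_on_ee_grid(fmap, displacement_field(u1, g$sp)))
  expect_equal(out1$data[1:15, , ], f[2:16, , ], tolerance = 1e-12)
  # a field leaving the grid warns and clamps
  u2 <- array(0, dim = c(g$d, 3)); u2[, , , 1] <- 40
  expect_warning(ei_aeration_on_ee_grid(fmap, displacement_field(u2, g$sp)),
                 "outside")
})

test_that("pull-back matches the phantom's analytic transport", {
  ph <- default_phantom()
  out <- ei_aeration_on_ee_grid(ph$ei$fgas, ph$truth$field, ph$ee$mask)
  # compare against the closed-form transported aeration at EE voxels:
  # 1 - (1 - F_EE)/J
  truth <- 1 - (1 - ph$ee$fgas$data) / ph$truth$jacobian
  sel <- ph$ee$mask$data & !is.na(out$data) & !is.na(truth)
  expect_lt(mean(abs(out$data[sel] - truth[sel])), 0.02)
})

test_that("strain-aeration intervals summarize aerated voxels", {
  g <- flat_grid(c(20, 20, 5), c(1, 1, 1))
  set.seed(12)
  f <- array(runif(prod(g$d), 0.05, 1), dim = g$d)
  # constructed inverted U: strain peaks at aeration 0.6
  s <- 0.3 - (f - 0.6)^2
  joint <- strain_vs_aeration(strain_map(s, g$sp),
                              aeration_map(f, g$sp), g$mask)
  expect_equal(sum(joint$intervals$n), sum(f > 0.1))
  med <- joint$intervals$median
  expect_true(med[3] > med[1] && med[3] > med[5])
  expect_true(which.max(med) %in% c(3, 4))
  # constant strain: every occupied interval has that median, zero IQR
  s0 <- array(0.1, dim = g$d)
  j0 <- strain_vs_aeration(strain_map(s0, g$sp), aeration_map(f, g$sp),
                           g$mask)
  occ <- j0$intervals$n > 0
  expect_true(all(abs(j0$intervals$median[occ] - 0.1) < 1e-12))
  expect_true(all(j0$intervals$q75[occ] - j0$intervals$q25[occ] == 0))
  # 2-D histogram covers voxels between the 5th and 95th strain percentiles
  expect_equal(sum(joint$hist2d) * joint$n_aerated,
               sum(s[f > 0.1] >= quantile(s[f > 0.1], 0.05, type = 7) &
                     s[f > 0.1] <= quantile(s[f > 0.1], 0.95, type = 7)),
               tolerance = 1e-9)
})

test_that("parametric response map bins and suppresses correctly", {
  g <- flat_grid(c(20, 20, 5), c(1, 1, 1))
  set.seed(13)
  f <- array(runif(prod(g$d)), dim = g$d)
  s <- array(0.1, dim = g$d)
  # identity pair: occupied bins on the diagonal only
  p <- prm(aeration_map(f, g$sp), aeration_map(f, g$sp),
           strain_map(s, g$sp), g$mask)
  occ <- which(!is.na(p$volume_fraction), arr.ind = TRUE)
  expect_true(all(occ[, 1] == occ[, 2]))
  expect_equal(sum(p$volume_fraction_all), 1, tolerance = 1e-12)
  expect_true(all(p$volume_fraction[!is.na(p$volume_fraction)] >= 5e-4))
  # F_gas exactly 1 falls in the last (100th) bin, not beyond
  f1 <- array(1, dim = g$d)
  p1 <- prm(aeration_map(f1, g$sp), aeration_map(f1, g$sp),
            strain_map(s, g$sp), g$mask)
  expect_equal(p1$volume_fraction_all[100, 100], 1)
  # per-bin mean strain is the mean of member strains
  expect_equal(p1$mean_strain[100, 100], 0.1)
})

test_that("delta aeration is the EI minus EE mean", {
  expect_equal(delta_aeration(0.514, 0.456), 0.058)
  expect_equal(delta_aeration(0.4, 0.4), 0)
  expect_equal(delta_aeration(0.3, 0.5), -delta_aeration(0.5, 0.3))
})

test_that("delta aeration tracks mean strain across warp amplitudes", {
  # family of phantoms differing only in expansion amplitude: delta
  # aeration and volume-weighted true mean strain rise together
  amps <- c(0.05, 0.15, 0.3)
  stats <- vapply(amps, function(a) {
    ph <- generate_phantom(small_spec(stretch_amp = a, hu_noise_sd = 0))
    c(delta = mean(ph$ei$fgas$data[ph$ei$mask$data]) -
        mean(ph$ee$fgas$data[ph$ee$mask$data]),
      strain = mean(ph$truth$jacobian[ph$ee$mask$data]) - 1)
  }, numeric(2))
  expect_true(all(diff(stats["delta", ]) > 0))
  expect_true(all(diff(stats["strain", ]) > 0))
  expect_gt(cor(stats["delta", ], stats["strain", ]), 0.9)
})
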