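mini_map <- function(values, spacing = c(1, 1, 1)) {
  # embeds a value vector into a small 3-D grid with an all-true mask
  n <- length(values)
  d <- c(n, 2, 2)
  a <- array(rep(values, 4), dim = d)
  list(map = aeration_map(a, spacing),
       mask = lung_mask(array(TRUE, dim = d), spacing))
}

test_that("HU to gas fraction is linear with clamping", {
  d <- c(4, 4, 2)
  hu <- array(c(-1000, 0, -500, -1200, 40, rep(-300, 27)), dim = d)
  vol <- ct_volume(hu, c(1, 1, 1))
  mask <- lung_mask(array(TRUE, dim = d), c(1, 1, 1))
  f <- hu_to_fgas(vol, mask)
  expect_equal(f$data[1], 1)      # air
  expect_equal(f$data[2], 0)      # tissue
  expect_equal(f$data[3], 0.5)    # midpoint
  expect_equal(f$data[4], 1)      # clamped below -1000
  expect_equal(f$data[5], 0)      # clamped above 0
  mask2 <- lung_mask(array(c(TRUE, rep(FALSE, 31)), dim = d), c(1, 1, 1))
  expect_true(all(is.na(hu_to_fgas(vol, mask2)$data[-1])))
  bad <- lung_mask(array(TRUE, dim = c(4, 4, 3)), c(1, 1, 1))
  expect_error(hu_to_fgas(vol, bad), "geometry")
})

test_that("aeration categories use half-open bounds, boundary upward", {
  mm <- mini_map(c(0, 0.05, 0.0999, 0.1, 0.3, 0.4999, 0.5, 0.7, 0.8999,
                   0.9, 0.95, 1))
  cat <- classify_aeration(mm$map)
  expect_equal(cat[1:12, 1, 1],
               c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 4L))
  # exhaustive and exclusive over [0, 1]
  grid <- mini_map(seq(0, 1, length.out = 101))
  cg <- classify_aeration(grid$map)
  expect_true(all(cg[!is.na(cg)] %in% 1:4))
})

test_that("mass summary computes category masses, percents and gas volume", {
  # two equal voxels at F_gas 0 and 0.5: masses 1 : 0.5
  d <- c(2, 2, 2)
  a <- array(NA_real_, dim = d)
  a[1, 1, 1] <- 0
  a[2, 1, 1] <- 0.5
  ms <- mass_summary(aeration_map(a, c(10, 10, 10)))
  expect_equal(unname(ms$percent["non"]), 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(unname(ms$percent["normal"]), 100 / 3, tolerance = 1e-12)
  expect_equal(sum(ms$percent), 100, tolerance = 1e-9)

  # 1000 voxels of 2.44 mm^3 at F_gas 0.5 hold 1.22 ml of gas
  d2 <- c(10, 10, 10)
  a2 <- array(0.5, dim = d2)
  ms2 <- mass_summary(aeration_map(a2, c(0.977, 0.977, 2.5566)))
  expect_equal(ms2$gas_volume_ml, 1.22, tolerance = 1e-3)

  # additivity over disjoint masks
  ph <- cached("small_phantom", generate_phantom(small_spec()))
  f <- hu_to_fgas(ph$ee$ct, ph$ee$mask)
  rois <- vertical_rois(ph$ee$mask, 4)
  parts <- vapply(rois$masks, function(m)
    mass_summary(f, lung_mask(m, ph$ee$mask$spacing))$total_mass_g,
    numeric(1))
  expect_equal(sum(parts), mass_summary(f)$total_mass_g, tolerance = 1e-9)
  empty <- array(NA_real_, dim = dim(f$data))
  expect_error(mass_summary(aeration_map(empty, f$spacing)), "empty")
})

test_that("heterogeneity equals the CoV and has its invariances", {
  d <- c(20, 20, 6)
  sp <- c(1, 1, 2.5)
  mask <- lung_mask(array(TRUE, dim = d), sp)
  uni <- aeration_map(array(0.4, dim = d), sp)
  expect_equal(heterogeneity(uni, mask)$cov, 0)

  set.seed(3)
  a <- array(runif(prod(d), 0.2, 0.8), dim = d)
  m1 <- heterogeneity(aeration_map(a, sp), mask)
  m2 <- heterogeneity(aeration_map(pmin(a * 1.2, 1), sp), mask)
  # positive rescaling leaves the CoV unchanged (up to the clamp)
  expect_equal(m1$cov, heterogeneity(aeration_map(a * 0.5, sp), mask)$cov,
               tolerance = 1e-12)
  # subtracting a constant lowers the mean and raises the CoV
  m3 <- heterogeneity(aeration_map(a - 0.1, sp), mask)
  expect_gt(m3$cov, m1$cov)
  # filter goes inert when the target FWHM is at the native resolution:
  # plain CoV recovered
  m0 <- heterogeneity(aeration_map(a, sp), mask, fwhm_mm = 1)
  expect_equal(m0$cov, sd(a) / mean(a), tolerance = 1e-10)
  # filtering reduces the measured heterogeneity of a noise field
  expect_lt(m1$cov, m0$cov)
  zero <- aeration_map(array(0, dim = d), sp)
  expect_error(heterogeneity(zero, mask), "undefined")
})

test_that("95th percentile interpolates order statistics", {
  d <- c(25, 2, 2)
  a <- array(NA_real_, dim = d)
  a[seq_len(100)] <- 1:100
  p <- percentile95(aeration_map(a / 100, c(1, 1, 1)))
  expect_equal(p * 100, 95.05, tolerance = 1e-9)
  # translation equivariance
  b <- (a + 100) / 1000
  expect_equal(percentile95(aeration_map(b, c(1, 1, 1))) * 1000,
               95.05 + 100, tolerance = 1e-9)
  cm <- mini_map(rep(0.3, 12))
  expect_equal(percentile95(cm$map), 0.3)
})
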