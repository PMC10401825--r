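test_that("preprocessing rescales, crops to the EI mask and pads", {
  d <- c(120, 130, 90)
  sp <- c(1, 1, 2.5)
  set.seed(5)
  hu <- array(runif(prod(d), -1000, 0), dim = d)
  ee <- ct_volume(hu, sp)
  ei <- ct_volume(hu + rnorm(prod(d), 0, 5), sp)
  m <- array(FALSE, dim = d)
  m[21:80, 31:100, 41:70] <- TRUE   # bounding box 60 x 70 x 30
  mask <- lung_mask(m, sp)
  prep <- preprocess_pair(ee, ei, mask, margin = 50L)
  expect_equal(dim(prep$fixed), c(160L, 170L, 130L))
  # air maps to 1, tissue-density maximum to 0
  hu_all <- c(ee$data[m], ei$data[m])
  expect_equal(max(c(prep$fixed[prep$mask], prep$moving[prep$mask])), 1,
               tolerance = 1e-9)
  expect_equal(min(c(prep$fixed[prep$mask], prep$moving[prep$mask])), 0,
               tolerance = 1e-9)
  # crop record round trip is exact
  idx <- rbind(c(21L, 31L, 41L), c(80L, 100L, 70L), c(50L, 60L, 55L))
  expect_identical(prep$to_original(prep$to_working(idx)), idx)
  expect_identical(prep$to_working(idx)[1, ], c(51L, 51L, 51L))
  empty <- lung_mask(array(c(TRUE, rep(FALSE, prod(d) - 1)), dim = d), sp)
  expect_silent(preprocess_pair(ee, ei, empty, 2L))
})

test_that("Jacobian of simple analytic fields matches closed forms", {
  d <- c(20, 20, 10)
  sp <- c(1, 1, 2.5)
  mask <- lung_mask(array(TRUE, dim = d), sp)
  # zero displacement: J = 1 everywhere, strain = 0
  u0 <- displacement_field(array(0, dim = c(d, 3)), sp)
  jm0 <- jacobian_map(u0, mask)
  expect_equal(unname(range(jm0$jacobian)), c(1, 1))
  expect_equal(unname(range(jm0$strain$data[jm0$mask])), c(0, 0))
  # uniform 1.1 scaling per axis: J = 1.331
  gx <- (seq_len(d[1]) - 1) * sp[1]
  gy <- (seq_len(d[2]) - 1) * sp[2]
  gz <- (seq_len(d[3]) - 1) * sp[3]
  u <- array(0, dim = c(d, 3))
  u[, , , 1] <- 0.1 * array(rep(gx, times = d[2] * d[3]), dim = d)
  u[, , , 2] <- 0.1 * array(rep(rep(gy, each = d[1]), times = d[3]), dim = d)
  u[, , , 3] <- 0.1 * array(rep(gz, each = d[1] * d[2]), dim = d)
  jm <- jacobian_map(displacement_field(u, sp), mask)
  expect_equal(unname(range(jm$jacobian)), c(1.331, 1.331),
               tolerance = 1e-9)
  expect_equal(stats::median(jm$strain$data[jm$mask]), 0.331,
               tolerance = 1e-9)
  # folding fields violate the diffeomorphism contract
  ubad <- array(0, dim = c(d, 3))
  ubad[, , , 1] <- -1.5 * array(rep(gx, times = d[2] * d[3]), dim = d)
  expect_error(jacobian_map(displacement_field(ubad, sp), mask),
               "diffeomorphic")
})

test_that("self-registration of an identity pair stays near zero", {
  spec <- small_spec(hu_noise_sd = 10, seed = 4L)
  ref <- make_reference(spec)
  # identical EE/EI (independent noise would be drawn in a real pair; here
  # the same image tests the null case)
  cfg <- registration_config(n_halvings = 2L,
                             resolution_factors = c(3L, 2L, 1L),
                             iterations = c(30L, 20L, 15L),
                             knot_mm = 26, margin = 10L, active_margin = 6L)
  reg <- suppressWarnings(
    register_pair(ref$ct, ref$ct, ref$mask, cfg, mask_ee = ref$mask))
  mag <- sqrt(reg$field$data[, , , 1]^2 + reg$field$data[, , , 2]^2 +
                reg$field$data[, , , 3]^2)
  expect_lt(max(mag[ref$mask$data]) / min(spec$spacing), 0.5)
  jm <- jacobian_map(reg$field, ref$mask)
  expect_lt(abs(mean(jm$strain$data[jm$mask])), 0.01)
})

test_that("stage schedule enforces knot spacing above voxel spacing", {
  spec <- small_spec(hu_noise_sd = 0)
  ph <- generate_phantom(spec)
  cfg <- registration_config(knot_mm = 4, n_halvings = 1L,
                             resolution_factors = c(2L, 1L),
                             iterations = c(5L, 5L), margin = 5L)
  expect_error(
    suppressWarnings(register_pair(ph$ee$ct, ph$ei$ct, ph$ei$mask, cfg)),
    "knot spacing")
})

test_that("registration recovers a small phantom's deformation", {
  ph <- cached("small_phantom", generate_phantom(small_spec()))
  cfg <- registration_config(n_halvings = 2L,
                             resolution_factors = c(3L, 2L, 1L),
                             iterations = c(60L, 40L, 30L),
                             knot_mm = 26, margin = 10L, active_margin = 8L)
  reg <- suppressWarnings(register_pair(ph$ee$ct, ph$ei$ct, ph$ei$mask,
                                        cfg, mask_ee = ph$ee$mask))
  expect_gt(reg$jmin, 0)
  du <- reg$field$data - ph$truth$field$data
  epe <- sqrt(du[, , , 1]^2 + du[, , , 2]^2 + du[, , , 3]^2)
  m <- ph$ee$mask$data
  # coarse grid (2 x 2 x 5 mm): median endpoint error below one voxel
  expect_lt(stats::median(epe[m]), 2)
  jm <- jacobian_map(reg$field, ph$ee$mask)
  serr <- jm$strain$data[jm$mask] - ph$truth$strain$data[jm$mask]
  expect_lt(abs(mean(serr)), 0.05)
})
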