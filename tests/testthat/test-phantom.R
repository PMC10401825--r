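test_that("reference image has the prescribed aeration structure", {
  spec <- phantom_spec(hu_noise_sd = 0)
  ref <- make_reference(spec)
  f <- ref$fgas$data[ref$mask$data]
  # bimodal: a non-aerated mode from the atelectatic slab and an aerated
  # mode from the gradient (width-weighted mode near the gradient midpoint)
  h <- hist(f, breaks = seq(0, 1, 0.05), plot = FALSE)
  peak_low <- which.max(h$counts[h$mids < 0.1])
  aerated <- h$counts
  aerated[h$mids < 0.4 | h$mids >= 0.9] <- 0
  expect_gt(h$counts[peak_low], 0.1 * sum(h$counts))
  expect_gt(max(aerated), 0.05 * sum(h$counts))
  expect_equal(h$mids[peak_low] < 0.1, TRUE)

  # flat-aeration phantom: every in-mask voxel at -500 HU
  spec2 <- phantom_spec(fgas_ventral = 0.5, fgas_dorsal = 0.5,
                        atelectasis_fraction = 0, texture_sd = 0,
                        hu_noise_sd = 0)
  ref2 <- make_reference(spec2)
  expect_equal(unname(range(ref2$ct$data[ref2$mask$data])), c(-500, -500))

  # no atelectasis: minimum aeration equals the dorsal endpoint
  spec3 <- phantom_spec(atelectasis_fraction = 0, texture_sd = 0,
                        hu_noise_sd = 0)
  ref3 <- make_reference(spec3)
  expect_equal(min(ref3$fgas$data[ref3$mask$data]), 0.15, tolerance = 0.05)
})

test_that("analytic warp has closed-form inverse and Jacobian", {
  spec <- phantom_spec(hu_noise_sd = 0)
  w <- analytic_warp(spec)
  set.seed(7)
  p <- cbind(runif(500, 10, 85), runif(500, 10, 85), runif(500, 10, 110))
  fw <- w$forward(p)
  back <- w$inverse(fw)
  expect_lt(max(abs(back - p)), 1e-8)

  # identity parameters give the identity map with J = 1
  spec_id <- phantom_spec(scale = c(1, 1, 1), stretch_amp = 0,
                          hu_noise_sd = 0)
  wid <- analytic_warp(spec_id)
  expect_lt(max(abs(wid$forward(p) - p)), 1e-12)
  expect_equal(unname(range(wid$jacobian(p))), c(1, 1))

  # uniform anisotropic scaling: J = prod(scale) everywhere
  spec_s <- phantom_spec(scale = c(1.1, 1.1, 1.1), stretch_amp = 0,
                         semiaxes_mm = c(30, 33, 45), hu_noise_sd = 0)
  ws <- analytic_warp(spec_s)
  expect_equal(unname(range(ws$jacobian(p))), rep(1.1^3, 2),
               tolerance = 1e-12)
})

test_that("closed-form Jacobian matches central differences of the field", {
  ph <- default_phantom()
  jm <- jacobian_map(ph$truth$field, ph$ee$mask)
  err <- abs(jm$jacobian - ph$truth$jacobian)[jm$mask]
  expect_lt(max(err), 1e-3)
})

test_that("density transport conserves tissue mass and volume", {
  spec <- phantom_spec(hu_noise_sd = 0)
  ph <- generate_phantom(spec)
  vox <- prod(spec$spacing) / 1000
  m_ee <- sum(1 - ph$ee$fgas$data[ph$ee$mask$data]) * vox
  m_ei <- sum(1 - ph$ei$fgas$data[ph$ei$mask$data]) * vox
  expect_lt(abs(m_ei - m_ee) / m_ee, 0.005)

  # volume consistency: integral of J over EE mask = EI lung volume
  v_pred <- sum(ph$truth$jacobian[ph$ee$mask$data])
  v_ei <- sum(ph$ei$mask$data)
  expect_lt(abs(v_pred - v_ei) / v_ei, 0.01)

  # in-mask EI gas fractions stay within [0, 1] before noise
  expect_true(all(ph$ei$fgas$data[ph$ei$mask$data] >= 0))
  expect_true(all(ph$ei$fgas$data[ph$ei$mask$data] <= 1))

  # with noise the measured (HU-derived) masses still agree within 2%
  ph20 <- generate_phantom(phantom_spec(hu_noise_sd = 20))
  a <- mass_summary(hu_to_fgas(ph20$ee$ct, ph20$ee$mask))
  b <- mass_summary(hu_to_fgas(ph20$ei$ct, ph20$ei$mask))
  expect_lt(abs(b$total_mass_g - a$total_mass_g) / a$total_mass_g, 0.02)
})

test_that("identity warp with zero noise transports the image unchanged", {
  spec <- phantom_spec(scale = c(1, 1, 1), stretch_amp = 0,
                       recruit_fraction = 0, hu_noise_sd = 0)
  ref <- make_reference(spec)
  w <- analytic_warp(spec)
  ei <- make_inspiratory(ref$ct, ref$mask, w, spec)
  expect_identical(ei$mask$data, ref$mask$data)
  expect_lt(max(abs(ei$ct$data - ref$ct$data)), 1e-9)
})

test_that("phantom generation is deterministic in the seed", {
  s <- small_spec(seed = 11L)
  a <- generate_phantom(s)
  b <- generate_phantom(s)
  expect_identical(a$ee$ct$data, b$ee$ct$data)
  expect_identical(a$ei$ct$data, b$ei$ct$data)
  c2 <- generate_phantom(small_spec(seed = 12L))
  expect_false(identical(a$ee$ct$data, c2$ee$ct$data))
})

test_that("recruitment block hits its target mass fraction", {
  for (rf in c(0.02, 0.05)) {
    ph <- generate_phantom(phantom_spec(recruit_fraction = rf,
                                        hu_noise_sd = 0))
    expect_equal(ph$truth$recruited_fraction, rf, tolerance = 0.003)
    # recruited block is aerated at end-inspiration
    f_ei <- ph$ei$fgas$data[ph$ei$mask$data]
    expect_gt(mean(f_ei >= 0.1), 0.5)
  }
})

test_that("invalid phantom parameters are rejected", {
  expect_error(phantom_spec(fgas_ventral = 1.2), "\\[0, 1\\]")
  expect_error(phantom_spec(atelectasis_fgas = 0.2), "non-aerated")
  expect_error(phantom_spec(stretch_amp = -1.2), "Jacobian")
  expect_error(phantom_spec(semiaxes_mm = c(80, 80, 80)), "fit")
})
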