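test_that("vertical ROI partition splits the lung into equal-height slabs", {
  d <- c(10, 60, 4)
  sp <- c(1, 1, 2.5)
  m <- array(FALSE, dim = d)
  m[, 11:50, ] <- TRUE  # y-extent 40 rows
  part <- vertical_rois(lung_mask(m, sp), 10)
  expect_length(part$masks, 10)
  expect_true(all(part$slabs$height == 4L))
  # ROI 1 is most dorsal (highest y rows)
  expect_equal(part$slabs$y_hi[1], 50L)
  expect_equal(part$slabs$y_lo[10], 11L)
  # disjoint and exhaustive
  un <- Reduce(`|`, part$masks)
  expect_identical(un, m)
  expect_equal(sum(vapply(part$masks, sum, numeric(1))), sum(m))

  # 43 rows over 10 ROIs: remainder rows assigned dorsal-first
  m2 <- array(FALSE, dim = c(10, 60, 4))
  m2[, 11:53, ] <- TRUE
  p2 <- vertical_rois(lung_mask(m2, sp), 10)
  expect_equal(p2$slabs$height, c(5L, 5L, 5L, rep(4L, 7)))
  expect_true(max(p2$slabs$height) - min(p2$slabs$height) <= 1L)
  expect_error(vertical_rois(lung_mask(m2, sp), 60), "exceeds")
})

test_that("tidal recruitment is the non-aerated mass drop over EE mass", {
  fake <- function(non, total) {
    structure(list(mass_g = c(non = non, poor = 0, normal = total - non,
                              hyper = 0),
                   total_mass_g = total), class = "aeration_masses")
  }
  expect_equal(tidal_recruitment(fake(10, 100), fake(7, 100)), 0.03)
  expect_equal(tidal_recruitment(fake(10, 100), fake(10, 100)), 0)
  expect_equal(tidal_recruitment(fake(10, 100), fake(6, 98),
                                 denominator = "mean"), 4 / 99)
})

test_that("regional recruitment localizes the recruited block dorsally", {
  ph0 <- cached("rec0", generate_phantom(phantom_spec(recruit_fraction = 0)))
  ph5 <- cached("rec5",
                generate_phantom(phantom_spec(recruit_fraction = 0.05)))
  get_fgas <- function(ph) list(ee = hu_to_fgas(ph$ee$ct, ph$ee$mask),
                                ei = hu_to_fgas(ph$ei$ct, ph$ei$mask))
  f0 <- get_fgas(ph0); f5 <- get_fgas(ph5)
  r0 <- regional_recruitment(f0$ee, f0$ei, ph0$ee$mask, ph0$ei$mask)
  r5 <- regional_recruitment(f5$ee, f5$ei, ph5$ee$mask, ph5$ei$mask)
  # the per-image partitions shift with lung expansion, which moves the
  # atelectasis boundary across ROI boundaries; differencing against the
  # matched no-recruitment phantom cancels that and isolates the block,
  # which lives in the dorsal-most ROIs
  diff_rec <- r5$recruitment - r0$recruitment
  expect_gt(max(diff_rec[1:3]), 0.05)
  expect_true(all(abs(diff_rec[5:10]) < 0.01))
  # the null phantom's profile averages out to (near) zero overall
  wavg0 <- sum(r0$recruitment * r0$mass_ee_g) / sum(r0$mass_ee_g)
  expect_lt(abs(wavg0), 0.01)
  # ROI-mass-weighted mean of regional values equals whole-lung TR
  tr5 <- tidal_recruitment(mass_summary(f5$ee), mass_summary(f5$ei))
  wavg <- sum(r5$recruitment * r5$mass_ee_g) / sum(r5$mass_ee_g)
  expect_equal(wavg, tr5, tolerance = 1e-9)
})

test_that("whole-lung TR recovery across recruitment fractions", {
  specs <- list(cached("rec0", generate_phantom(
                  phantom_spec(recruit_fraction = 0))),
                generate_phantom(phantom_spec(recruit_fraction = 0.02)),
                cached("rec5", generate_phantom(
                  phantom_spec(recruit_fraction = 0.05))))
  for (ph in specs) {
    tr <- tidal_recruitment(
      mass_summary(hu_to_fgas(ph$ee$ct, ph$ee$mask)),
      mass_summary(hu_to_fgas(ph$ei$ct, ph$ei$mask)))
    expect_lt(abs(tr - ph$truth$recruited_fraction), 0.01)
  }
})

test_that("intratidal category changes sum to the total mass change", {
  ph <- cached("rec0", generate_phantom(phantom_spec(recruit_fraction = 0)))
  ms_ee <- mass_summary(hu_to_fgas(ph$ee$ct, ph$ee$mask))
  ms_ei <- mass_summary(hu_to_fgas(ph$ei$ct, ph$ei$mask))
  tab <- intratidal_change(ms_ee, ms_ei)
  expect_equal(sum(tab$delta_g),
               ms_ei$total_mass_g - ms_ee$total_mass_g, tolerance = 1e-9)
  # identical summaries: all zero
  tab0 <- intratidal_change(ms_ee, ms_ee)
  expect_true(all(tab0$delta_g == 0))
  # expansion without recruitment moves mass from poor to normal aeration
  expect_gt(tab$delta_g[tab$category == "normal"], 0)
  expect_lt(tab$delta_g[tab$category == "poor"], 0)
})

test_that("ROI profiles follow the phantom's aeration gradient", {
  ph <- cached("rec0", generate_phantom(phantom_spec(recruit_fraction = 0)))
  f <- hu_to_fgas(ph$ee$ct, ph$ee$mask)
  part <- vertical_rois(ph$ee$mask, 10)
  prof <- roi_profile(part, f)
  # ventral-to-dorsal gradient: mean aeration increases from ROI 1 (dorsal,
  # atelectatic, ROIs 1-2 both inside the slab) to ROI 10 (ventral)
  expect_true(all(diff(prof$mean_fgas) > -0.02))
  expect_true(all(diff(prof$mean_fgas[2:10]) > 0))
  # with the truth strain present: median strain highest mid-dorsally
  prof2 <- roi_profile(part, f, ph$truth$strain)
  expect_true(which.max(prof2$median_strain) %in% 3:6)
  # uniform aeration: all ROI means equal
  u <- aeration_map(ifelse(ph$ee$mask$data, 0.5, NA_real_), f$spacing)
  pu <- roi_profile(part, u)
  expect_equal(unname(range(pu$mean_fgas)), c(0.5, 0.5))
})
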