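test_that("dynamic series and phantom constructors validate their inputs", {
  expect_error(dynamic_series(array(0, c(4, 4, 1))), "4-D")
  expect_error(dynamic_series(array(0, c(4, 4, 1, 1))), "timepoints")
  expect_error(dynamic_series(array(NA_real_, c(4, 4, 1, 5))), "finite")
  # VIF voxel must sit outside the tumor region
  mask <- array(FALSE, c(8, 8, 1)); mask[4:5, 4:5, 1] <- TRUE
  expect_error(
    generate_phantom(dim = c(8, 8, 1), vif_voxel = c(4, 4, 1), tumor_mask = mask),
    "tumor"
  )
})

test_that("noise-free phantom voxels bit-match the simulator times sensitivity", {
  sens <- array(1, c(8, 8, 1)); sens[, 5:8, ] <- 0.5
  mask <- array(FALSE, c(8, 8, 1)); mask[4:6, 4:6, 1] <- TRUE
  ph <- generate_phantom(dim = c(8, 8, 1), vif_voxel = c(1, 1, 1),
                         tumor_mask = mask, sensitivity = sens, peak_snr = Inf)
  expected <- simulate_dynamic_signal(physio_params(), acq_params(), vif_params())$signal
  expect_identical(ph$series$data[4, 4, 1, ], expected)          # sens 1
  expect_identical(ph$series$data[4, 6, 1, ], expected * 0.5)    # sens 0.5
  expect_true(all(ph$series$data[8, 1, 1, ] == 0))               # background
  # VIF voxel carries the excited bolus
  expect_equal(ph$series$data[1, 1, 1, ],
               sin(20 * pi / 180) * vif_concentration(0:59, vif_params()))
})

test_that("phantoms are reproducible under a seed and attain the requested tumor peak SNR", {
  p1 <- generate_phantom(peak_snr = 13, seed = 21)
  p2 <- generate_phantom(peak_snr = 13, seed = 21)
  expect_identical(p1$series$data, p2$series$data)
  truth <- p1$truth
  peaks <- vapply(which(truth$tumor_mask), function(idx) {
    pos <- arrayInd(idx, dim(truth$tumor_mask))
    max(p1$series$data[pos[1], pos[2], pos[3], ])
  }, numeric(1))
  empirical_snr <- mean(peaks) / truth$noise_sigma
  expect_equal(empirical_snr, 13, tolerance = 0.12)
})

test_that("VIF timecourse extraction recovers the generating bolus and flags dead voxels", {
  ph <- generate_phantom(peak_snr = Inf)
  vc <- extract_vif_timecourse(ph$series, ph$truth$vif_voxel)
  ref <- sin(20 * pi / 180) * vif_concentration(vc$time_s, vif_params())
  expect_equal(vc$signal, ref, tolerance = 1e-12)
  expect_error(extract_vif_timecourse(ph$series, c(99, 1, 1)), "in-bounds")
  expect_warning(extract_vif_timecourse(ph$series, c(16, 16, 1)), "bolus")
})

test_that("AUC maps average half-open windows and are additive over subwindows", {
  ph <- generate_phantom(peak_snr = Inf)
  s <- ph$series
  expect_error(auc_map(s, c(10, 10)), "window")
  expect_error(auc_map(s, c(-5, -1)), "timepoints")
  one <- auc_map(s, c(3, 4))  # exactly one timepoint
  expect_equal(as.vector(one), as.vector(s$data[, , , 4]))
  a <- auc_map(s, c(0, 10)); b <- auc_map(s, c(10, 30)); ab <- auc_map(s, c(0, 30))
  expect_equal((10 * a + 20 * b) / 30, ab, tolerance = 1e-12)
  # the bolus peaks early: VIF voxel outshines tumor voxels in the first 15 s
  early <- auc_map(s, c(0, 15))
  vv <- ph$truth$vif_voxel
  expect_gt(early[vv[1], vv[2], vv[3]], max(early[ph$truth$tumor_mask]))
  # constant series: the mean over any window is the constant
  const <- dynamic_series(array(2.5, c(3, 3, 1, 6)))
  expect_true(all(auc_map(const, c(0, 4)) == 2.5))
})

test_that("voxelwise fitting fills maps inside the mask only and recovers the washout ratio", {
  ph <- generate_phantom(peak_snr = Inf)
  vc <- extract_vif_timecourse(ph$series, ph$truth$vif_voxel)
  mask <- ph$truth$tumor_mask
  expect_error(voxelwise_fit(ph$series, array(FALSE, dim(mask)), vc), "mask")
  pm <- voxelwise_fit(ph$series, mask, vc, model = "I")
  expect_true(all(is.na(pm$maps$k_ve[!mask])))
  expect_true(all(is.finite(pm$maps$k_ve[mask])))
  td <- tidy(pm)
  expect_equal(nrow(td), sum(mask))
  expect_true(all(td$converged))
  # the identifiable washout ratio k_ve/v_e is recovered despite the fitted
  # VIF amplitude (individual parameters are only defined up to that scale)
  expect_lt(max(abs(td$kve_ve - 0.02 / 0.30) / (0.02 / 0.30)), 0.05)
  expect_s3_class(ggplot2::ggplot_build(autoplot(pm)), "ggplot_built")
})

test_that("receive-sensitivity scaling is absorbed by the VIF scale, leaving the ratio map unchanged", {
  mask <- array(FALSE, c(8, 8, 1)); mask[4:6, 4:6, 1] <- TRUE
  sens <- array(1, c(8, 8, 1)); sens[mask] <- 0.5
  ph1 <- generate_phantom(dim = c(8, 8, 1), vif_voxel = c(1, 1, 1),
                          tumor_mask = mask, peak_snr = Inf)
  ph2 <- generate_phantom(dim = c(8, 8, 1), vif_voxel = c(1, 1, 1),
                          tumor_mask = mask, sensitivity = sens, peak_snr = Inf)
  vc1 <- extract_vif_timecourse(ph1$series, c(1, 1, 1))
  vc2 <- extract_vif_timecourse(ph2$series, c(1, 1, 1))
  r1 <- tidy(voxelwise_fit(ph1$series, mask, vc1, "I"))$kve_ve
  r2 <- tidy(voxelwise_fit(ph2$series, mask, vc2, "I"))$kve_ve
  expect_lt(max(abs(r2 - r1) / abs(r1)), 1e-2)
})

test_that("series and parameter maps round-trip through NIfTI", {
  skip_if_not_installed("RNifti")
  ph <- generate_phantom(dim = c(6, 6, 1), vif_voxel = c(1, 1, 1),
                         tumor_mask = local({
                           m <- array(FALSE, c(6, 6, 1)); m[3:4, 3:4, 1] <- TRUE; m
                         }), peak_snr = Inf)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "series.nii.gz")
  write_dynamic_series(ph$series, path)
  back <- read_dynamic_series(path)
  expect_equal(back$data, ph$series$data, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$TR, 1)
  vc <- extract_vif_timecourse(ph$series, c(1, 1, 1))
  pm <- voxelwise_fit(ph$series, ph$truth$tumor_mask, vc, "I")
  write_parameter_maps(pm, file.path(dir, "maps"))
  expect_true(file.exists(file.path(dir, "maps", "k_ve.nii.gz")))
  expect_true(file.exists(file.path(dir, "maps", "voxel_fits.csv")))
})
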