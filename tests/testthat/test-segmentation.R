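test_that("noise estimation is slice-wise and exact on trivial input", {
  zero <- scan_volume(array(0, c(8, 8, 4)))
  prof <- estimate_noise(zero)
  expect_equal(prof$n_average, rep(0, 4))
  expect_equal(nrow(prof), 4)
})

test_that("thresholding keeps voxels at or above k x N_average per slice", {
  v <- scan_volume(array(c(6.1, 5.9, rep(0, 14)), c(4, 4, 1)))
  prof <- data.frame(slice = 1, n_average = 2.0, sd = 0.5)
  m <- threshold_mask(v, prof, k = 3)
  expect_equal(m[1, 1, 1], 1L)  # 6.1 >= 6.0 kept
  expect_equal(m[2, 1, 1], 0L)  # 5.9 < 6.0 removed
  expect_true(all(threshold_mask(v, prof, k = 0) == 1L))  # k = 0 keeps all
  bad <- data.frame(slice = 1:2, n_average = c(1, 1), sd = c(1, 1))
  expect_error(threshold_mask(v, bad), "slices")
})

test_that("thresholding is anti-monotone in k and idempotent", {
  acq <- acquisition_spec()
  scan <- add_rician_noise(render_phantom(default_phantom(), acq), 1, 21)
  prof <- estimate_noise(acquire_noise_scan(acq, 22))
  m3 <- threshold_mask(scan, prof, 3)
  m5 <- threshold_mask(scan, prof, 5)
  expect_true(all(m5 <= m3))  # stricter threshold is a subset
  # masking the scan with its own mask and re-thresholding changes nothing
  masked <- scan
  masked$intensities <- scan$intensities * m3
  expect_equal(threshold_mask(masked, prof, 3), m3)
})

test_that("delineation finds the four loaded tubes and reports the control missing", {
  acq <- acquisition_spec()
  ph <- default_phantom("PFPE", texture_seed = 2)
  scan <- add_rician_noise(render_phantom(ph, acq), acq$sigma, 31)
  prof <- estimate_noise(acquire_noise_scan(acq, 32))
  seg <- delineate_rois(threshold_mask(scan, prof, 3), phantom_priors(ph),
                        acq$spacing)
  expect_equal(nrow(seg$segments), 4)
  expect_setequal(seg$segments$role,
                  c("tube1_high", "tube2_high", "tube3_low", "tube4_low"))
  expect_equal(seg$missing, "control")
  # every labeled voxel passed the threshold
  expect_true(all(seg$support[seg$labels > 0] == 1L))
})

test_that("empty masks yield zero segments with all priors missing", {
  pri <- data.frame(role = c("a", "b"), cx = c(2, 6), cy = 2, cz = 2,
                    match_radius = 3)
  seg <- delineate_rois(array(0L, c(8, 8, 4)), pri, c(1, 1, 1))
  expect_equal(nrow(seg$segments), 0)
  expect_setequal(seg$missing, c("a", "b"))
})

test_that("components nearest one prior merge; far components are dropped", {
  m <- array(0L, c(20, 10, 3))
  m[2:4, 2:4, 1:3] <- 1L     # component A, centroid ~ (3, 3)
  m[6:8, 2:4, 1:3] <- 1L     # component B, centroid ~ (7, 3)
  m[17:19, 8:9, 1:3] <- 1L   # far component, no prior nearby
  pri <- data.frame(role = "seg", cx = 5, cy = 3, cz = 1.5, match_radius = 4)
  seg <- delineate_rois(m, pri, c(1, 1, 1))
  expect_equal(nrow(seg$segments), 1)
  expect_equal(sum(seg$labels == seg$segments$id), 2 * 27)  # A and B merged
  expect_true(all(seg$labels[17:19, 8:9, ] == 0))           # artifact dropped
})

test_that("manifest reproduces totals as sums of parts", {
  mf <- build_manifest()
  tt <- attr(mf, "totals")
  expect_equal(tt$scans, sum(mf$scans))
  expect_equal(tt$segments, sum(mf$scans * mf$segments_per_scan))
  pe <- tt$per_experiment
  expect_equal(sum(pe$segments), tt$segments)
  # in-vivo rows carry 3 segments per scan, phantoms 4
  expect_equal(unique(mf$segments_per_scan[mf$experiment == "invivo"]), 3L)
  expect_equal(unique(mf$segments_per_scan[mf$experiment != "invivo"]), 4L)
})

test_that("reader perturbation stays inside the threshold mask", {
  acq <- acquisition_spec()
  ph <- default_phantom()
  scan <- add_rician_noise(render_phantom(ph, acq), acq$sigma, 41)
  prof <- estimate_noise(acquire_noise_scan(acq, 42))
  seg <- delineate_rois(threshold_mask(scan, prof, 3), phantom_priors(ph),
                        acq$spacing)
  expect_identical(reader_perturb(seg, 0)$labels, seg$labels)
  pert <- reader_perturb(seg, 0.3, seed = 5)
  expect_true(all(pert$support[pert$labels > 0] == 1L))
  expect_false(identical(pert$labels, seg$labels))
  # ICC of a feature across magnitude-0 re-reads is exactly 1
  reads <- vapply(1:2, function(i) {
    s <- reader_perturb(seg, 0, seed = i)
    vapply(s$segments$id, function(id) mean(scan$intensities[s$labels == id]), 0)
  }, numeric(4))
  expect_identical(icc(reads), 1)
})
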