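acq64 <- acquisition_spec()

test_that("noiseless render is proportional to concentration with zero background", {
  ph <- default_phantom("PFPE", texture_seed = 1)
  v <- render_phantom(ph, acq64)
  expect_true(all(v$intensities >= 0))
  # doubling every tube's concentration doubles every voxel
  ph2 <- ph
  ph2$tubes$f19_concentration <- 2 * ph$tubes$f19_concentration
  v2 <- render_phantom(ph2, acq64)
  expect_equal(v2$intensities, 2 * v$intensities)
  # a zero-concentration tube contributes nothing
  ph0 <- phantom_spec(data.frame(cx = 17, cy = 17, cz = 9, radius = 3,
                                 length = 12, f19_concentration = 0))
  expect_true(all(render_phantom(ph0, acq64)$intensities == 0))
})

test_that("two homogeneous tubes at 244 and 118 mM have intensity ratio 244/118", {
  mk <- function(conc) phantom_spec(data.frame(
    cx = 17.6, cy = 17.6, cz = 9, radius = 3, length = 12,
    f19_concentration = conc))
  hi <- render_phantom(mk(244), acq64)$intensities
  lo <- render_phantom(mk(118), acq64)$intensities
  core <- hi == max(hi)  # interior voxels, no partial volume
  expect_equal(unique(hi[core] / lo[core]), 244 / 118, tolerance = 1e-12)
})

test_that("tube outside the grid warns and contributes nothing", {
  ph <- phantom_spec(data.frame(cx = 200, cy = 200, cz = 9, radius = 3,
                                length = 12, f19_concentration = 100))
  expect_warning(v <- render_phantom(ph, acq64), "outside the grid")
  expect_true(all(v$intensities == 0))
})

test_that("Rician noise: zero sigma is identity, seeds reproduce, Rayleigh mean", {
  ph <- default_phantom()
  base <- render_phantom(ph, acq64)
  expect_identical(add_rician_noise(base, 0, 1)$intensities, base$intensities)
  n1 <- add_rician_noise(base, 1, 42)
  n2 <- add_rician_noise(base, 1, 42)
  expect_identical(n1$intensities, n2$intensities)
  expect_false(identical(n1$intensities,
                         add_rician_noise(base, 1, 43)$intensities))
  expect_true(all(n1$intensities >= 0))
  # background mean ~ sigma sqrt(pi/2) over >= 1e5 voxels
  big <- acquisition_spec(shape = c(64, 64, 30), sigma = 2)
  nz <- acquire_noise_scan(big, 7)
  expect_equal(mean(nz$intensities), 2 * sqrt(pi / 2), tolerance = 0.01)
  expect_error(add_rician_noise(base, -1), "sigma")
})

test_that("noise scans are flagged, slice means track the Rayleigh mean", {
  nz <- acquire_noise_scan(acq64, 3)
  expect_true(isTRUE(nz$meta$noise_only))
  prof <- estimate_noise(nz)
  expect_equal(nrow(prof), dim(nz$intensities)[3])
  expect_true(all(abs(prof$n_average / (1 * sqrt(pi / 2)) - 1) < 0.05))
  expect_true(all(acquire_noise_scan(acquisition_spec(sigma = 0), 1)$intensities == 0))
  expect_false(identical(acquire_noise_scan(acq64, 1)$intensities,
                         acquire_noise_scan(acq64, 2)$intensities))
})

test_that("session perturbations transform geometry and scale gain/noise", {
  ph <- default_phantom()
  idp <- session_perturbation()
  out <- apply_session_perturbation(ph, acq64, idp)
  expect_equal(out$spec$tubes, ph$tubes)
  expect_equal(out$acq$gain, acq64$gain)
  # translation by exactly one voxel pitch shifts the render by one voxel
  tr <- session_perturbation(translation = c(0.55, 0, 0))
  shifted <- render_phantom(apply_session_perturbation(ph, acq64, tr)$spec, acq64)
  base <- render_phantom(ph, acq64)
  expect_equal(shifted$intensities[2:64, , ], base$intensities[1:63, , ],
               tolerance = 1e-12)
  # gain factor scales the noiseless render linearly
  gf <- apply_session_perturbation(ph, acq64,
                                   session_perturbation(gain_factor = 1.1))
  expect_equal(render_phantom(gf$spec, gf$acq)$intensities,
               1.1 * base$intensities, tolerance = 1e-12)
  expect_error(apply_session_perturbation(
    ph, acq64, session_perturbation(translation = c(500, 0, 0))),
    "outside the grid")
})

test_that("bias fields are mean-one with the requested max deviation", {
  ph <- default_phantom()
  pb <- apply_session_perturbation(ph, acq64,
                                   session_perturbation(bias_amplitude = 0.1,
                                                        seed = 9))
  bf <- f19rad:::bias_field(pb$acq$bias, acq64$shape)
  expect_equal(max(abs(bf - 1)), 0.1, tolerance = 1e-9)
  expect_lt(abs(mean(bf) - 1), 0.02)
})

test_that("test-retest simulation respects trial semantics", {
  ph <- default_phantom()
  acq0 <- acquisition_spec(sigma = 0)
  pair <- simulate_test_retest(ph, acq0, "intrasession", seeds = c(1, 2))
  expect_identical(pair$test$intensities, pair$retest$intensities)
  expect_error(simulate_test_retest(ph, acq64, "intrasession",
                                    pert = session_perturbation(gain_factor = 1.2)),
               "perturbation")
  expect_error(simulate_test_retest(ph, acq64, "intersession"), "requires")
  # intrasession noise difference has ~zero median
  pair2 <- simulate_test_retest(ph, acq64, "intrasession", seeds = c(5, 6))
  expect_lt(abs(median(pair2$test$intensities - pair2$retest$intensities)), 0.05)
  # intersession translation moves the retest tubes by the set amount
  tr <- session_perturbation(translation = c(1.1, 0, 0))
  p3 <- apply_session_perturbation(ph, acq64, tr)
  expect_equal(p3$spec$tubes$cx - ph$tubes$cx, rep(1.1, 5))
})

test_that("in-vivo scene has three labeled regions and a proportional reference", {
  sc <- render_invivo_scene(acq64, seeds = c(1, 2), scene_seed = 3)
  expect_setequal(setdiff(unique(as.vector(sc$mask)), 0L), 1:3)
  # reference tube mean intensity ~ gain x 210 mM (partial volume and
  # texture keep it near, not at, the nominal value)
  ref_mean <- mean(sc$test$intensities[sc$mask == 3])
  expect_equal(ref_mean, acq64$gain * 210, tolerance = 0.15)
  sc2 <- render_invivo_scene(acq64, seeds = c(1, 2), scene_seed = 3)
  expect_identical(sc$test$intensities, sc2$test$intensities)
  expect_identical(sc$mask, sc2$mask)
})

test_that("detection series finds a floor above five noise SDs", {
  ds <- detection_series(c(0, 25, 50, 118, 244), acq64, replicates = 3, seed = 5)
  tab <- ds$table
  expect_false(tab$detected[tab$concentration == 0])
  # background-only ROI mean is the Rayleigh mean
  expect_equal(tab$mean[tab$concentration == 0], sqrt(pi / 2), tolerance = 0.05)
  expect_true(all(diff(tab$mean) > 0))          # monotone in concentration
  expect_true(ds$floor %in% tab$concentration[tab$detected])
  expect_equal(ds$floor, min(tab$concentration[tab$detected]))
  # linear fit above the floor: slope ~ gain, intercept ~ background
  above <- tab[tab$concentration >= ds$floor, ]
  fit <- lm(mean ~ concentration, data = above)
  expect_equal(unname(coef(fit)[2]), acq64$gain, tolerance = 0.1)
  expect_lt(abs(coef(fit)[1]), 5 * sqrt(pi / 2))
  expect_error(detection_series(numeric(), acq64), "empty")
  expect_error(detection_series(c(1, 2), acq64, replicates = 1), "replicates")
})

test_that("volumes round-trip through NRRD and NIfTI with spacing", {
  v <- scan_volume(array(rnorm(4 * 3 * 2)^2, c(4, 3, 2)), c(0.55, 0.55, 1.5))
  for (ext in c("raw.nrrd", "ascii.nrrd", "img.nii.gz")) {
    path <- file.path(tempdir(), ext)
    enc <- if (ext == "ascii.nrrd") "ascii" else "raw"
    write_volume(v, path, encoding = enc)
    r <- read_volume(path)
    expect_equal(r$intensities, v$intensities, tolerance = 1e-7)
    expect_equal(r$spacing, v$spacing, tolerance = 1e-5)
  }
  # integer masks round-trip exactly
  m <- array(sample(0:3, 24, TRUE), c(4, 3, 2))
  p <- file.path(tempdir(), "mask.nrrd")
  write_volume(m, p, spacing = c(1, 1, 2))
  expect_identical(read_volume(p)$intensities, m)
})

test_that("master seeds expand deterministically into distinct child seeds", {
  s1 <- expand_seeds(99, 10)
  expect_identical(s1, expand_seeds(99, 10))
  expect_equal(length(unique(s1)), 10)
  expect_true(all(s1 > 0 & s1 < 2^31))
})
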