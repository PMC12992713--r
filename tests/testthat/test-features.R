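test_that("discretization follows the documented bin arithmetic", {
  expect_equal(discretize(c(1, 2, 3, 4),
                          discretization_spec("fixed-bin-width", 1))$levels,
               c(1L, 2L, 3L, 4L))
  expect_equal(discretize(rep(7, 5))$ng, 1L)  # constant ROI collapses
  d2 <- discretize(0:10, discretization_spec("fixed-bin-count", 2))
  expect_equal(d2$levels, ifelse(0:10 < 5, 1L, 2L))
  expect_error(discretize(numeric()), "empty")
  expect_error(discretization_spec("fixed-bin-count", 1), "count")
  expect_error(discretization_spec("fixed-bin-width", 0), "width")
})

test_that("first-order features match direct arithmetic", {
  f <- firstorder_features(c(1, 2, 2), voxel_volume = 2)
  expect_equal(unname(f["Mean"]), 5 / 3)
  expect_equal(unname(f["Energy"]), 9)
  expect_equal(unname(f["TotalEnergy"]), 18)
  expect_equal(unname(f["Range"]), 1)
  expect_equal(unname(f["RootMeanSquared"]), sqrt(3))
  # population moments on a constructed ROI
  x <- c(2, 4, 4, 4, 5, 5, 7, 9)
  g <- firstorder_features(x)
  expect_equal(unname(g["Variance"]), mean((x - mean(x))^2))
  expect_equal(unname(g["Skewness"]),
               mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5)
  expect_equal(unname(g["MeanAbsoluteDeviation"]), mean(abs(x - mean(x))))
})

test_that("degenerate and symmetric intensity distributions behave as stated", {
  cst <- firstorder_features(rep(4, 10))
  expect_equal(unname(cst["Variance"]), 0)
  expect_equal(unname(cst["Entropy"]), 0)
  expect_equal(unname(cst["Uniformity"]), 1)
  expect_equal(unname(cst["Skewness"]), 0)
  sym <- firstorder_features(c(2, 5, 8))  # {-a, 0, a} shifted positive
  expect_equal(unname(sym["Skewness"]), 0)
  expect_error(firstorder_features(numeric()), "empty")
})

test_that("voxel volume is exact under the study's anisotropic spacing", {
  m <- array(0L, c(6, 6, 6))
  m[1:10] <- 1L
  s <- shape_features(m, c(0.55, 0.55, 1.5))
  expect_equal(unname(s["VoxelVolume"]), 10 * 0.55 * 0.55 * 1.5)
})

test_that("cube sphericity approaches the closed form", {
  s <- shape_features(array(1L, c(20, 20, 20)), c(1, 1, 1))
  target <- (36 * pi)^(1 / 3) / 6
  expect_equal(unname(s["Sphericity"]), target, tolerance = 0.02)
  expect_equal(unname(s["VoxelVolume"]), 8000)
  expect_equal(unname(s["MeshVolume"]), 8000, tolerance = 0.01)
  expect_equal(unname(s["Maximum3DDiameter"]), 19 * sqrt(3), tolerance = 1e-9)
})

test_that("digitized ball sphericity grows toward 1 from below", {
  sph <- vapply(c(5, 8, 12), function(r)
    unname(shape_features(make_ball(r), c(1, 1, 1))["Sphericity"]), 0)
  expect_true(all(diff(sph) > 0))
  expect_true(all(sph < 1))
  expect_gt(sph[3], 0.97)
})

test_that("mesh volume tracks voxel volume for large convex bodies", {
  for (mask in list(make_ball(8), array(1L, c(12, 15, 9)))) {
    s <- shape_features(mask, c(1, 1, 1))
    expect_gt(unname(s["MeshVolume"]), 0)
    expect_equal(unname(s["MeshVolume"]) / unname(s["VoxelVolume"]), 1,
                 tolerance = 0.05)
  }
})

test_that("axis lengths and anisotropy descriptors are coherent", {
  # a flat 1-slice plate: flatness small, elongation moderate
  plate <- array(0L, c(12, 6, 3))
  plate[1:12, 1:6, 2] <- 1L
  s <- shape_features(plate, c(1, 1, 1))
  expect_gt(unname(s["MajorAxisLength"]), unname(s["MinorAxisLength"]))
  expect_gt(unname(s["MinorAxisLength"]), unname(s["LeastAxisLength"]))
  expect_lt(unname(s["Flatness"]), 0.3)
  # single voxel reports its physical extent
  one <- array(0L, c(3, 3, 3)); one[2, 2, 2] <- 1L
  s1 <- shape_features(one, c(0.55, 0.55, 1.5))
  expect_equal(unname(s1["MajorAxisLength"]), 4 * sqrt(1.5^2 / 12))
  expect_error(shape_features(array(0L, c(3, 3, 3))), "empty")
})
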