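test_that("CCC matches hand evaluations and endpoint cases", {
  expect_equal(ccc(c(1, 2, 3), c(1, 2, 3)), 1, tolerance = 1e-12)
  expect_equal(ccc(c(1, 2, 3), c(3, 2, 1)), -1, tolerance = 1e-12)
  expect_equal(ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7, tolerance = 1e-12)
  expect_equal(ccc(c(5, 5, 5), c(5, 5, 5)), 1)   # identical constants
  expect_equal(ccc(c(5, 5, 5), c(5, 5, 5) ), 1)
  expect_equal(ccc(c(2, 3), c(3, 2)), -1)
  expect_error(ccc(1, 1), "at least 2")
  expect_error(ccc(1:3, 1:2), "equal length")
})

test_that("NDR matches hand evaluation and flags zero-range features", {
  expect_equal(ndr(c(1, 5, 9), c(1, 5, 9)), 1)
  expect_equal(ndr(c(0, 10), c(1, 9)), 0.9, tolerance = 1e-12)
  expect_true(is.na(ndr(c(3, 3, 3), c(3, 3, 3))))
})

test_that("stability calls are conjunctive with inclusive boundaries", {
  expect_true(stability_call(0.85, 0.90))
  expect_false(stability_call(0.849, 0.99))
  expect_false(stability_call(0.99, 0.899))
  expect_false(stability_call(NA, 0.95))
  # grid of calls is monotone nonincreasing in both thresholds
  set.seed(3)
  cc <- runif(200, -1, 1); nn <- runif(200, 0, 1)
  grid_c <- seq(0.75, 0.90, by = 0.05)
  grid_n <- seq(0.85, 0.95, by = 0.05)
  counts <- outer(grid_c, grid_n, Vectorize(function(a, b)
    sum(stability_call(cc, nn, a, b))))
  expect_true(all(apply(counts, 1, function(r) all(diff(r) <= 0))))
  expect_true(all(apply(counts, 2, function(cl) all(diff(cl) <= 0))))
})

test_that("CCC obeys its structural invariants", {
  set.seed(4)
  for (i in 1:25) {
    n <- sample(4:40, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3))
    y <- 0.5 * x + rnorm(n, sd = runif(1, 0.1, 2)) + runif(1, -1, 1)
    # |CCC| <= |Pearson r|
    expect_lte(abs(ccc(x, y)), abs(cor(x, y)) + 1e-12)
    # joint permutation invariance
    p <- sample(n)
    expect_equal(ccc(x, y), ccc(x[p], y[p]), tolerance = 1e-12)
    # NDR invariance under common affine rescaling
    expect_equal(ndr(x, y), ndr(3 * x + 7, 3 * y + 7), tolerance = 1e-12)
    expect_lte(ndr(x, y), 1)
  }
  # CCC equals Pearson r when means and variances match
  x <- c(1, 2, 4, 7, 9)
  y <- rev(x) + 0  # same mean and variance
  expect_equal(ccc(x, y), cor(x, y), tolerance = 1e-12)
})

test_that("attenuating the retest arm monotonically degrades estimated CCC", {
  set.seed(5)
  x <- rnorm(4000)
  vals <- vapply(c(1, 0.8, 0.6, 0.4), function(lam)
    ccc(x, lam * x + rnorm(4000, sd = 0.1)), 0)
  expect_true(all(diff(vals) < 0))
})

test_that("Bland-Altman bias, limits and reference band behave as constructed", {
  x <- c(1, 3, 7, 9, 12)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa, c(0, 0))
  bac <- bland_altman(x + 2, x)
  expect_equal(bac$bias, 2)
  expect_error(bland_altman(1:2, 1:2), "at least 3")
  # ~95% of differences inside the band when the true CCC equals 0.85
  set.seed(6)
  n <- 10000
  s2 <- 1; rho <- 0.85  # equal variances, zero bias -> CCC = rho
  z <- matrix(rnorm(2 * n), n)
  xx <- z[, 1]
  yy <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
  ba <- bland_altman(xx, yy, expected_ccc = 0.85)
  inside <- mean(xx - yy > ba$reference_band[1] & xx - yy < ba$reference_band[2])
  expect_equal(inside, 0.95, tolerance = 0.01)
})

test_that("ICC(2,1) agrees with an ANOVA-based oracle and endpoint cases", {
  m <- matrix(c(9, 6, 8, 7, 10,
                2, 1, 4, 1, 5,
                5, 3, 6, 2, 6), 5, 3)  # 5 items x 3 readers
  # independent route: mean squares from aov()
  df <- data.frame(y = as.vector(m),
                   item = factor(rep(1:5, 3)), reader = factor(rep(1:3, each = 5)))
  ms <- anova(aov(y ~ item + reader, df))$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  expected <- (msr - mse) / (msr + 2 * mse + (3 / 5) * (msc - mse))
  expect_equal(icc(m), expected, tolerance = 1e-12)
  # identical reads
  expect_equal(icc(cbind(1:4, 1:4, 1:4)), 1)
  # independent random reads have ICC near 0
  set.seed(7)
  big <- matrix(rnorm(2000), 1000, 2)
  expect_lt(abs(icc(big)), 0.08)
  expect_error(icc(matrix(1, 1, 3)), "at least 2")
})

test_that("Jensen-Shannon divergence spans [0, 1] with symmetry", {
  set.seed(8)
  a <- rnorm(500)
  expect_equal(js_divergence(a, a), 0)
  expect_equal(js_divergence(rnorm(500), rnorm(500, 50)), 1)  # disjoint support
  b <- rnorm(500, 1)
  expect_equal(js_divergence(a, b), js_divergence(b, a), tolerance = 1e-12)
  expect_error(js_divergence(numeric(), a), "empty")
})

test_that("normalization check reports the relative JSD change", {
  set.seed(9)
  pairs <- lapply(1:3, function(i) {
    segs_t <- lapply(1:2, function(s) rnorm(300, mean = 5 * s))
    segs_r <- lapply(1:2, function(s) rnorm(300, mean = 5 * s))
    list(test = segs_t, retest = segs_r)
  })
  nc <- normalization_check(pairs)
  expect_true(nc$mean_raw > 0 && nc$mean_standardized > 0)
  expect_equal(nc$delta_pct,
               100 * abs(nc$mean_standardized - nc$mean_raw) / nc$mean_raw)
})

test_that("distribution comparisons: identical groups are non-significant and
           label permutations leave the statistic unchanged", {
  set.seed(10)
  g <- rnorm(60)
  out <- compare_distributions(list(a = g, b = g))
  expect_gt(min(out$pairwise$p_adj), 0.99)
  g2 <- list(a = rnorm(40), b = rnorm(40, 1), c = rnorm(40, 2))
  k1 <- compare_distributions(g2)$kruskal$statistic
  k2 <- compare_distributions(g2[c(3, 1, 2)])$kruskal$statistic
  expect_equal(k1, k2)
  expect_warning(compare_distributions(list(a = rnorm(10), b = 1:2, c = rnorm(10))),
                 "fewer than 3")
  # BH adjustment across the declared family follows the step-up rule
  cmp <- compare_distributions(list(a = rnorm(30), b = rnorm(30, 0.5),
                                    c = rnorm(30, 1), d = rnorm(30, 1.5)))
  pw <- cmp$pairwise
  expect_equal(pw$p_adj, p.adjust(pw$p, "BH"))
  expect_true(all(pw$p_adj >= pw$p))
})

test_that("class-versus-overall comparisons return BH-adjusted medians", {
  set.seed(11)
  pool <- c(rnorm(50, 0.8, 0.1), rnorm(50, 0.5, 0.2))
  cls <- list(intensity = pool[1:50], texture = pool[51:100])
  cv <- class_vs_overall(cls, pool)
  expect_equal(cv$class, c("intensity", "texture"))
  expect_equal(cv$median, c(median(pool[1:50]), median(pool[51:100])))
  expect_true(all(cv$p_adj >= cv$p - 1e-15))
})
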