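## Agreement statistics: concordance correlation coefficient (CCC),
## normalized dynamic range (NDR), stability calls, Bland-Altman with an
## expected-CCC reference band, absolute-agreement ICC, Jensen-Shannon
## divergence, and stratified distribution comparisons.

ccc_moments <- function(x, y) {
  n <- length(x)
  mu1 <- mean(x); mu2 <- mean(y)
  list(n = n, mu1 = mu1, mu2 = mu2,
       s12 = mean((x - mu1) * (y - mu2)),   # population (1/n) moments
       s1 = mean((x - mu1)^2), s2 = mean((y - mu2)^2))
}

#' Concordance correlation coefficient
#'
#' Lin's CCC in its sample form with population (1/n) moments:
#' `2 s12 / (s1 + s2 + (mu1 - mu2)^2)`. 1 means perfect positive
#' agreement, -1 perfect negative agreement. If the denominator vanishes
#' the pair is degenerate: identical constant vectors give 1 (perfect
#' agreement), anything else is recorded as 0.
#'
#' @param x,y paired test and retest values (length >= 2).
#' @return CCC in `[-1, 1]`.
#' @export
ccc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values must be excluded pairwise first")
  m <- ccc_moments(x, y)
  den <- m$s1 + m$s2 + (m$mu1 - m$mu2)^2
  if (den <= 0) return(if (all(x == y)) 1 else 0)
  2 * m$s12 / den
}

#' Normalized dynamic range
#'
#' `1 - (1/n) sum |test - retest| / (max - min)` with the maximum and
#' minimum taken over the pooled test and retest values of the feature.
#' A feature with no dynamic range (pooled max equals min) has an
#' undefined NDR, returned as `NA` (it then fails the stability
#' criterion).
#'
#' @param x,y paired test and retest values.
#' @return NDR (at most 1), or `NA` for zero-range features.
#' @export
ndr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 1) stop("need at least 1 paired observation")
  rng <- range(c(x, y))
  if (rng[2] - rng[1] <= 0) return(NA_real_)
  1 - mean(abs(x - y)) / (rng[2] - rng[1])
}

#' Stability call from CCC and NDR
#'
#' A feature is "stable" iff CCC >= `ccc_min` and NDR >= `ndr_min`
#' (boundaries inclusive). An undefined (`NA`) NDR fails the call.
#'
#' @param ccc_value,ndr_value the two statistics.
#' @param ccc_min,ndr_min thresholds (defaults 0.85 and 0.90).
#' @return logical.
#' @export
stability_call <- function(ccc_value, ndr_value, ccc_min = 0.85, ndr_min = 0.90) {
  stopifnot(ccc_min > 0, ccc_min <= 1, ndr_min > 0, ndr_min <= 1)
  !is.na(ccc_value) & !is.na(ndr_value) &
    ccc_value >= ccc_min & ndr_value >= ndr_min
}

#' Per-feature agreement between a test and a retest feature table
#'
#' Pairs the rows of two feature tables on key columns, excludes missing
#' values pairwise, and computes CCC, NDR and the stability call for every
#' feature column. Zero-variance/zero-range features are flagged
#' degenerate and never called stable.
#'
#' @param test,retest `feature_table` objects (or plain data.frames) from
#'   the two arms.
#' @param keys columns identifying a paired observation (default
#'   `pair_id` + `segment`).
#' @param ccc_min,ndr_min stability thresholds.
#' @return data.frame of class `agreement_table`: one row per feature with
#'   `feature`, `filter`, `family`, `class`, `n`, `ccc`, `ndr`, `stable`,
#'   `degenerate`.
#' @export
agreement_table <- function(test, retest, keys = c("pair_id", "segment"),
                            ccc_min = 0.85, ndr_min = 0.90) {
  if (!all(keys %in% names(test)) || !all(keys %in% names(retest)))
    stop("key columns missing: ", paste(keys, collapse = ", "))
  kt <- do.call(paste, c(test[keys], sep = "\r"))
  kr <- do.call(paste, c(retest[keys], sep = "\r"))
  common <- intersect(kt, kr)
  test <- test[match(common, kt), , drop = FALSE]
  retest <- retest[match(common, kr), , drop = FALSE]
  fc <- intersect(feature_columns(test), feature_columns(retest))
  fc <- setdiff(fc, keys)
  tx <- feature_taxonomy(fc)
  res <- lapply(fc, function(f) {
    x <- test[[f]]; y <- retest[[f]]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 2)
      return(data.frame(n = length(x), ccc = NA_real_, ndr = NA_real_,
                        stable = FALSE, degenerate = TRUE))
    m <- ccc_moments(x, y)
    den <- m$s1 + m$s2 + (m$mu1 - m$mu2)^2
    cv <- ccc(x, y)
    nv <- ndr(x, y)
    degen <- den <= 0 || is.na(nv)
    data.frame(n = length(x), ccc = cv, ndr = nv,
               stable = stability_call(cv, nv, ccc_min, ndr_min) & !degen,
               degenerate = degen)
  })
  out <- cbind(tx[, c("feature", "filter", "family", "class")],
               do.call(rbind, res))
  rownames(out) <- NULL
  class(out) <- c("agreement_table", "data.frame")
  attr(out, "thresholds") <- c(ccc_min = ccc_min, ndr_min = ndr_min)
  out
}

#' @export
print.agreement_table <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf("<agreement_table> %d features; CCC >= %.2f & NDR >= %.2f\n",
              nrow(x), th[1], th[2]))
  ok <- !x$degenerate
  cat(sprintf("  median CCC %.3f; stable %d/%d (%.1f%%); degenerate %d\n",
              stats::median(x$ccc[ok], na.rm = TRUE), sum(x$stable),
              nrow(x), 100 * mean(x$stable), sum(x$degenerate)))
  invisible(x)
}

#' Bland-Altman analysis with an expected-CCC reference band
#'
#' Bias and 95% limits of agreement of the test-retest differences, plus
#' a reference band for the differences expected if the true CCC equaled
#' `expected_ccc`: under equal variances and no bias the CCC reduces to
#' `1 - var(d) / (2 s^2)`, so the band is
#' `+- 1.96 sqrt(2 s^2 (1 - expected_ccc))` with `s^2` the pooled
#' population variance.
#'
#' @param x,y paired values (n >= 3).
#' @param expected_ccc reference agreement level (default 0.85).
#' @return list with `bias`, `loa` (length 2), `reference_band` (length 2),
#'   `sd_diff`, `n`.
#' @export
bland_altman <- function(x, y, expected_ccc = 0.85) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  d <- x - y
  bias <- mean(d)
  sdd <- stats::sd(d)
  s2 <- (mean((x - mean(x))^2) + mean((y - mean(y))^2)) / 2
  half <- 1.96 * sqrt(2 * s2 * (1 - expected_ccc))
  list(bias = bias, loa = bias + c(-1, 1) * 1.96 * sdd,
       reference_band = c(-half, half), sd_diff = sdd, n = length(x))
}

#' Intraclass correlation coefficient (two-way random, absolute agreement)
#'
#' Single-measurement ICC(2,1) from the two-way ANOVA mean squares, the
#' default for reader-agreement analyses. Rows of `m` are items
#' (segments), columns are readers or repeated reads; complete cases only.
#'
#' @param m numeric matrix, items x readers (>= 2 of each).
#' @return ICC value; identical reads give exactly 1; zero between-item
#'   variance with residual error is degenerate and returns `NA`.
#' @export
icc <- function(m) {
  m <- as.matrix(m)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 items and 2 readers")
  mu <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  msr <- k * sum((row_m - mu)^2) / (n - 1)
  msc <- n * sum((col_m - mu)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + mu)^2)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (den <= 0) return(if (all(m == m[1])) 1 else NA_real_)
  if (msr <= .Machine$double.eps * mu^2 && mse > 0) return(NA_real_)
  (msr - mse) / den
}

#' Jensen-Shannon divergence of two samples
#'
#' Histograms both samples on a common equal-width binning over the pooled
#' range and returns the base-2 JSD, which lies in `[0, 1]`; identical
#' samples give 0, disjoint-support samples 1.
#'
#' @param a,b numeric samples (nonempty).
#' @param bins number of histogram bins.
#' @return JSD in `[0, 1]`.
#' @export
js_divergence <- function(a, b, bins = 64) {
  if (!length(a) || !length(b)) stop("empty input sample")
  rng <- range(c(a, b))
  if (rng[2] - rng[1] <= 0) return(0)  # identical constants
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  p <- tabulate(pmin(findInterval(a, edges, rightmost.closed = TRUE), bins),
                nbins = bins) / length(a)
  q <- tabulate(pmin(findInterval(b, edges, rightmost.closed = TRUE), bins),
                nbins = bins) / length(b)
  mmid <- (p + q) / 2
  kl <- function(u, v) {
    i <- u > 0
    sum(u[i] * log2(u[i] / v[i]))
  }
  0.5 * kl(p, mmid) + 0.5 * kl(q, mmid)
}

#' Intensity-normalization check via histogram similarity
#'
#' Quantifies how much per-scan z-standardization changes test-retest
#' intensity histogram similarity. For every scan pair, the JSD between
#' test and retest intensities of each segment is computed on the raw
#' values and again after standardizing each scan (zero mean, unit
#' variance over its pooled segmented voxels). The summary is the relative
#' change (%) of the mean per-segment JSD.
#'
#' @param pairs list of scan pairs; each element is
#'   `list(test = <list of per-segment intensity vectors>, retest = ...)`
#'   with matching segment order.
#' @param bins histogram bins for the JSD.
#' @return list with `mean_raw`, `mean_standardized` and `delta_pct`.
#' @export
normalization_check <- function(pairs, bins = 64) {
  if (!length(pairs)) stop("no scan pairs supplied")
  raw <- c(); std <- c()
  for (p in pairs) {
    stopifnot(length(p$test) == length(p$retest))
    zt <- unlist(p$test); zr <- unlist(p$retest)
    t_mu <- mean(zt); t_sd <- stats::sd(zt)
    r_mu <- mean(zr); r_sd <- stats::sd(zr)
    for (s in seq_along(p$test)) {
      raw <- c(raw, js_divergence(p$test[[s]], p$retest[[s]], bins))
      std <- c(std, js_divergence((p$test[[s]] - t_mu) / t_sd,
                                  (p$retest[[s]] - r_mu) / r_sd, bins))
    }
  }
  mr <- mean(raw); ms <- mean(std)
  list(mean_raw = mr, mean_standardized = ms,
       delta_pct = 100 * abs(ms - mr) / mr)
}

#' Compare CCC distributions across strata
#'
#' The non-parametric comparison battery: a Shapiro-Wilk normality gate
#' per group, a Kruskal-Wallis test across groups, and pairwise two-sample
#' rank tests with Benjamini-Hochberg correction over the declared family.
#' Groups smaller than 3 are excluded with a warning.
#'
#' @param groups named list of numeric vectors (e.g. CCC values per
#'   feature class).
#' @return list with `shapiro` (per-group W and p), `kruskal`
#'   (statistic, df, p), and `pairwise` (group1, group2, p, p_adj).
#' @export
compare_distributions <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  small <- names(groups)[vapply(groups, length, 0L) < 3]
  if (length(small)) {
    warning("excluding groups with fewer than 3 values: ",
            paste(small, collapse = ", "))
    groups <- groups[!names(groups) %in% small]
  }
  if (length(groups) < 2) stop("fewer than 2 usable groups")
  shapiro <- do.call(rbind, lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    if (length(unique(g)) < 3 || length(g) < 3) {
      data.frame(group = nm, W = NA_real_, p = NA_real_)
    } else {
      g2 <- if (length(g) > 5000) g[seq(1, length(g), length.out = 5000)] else g
      sw <- stats::shapiro.test(g2)
      data.frame(group = nm, W = unname(sw$statistic), p = sw$p.value)
    }
  }))
  vals <- unlist(groups, use.names = FALSE)
  lab <- factor(rep(names(groups), lengths(groups)))
  kw <- stats::kruskal.test(vals, lab)
  cmb <- utils::combn(names(groups), 2)
  pw <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                   p = apply(cmb, 2, function(pair)
                     stats::wilcox.test(groups[[pair[1]]],
                                        groups[[pair[2]]])$p.value))
  pw$p_adj <- stats::p.adjust(pw$p, method = "BH")
  list(shapiro = shapiro,
       kruskal = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p = kw$p.value),
       pairwise = pw)
}

#' Class-versus-overall rank comparisons
#'
#' Tests each feature-class CCC subset against the full pool with a
#' two-sample rank test, BH-adjusted across the classes (the overlap of
#' each class with the pool is a documented caveat of this design).
#'
#' @param class_sets named list of numeric vectors.
#' @param overall numeric vector (the pooled values).
#' @return data.frame with `class`, `median`, `p`, `p_adj`.
#' @export
class_vs_overall <- function(class_sets, overall) {
  res <- do.call(rbind, lapply(names(class_sets), function(nm) {
    g <- class_sets[[nm]][!is.na(class_sets[[nm]])]
    p <- if (length(g) >= 3) stats::wilcox.test(g, overall)$p.value else NA_real_
    data.frame(class = nm, median = stats::median(g), p = p)
  }))
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res
}
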