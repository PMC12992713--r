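## Gray-level texture matrices and their feature sets. Matrices are
## computed by compiled kernels on a 3D integer level array (0 outside the
## ROI, 1..Ng inside); feature definitions follow the standard radiomics
## reference set. Directional families (GLCM, GLRLM) compute features per
## direction and average them.

#' Compute a gray-level texture matrix
#'
#' @param family one of `"GLCM"`, `"GLRLM"`, `"GLSZM"`, `"GLDM"`, `"NGTDM"`.
#' @param levels integer 3D array of discretized gray levels, `0` outside
#'   the ROI, `1..ng` inside.
#' @param ng number of gray levels (defaults to `max(levels)`).
#' @param alpha GLDM dependence tolerance (level difference), default 0.
#' @return the raw count matrix/array for the family:
#'   GLCM `ng x ng x 13` (symmetric counts per direction), GLRLM
#'   `ng x maxrun x 13`, GLSZM `ng x maxzone`, GLDM `ng x 27`
#'   (dependence = 1 + dependent neighbors), NGTDM `ng x 2`
#'   (columns `n_i`, `s_i`).
#' @export
texture_matrix <- function(family = c("GLCM", "GLRLM", "GLSZM", "GLDM", "NGTDM"),
                           levels, ng = max(levels), alpha = 0L) {
  family <- match.arg(family)
  stopifnot(is.array(levels), length(dim(levels)) == 3L)
  dims <- as.integer(dim(levels))
  lv <- as.integer(levels)
  ng <- max(1L, as.integer(ng))
  switch(family,
    GLCM = .cpp_glcm(lv, dims, ng),
    GLRLM = {
      m <- .cpp_glrlm(lv, dims)
      # pad gray-level axis to ng if the top level is unused
      if (dim(m)[1] < ng) {
        p <- array(0, c(ng, dim(m)[2], 13))
        p[seq_len(dim(m)[1]), , ] <- m
        p
      } else m
    },
    GLSZM = {
      m <- .cpp_glszm(lv, dims, ng)
      m
    },
    GLDM = .cpp_gldm(lv, dims, ng, as.integer(alpha)),
    NGTDM = .cpp_ngtdm(lv, dims, ng)
  )
}

entropy2 <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log2(p))
}

glcm_features_one <- function(C) {
  ng <- nrow(C)
  tot <- sum(C)
  if (tot == 0) return(rep(NA_real_, 24))
  p <- C / tot
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)  # == colSums(p) by symmetry
  mu <- sum(i * p)
  sig2 <- sum((i - mu)^2 * p)
  sig <- sqrt(sig2)
  # diagonal / cross-diagonal marginals
  dvals <- 0:(ng - 1)
  pxmy <- vapply(dvals, function(d) sum(p[abs(i - j) == d]), 0)
  svals <- 2:(2 * ng)
  pxpy <- vapply(svals, function(s) sum(p[(i + j) == s]), 0)
  da <- sum(dvals * pxmy)
  hxy <- entropy2(p)
  pxy_prod <- px[row(p)] * px[col(p)]
  hxy1 <- -sum(ifelse(p > 0 & pxy_prod > 0, p * log2(pxy_prod), 0))
  hxy2 <- entropy2(pxy_prod)
  hx <- entropy2(px)
  imc1 <- if (hx == 0) 0 else (hxy - hxy1) / hx
  imc2 <- if (hxy2 <= hxy) 0 else sqrt(1 - exp(-2 * (hxy2 - hxy)))
  corr <- if (sig2 <= .Machine$double.eps) NA_real_ else
    (sum(i * j * p) - mu^2) / sig2
  # MCC: second largest eigenvalue of the transition matrix Q
  mcc <- if (ng == 1L) 1 else {
    pos <- px > 0
    if (sum(pos) < 2L) 1 else {
      psub <- p[pos, pos, drop = FALSE]
      pxs <- px[pos]
      Q <- matrix(0, sum(pos), sum(pos))
      for (kk in seq_len(sum(pos)))
        Q <- Q + outer(psub[, kk], psub[, kk]) / (pxs * pxs[kk])
      ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      sqrt(max(0, ev[2]))
    }
  }
  c(
    Autocorrelation = sum(i * j * p),
    JointAverage = mu,
    ClusterProminence = sum((i + j - 2 * mu)^4 * p),
    ClusterShade = sum((i + j - 2 * mu)^3 * p),
    ClusterTendency = sum((i + j - 2 * mu)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = entropy2(pxmy),
    DifferenceVariance = sum((dvals - da)^2 * pxmy),
    Id = sum(p / (1 + abs(i - j))),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + ((i - j) / ng)^2)),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(ifelse(i != j, p / (i - j)^2, 0)),
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MaximumProbability = max(p),
    MCC = mcc,
    SumAverage = sum(svals * pxpy),
    SumEntropy = entropy2(pxpy),
    SumSquares = sig2
  )
}

# Shared structure of the run-length / size-zone families: counts P over
# (gray level i, size/length s).
rl_style_features <- function(P, prefix_pairs) {
  ng <- nrow(P); ns <- ncol(P)
  nruns <- sum(P)
  if (nruns == 0) return(rep(NA_real_, 16))
  i <- matrix(seq_len(ng), ng, ns)
  s <- matrix(seq_len(ns), ng, ns, byrow = TRUE)
  np <- sum(P * s)
  p <- P / nruns
  mu_i <- sum(i * p); mu_s <- sum(s * p)
  vals <- c(
    sum(P / s^2) / nruns,           # short emphasis
    sum(P * s^2) / nruns,           # long emphasis
    sum(rowSums(P)^2) / nruns,      # gray level non-uniformity
    sum(rowSums(P)^2) / nruns^2,    # ... normalized
    sum(colSums(P)^2) / nruns,      # size non-uniformity
    sum(colSums(P)^2) / nruns^2,    # ... normalized
    nruns / np,                     # run/zone percentage
    sum((i - mu_i)^2 * p),          # gray level variance
    sum((s - mu_s)^2 * p),          # run/zone variance
    entropy2(p),                    # entropy
    sum(P / i^2) / nruns,           # low gray level emphasis
    sum(P * i^2) / nruns,           # high gray level emphasis
    sum(P / (i^2 * s^2)) / nruns,
    sum(P * i^2 / s^2) / nruns,
    sum(P * s^2 / i^2) / nruns,
    sum(P * i^2 * s^2) / nruns
  )
  names(vals) <- prefix_pairs
  vals
}

glrlm_names <- c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
  "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
  "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LongRunHighGrayLevelEmphasis")

glszm_names <- c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
  "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
  "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LargeAreaHighGrayLevelEmphasis")

gldm_features_one <- function(P) {
  ng <- nrow(P); nd <- ncol(P)
  nz <- sum(P)
  if (nz == 0) return(rep(NA_real_, 14))
  i <- matrix(seq_len(ng), ng, nd)
  j <- matrix(seq_len(nd), ng, nd, byrow = TRUE)
  p <- P / nz
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  c(
    SmallDependenceEmphasis = sum(P / j^2) / nz,
    LargeDependenceEmphasis = sum(P * j^2) / nz,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
    DependenceNonUniformity = sum(colSums(P)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(P)^2) / nz^2,
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    DependenceVariance = sum((j - mu_j)^2 * p),
    DependenceEntropy = entropy2(p),
    LowGrayLevelEmphasis = sum(P / i^2) / nz,
    HighGrayLevelEmphasis = sum(P * i^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nz
  )
}

ngtdm_features_one <- function(M) {
  ni <- M[, 1]; si <- M[, 2]
  N <- sum(ni)
  if (N == 0) return(rep(NA_real_, 5))
  ng <- nrow(M)
  lev <- seq_len(ng)
  pi_ <- ni / N
  pos <- pi_ > 0
  ngp <- sum(pos)
  ps <- sum(pi_ * si)
  coarseness <- if (ps == 0) 1e6 else 1 / ps
  contrast <- if (ngp <= 1) 0 else {
    s1 <- 0
    for (a in lev[pos]) for (b in lev[pos]) s1 <- s1 + pi_[a] * pi_[b] * (a - b)^2
    (s1 / (ngp * (ngp - 1))) * (sum(si) / N)
  }
  busy_den <- 0
  for (a in lev[pos]) for (b in lev[pos])
    busy_den <- busy_den + abs(a * pi_[a] - b * pi_[b])
  busyness <- if (busy_den == 0) 0 else ps / busy_den
  complexity <- 0
  for (a in lev[pos]) for (b in lev[pos])
    complexity <- complexity +
      abs(a - b) * (pi_[a] * si[a] + pi_[b] * si[b]) / (pi_[a] + pi_[b])
  complexity <- complexity / N
  strength_num <- 0
  for (a in lev[pos]) for (b in lev[pos])
    strength_num <- strength_num + (pi_[a] + pi_[b]) * (a - b)^2
  strength <- if (sum(si) == 0) 0 else strength_num / sum(si)
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}

#' Texture features from a matrix
#'
#' Computes the standard named feature set of a texture-matrix family.
#' Directional families (GLCM, GLRLM) receive the per-direction count
#' array and return features averaged over the 13 directions. Degenerate
#' matrices yield defined limits where they exist and `NA` otherwise.
#'
#' @param family the family the matrix came from.
#' @param m output of [texture_matrix()].
#' @return named numeric vector (24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM,
#'   5 NGTDM).
#' @export
texture_features <- function(family = c("GLCM", "GLRLM", "GLSZM", "GLDM", "NGTDM"),
                             m) {
  family <- match.arg(family)
  switch(family,
    GLCM = {
      # directions with no in-ROI voxel pairs (e.g. single-slice ROIs) are
      # excluded from the directional average
      keep <- vapply(seq_len(dim(m)[3]), function(d) sum(m[, , d]) > 0, TRUE)
      nm <- names(glcm_features_one(matrix(1)))
      if (!any(keep)) return(stats::setNames(rep(NA_real_, 24), nm))
      per <- vapply(which(keep),
                    function(d) glcm_features_one(matrix(m[, , d], dim(m)[1])),
                    numeric(24))
      stats::setNames(rowMeans(per), nm)
    },
    GLRLM = {
      per <- vapply(seq_len(dim(m)[3]),
                    function(d) rl_style_features(matrix(m[, , d], dim(m)[1]),
                                                  glrlm_names),
                    numeric(16))
      stats::setNames(rowMeans(per), glrlm_names)
    },
    GLSZM = rl_style_features(m, glszm_names),
    GLDM = gldm_features_one(m),
    NGTDM = ngtdm_features_one(m)
  )
}

texture_feature_names <- function(family) {
  switch(family,
    GLCM = names(glcm_features_one(matrix(1))),
    GLRLM = glrlm_names,
    GLSZM = glszm_names,
    GLDM = names(gldm_features_one(matrix(1, 1, 1))),
    NGTDM = names(ngtdm_features_one(matrix(c(1, 0), 1, 2)))
  )
}
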