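## Image filters applied before feature extraction. All filters operate on
## the whole volume; ROI restriction happens at discretization time.

# 1D convolution along one axis of a 3D array with symmetric (edge-repeat)
# padding. `k` is the kernel, `origin` the index of its center tap.
conv_axis <- function(arr, k, axis, origin = (length(k) + 1L) %/% 2L) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- d[axis]
  m <- matrix(a, nrow = n)
  pre <- origin - 1L
  post <- length(k) - origin
  idx_pre <- if (pre > 0) pmin(pmax(rev(seq_len(pre)), 1L), n) else integer()
  idx_post <- if (post > 0) pmin(pmax(n + 1L - seq_len(post), 1L), n) else integer()
  padded <- m[c(idx_pre, seq_len(n), rev(idx_post)), , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * padded[(j - 1L) + seq_len(n), , drop = FALSE]
  aperm(array(out, dim = d[perm]), order(perm))
}

sep_conv3 <- function(arr, kx, ky, kz) {
  arr <- conv_axis(arr, kx, 1L)
  arr <- conv_axis(arr, ky, 2L)
  conv_axis(arr, kz, 3L)
}

gauss_kernel <- function(sigma, truncate = 4) {
  if (sigma <= 0) return(1)
  h <- max(1L, ceiling(truncate * sigma))
  t <- (-h):h
  k <- exp(-t^2 / (2 * sigma^2))
  k / sum(k)
}

# Gaussian smoothing with per-axis sigma in voxel units.
gauss_smooth3 <- function(arr, sigma_vox) {
  sigma_vox <- rep(sigma_vox, length.out = 3)
  sep_conv3(arr, gauss_kernel(sigma_vox[1]), gauss_kernel(sigma_vox[2]),
            gauss_kernel(sigma_vox[3]))
}

#' Filter specification
#'
#' @param name one of `"original"`, `"square"`, `"squareroot"`,
#'   `"logarithm"`, `"exponential"`, `"gradient"`, `"log_sigma"` (Laplacian
#'   of Gaussian; requires `sigma_mm`), `"wavelet"` (one-level undecimated
#'   Haar decomposition; requires `subband`).
#' @param sigma_mm LoG scale in mm (> 0).
#' @param subband one of the 8 strings over {L, H}^3; letters apply to the
#'   x, y, z axes in that order.
#' @return object of class `filter_spec`; its `label` field is the column
#'   prefix used in feature tables.
#' @export
filter_spec <- function(name, sigma_mm = NULL, subband = NULL) {
  valid <- c("original", "square", "squareroot", "logarithm", "exponential",
             "gradient", "log_sigma", "wavelet")
  if (!name %in% valid) stop("unknown filter name: ", name)
  label <- name
  if (name == "log_sigma") {
    if (is.null(sigma_mm) || sigma_mm <= 0) stop("log_sigma requires sigma_mm > 0")
    label <- sprintf("log_sigma_%g", sigma_mm)
  }
  if (name == "wavelet") {
    subs <- apply(expand.grid(c("L", "H"), c("L", "H"), c("L", "H")), 1, paste,
                  collapse = "")
    if (is.null(subband) || !subband %in% subs)
      stop("wavelet requires a subband in {L,H}^3, e.g. 'LLH'")
    label <- paste0("wavelet_", subband)
  }
  structure(list(name = name, sigma_mm = sigma_mm, subband = subband,
                 label = label), class = "filter_spec")
}

#' Default filter set
#'
#' Original plus square, square-root, logarithm, exponential, gradient,
#' Laplacian-of-Gaussian at sigma = 1, 2, 3 mm, and the 8 one-level Haar
#' wavelet subbands: 16 filters in total.
#'
#' @return list of `filter_spec` objects.
#' @export
default_filters <- function() {
  base <- lapply(c("original", "square", "squareroot", "logarithm",
                   "exponential", "gradient"), filter_spec)
  logs <- lapply(c(1, 2, 3), function(s) filter_spec("log_sigma", sigma_mm = s))
  subs <- apply(expand.grid(x = c("L", "H"), y = c("L", "H"), z = c("L", "H")),
                1, function(r) paste(r, collapse = ""))
  wavs <- lapply(subs, function(s) filter_spec("wavelet", subband = s))
  c(base, logs, wavs)
}

#' Apply an intensity or convolution filter to a volume
#'
#' Pointwise filters use the range-normalizing constants of the standard
#' radiomics definitions (with m = max |x| over the volume):
#' square `x^2 / m`, square-root `sign(x) sqrt(|x| m)`, logarithm
#' `sign(x) m log(1 + |x|) / log(1 + m)`, exponential `exp(x log(m) / m)`.
#' Gradient is the magnitude of central differences scaled by physical
#' spacing. The Laplacian of Gaussian is computed as the sum over axes of
#' sampled second-derivative-of-Gaussian kernels (sigma in mm, truncated
#' at 4 sigma, scale-normalized by sigma^2). Wavelet subbands come from a
#' one-level undecimated separable Haar decomposition.
#'
#' @param vol a `scan_volume`.
#' @param f a `filter_spec` (or a filter name, for convenience).
#' @return the filtered `scan_volume`.
#' @export
apply_filter <- function(vol, f) {
  if (is.character(f)) f <- filter_spec(f)
  stopifnot(inherits(vol, "scan_volume"), inherits(f, "filter_spec"))
  x <- vol$intensities
  sp <- vol$spacing
  m <- max(abs(x))
  out <- switch(f$name,
    original = x,
    square = if (m == 0) x else x^2 / m,
    squareroot = if (m == 0) x else sign(x) * sqrt(abs(x) * m),
    logarithm = if (m == 0) x else sign(x) * m * log1p(abs(x)) / log1p(m),
    exponential = if (m == 0) array(1, dim(x)) else exp(x * log(m) / m),
    gradient = gradient_magnitude(x, sp),
    log_sigma = log_filter(x, sp, f$sigma_mm),
    wavelet = wavelet_subband(x, f$subband)
  )
  res <- vol
  res$intensities <- out
  res$meta$filter <- f$label
  res
}

gradient_magnitude <- function(x, spacing) {
  d <- dim(x)
  g2 <- array(0, d)
  for (ax in 1:3) {
    if (d[ax] < 2) next
    # central differences, one-sided at the boundary
    k <- c(-1, 0, 1) / (2 * spacing[ax])
    g <- conv_axis(x, k, ax)
    # fix boundary slices to one-sided differences
    sub <- function(a, i) {
      args <- c(list(a), rep(list(quote(expr = )), 3))
      args[[ax + 1L]] <- i
      do.call(`[`, args)
    }
    asn <- function(a, i, value) {
      args <- c(list(a), rep(list(quote(expr = )), 3), list(value = value))
      args[[ax + 1L]] <- i
      do.call(`[<-`, args)
    }
    g <- asn(g, 1L, (sub(x, 2L) - sub(x, 1L)) / spacing[ax])
    g <- asn(g, d[ax], (sub(x, d[ax]) - sub(x, d[ax] - 1L)) / spacing[ax])
    g2 <- g2 + g^2
  }
  sqrt(g2)
}

# Sampled LoG kernels: per axis, the Gaussian and its second derivative,
# sampled at voxel pitch in mm. The smoothing taps are normalized to sum 1;
# the second-derivative taps share the same normalization constant so the
# separable sum reproduces sigma^2 * Laplacian(Gaussian * I).
log_axis_kernels <- function(sigma, pitch, truncate = 4) {
  h <- max(1L, ceiling(truncate * sigma / pitch))
  t <- ((-h):h) * pitch
  g <- exp(-t^2 / (2 * sigma^2))
  norm <- sum(g)
  d2 <- (t^2 / sigma^4 - 1 / sigma^2) * g / norm
  list(g = g / norm, d2 = d2)
}

log_filter <- function(x, spacing, sigma_mm) {
  ks <- lapply(1:3, function(ax) log_axis_kernels(sigma_mm, spacing[ax]))
  out <- array(0, dim(x))
  for (ax in 1:3) {
    kern <- lapply(1:3, function(a) if (a == ax) ks[[a]]$d2 else ks[[a]]$g)
    out <- out + sep_conv3(x, kern[[1]], kern[[2]], kern[[3]])
  }
  sigma_mm^2 * out
}

wavelet_subband <- function(x, subband) {
  lo <- c(1, 1) / sqrt(2)
  hi <- c(1, -1) / sqrt(2)
  letters <- strsplit(subband, "")[[1]]
  for (ax in 1:3) {
    k <- if (letters[ax] == "L") lo else hi
    x <- conv_axis(x, k, ax, origin = 1L)
  }
  x
}
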