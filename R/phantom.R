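#' Phantom specification
#'
#' Describes an agarose tube phantom: a set of cylindrical tubes with
#' physical geometry (mm) and per-tube 19F nuclei concentration (mM).
#' Signal is linear in 19F nuclei concentration, so tube contrast is set
#' entirely by `f19_concentration`.
#'
#' @param tubes a data.frame with one row per tube and columns
#'   `cx, cy, cz` (center, mm), `radius` (mm), `length` (mm) and
#'   `f19_concentration` (mM 19F nuclei). An optional `name` column labels
#'   the tubes. Tube axes default to the z (slice) direction; a full
#'   orientation matrix per tube is kept in `orientations`.
#' @param agent agent label, `"PFPE"` or `"PFCE"` (bookkeeping only; both
#'   scale linearly with 19F nuclei content).
#' @param orientations optional list of 3x3 rotation matrices, one per tube.
#' @param texture optional heterogeneity description: a list with `amp`
#'   (fractional amplitude of the intra-tube concentration modulation),
#'   `seed` (drives the per-tube random harmonics) and `n_modes`.
#'   `NULL` means perfectly homogeneous tubes.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(tubes, agent = c("PFPE", "PFCE"),
                         orientations = NULL, texture = NULL) {
  agent <- match.arg(agent)
  tubes <- as.data.frame(tubes)
  need <- c("cx", "cy", "cz", "radius", "length", "f19_concentration")
  if (!all(need %in% names(tubes)))
    stop("`tubes` must have columns ", paste(need, collapse = ", "))
  if (nrow(tubes) > 0) {
    if (any(tubes$radius <= 0) || any(tubes$length <= 0))
      stop("tube radii and lengths must be positive")
    if (any(tubes$f19_concentration < 0))
      stop("concentrations must be non-negative")
  }
  if (is.null(tubes$name))
    tubes$name <- if (nrow(tubes)) paste0("tube", seq_len(nrow(tubes))) else character()
  if (is.null(orientations))
    orientations <- replicate(nrow(tubes), diag(3), simplify = FALSE)
  if (!is.null(texture)) {
    stopifnot(is.list(texture), texture$amp >= 0)
    if (is.null(texture$n_modes)) texture$n_modes <- 4L
  }
  structure(list(tubes = tubes, agent = agent, orientations = orientations,
                 texture = texture),
            class = "phantom_spec")
}

#' Default five-tube phantom
#'
#' The study phantom layout: five identical 0.5-mL microcentrifuge tubes
#' in a holder within a 35 x 35 mm field of view - four
#' perfluorocarbon-loaded (two at 244 mM and two at 118 mM 19F nuclei)
#' plus one agarose-only control at 0 mM. The tubes share one geometry,
#' as in a real tube holder, so between-segment shape variance comes only
#' from where each tube sits on the voxel lattice. A mild (15%) smooth
#' concentration heterogeneity emulates nanoemulsion dispersion
#' inhomogeneity and gives texture features a reproducible substrate.
#'
#' @param agent `"PFPE"` or `"PFCE"`.
#' @param texture_seed seed for the per-tube heterogeneity harmonics.
#' @param texture_amp fractional amplitude of the heterogeneity field.
#' @return a `phantom_spec`.
#' @export
default_phantom <- function(agent = "PFPE", texture_seed = 1L, texture_amp = 0.15) {
  # grid is 64 x 64 x 12 at 0.55 x 0.55 x 1.5 mm -> 35.2 x 35.2 x 18 mm
  g <- c(35.2, 35.2, 18) / 2
  tubes <- data.frame(
    cx = g[1] + c(-8, 8, -8, 8, 0),
    cy = g[2] + c(-8, -8, 8, 8, 0),
    cz = g[3],
    radius = 3.0,
    length = 14,
    f19_concentration = c(244, 244, 118, 118, 0),
    name = c("tube1_high", "tube2_high", "tube3_low", "tube4_low", "control")
  )
  phantom_spec(tubes, agent,
               texture = list(amp = texture_amp, seed = as.integer(texture_seed),
                              n_modes = 4L))
}

#' Acquisition specification
#'
#' @param shape integer length-3 grid size in voxels (default 64 x 64 x 12,
#'   the 19F acquisition matrix).
#' @param spacing voxel spacing in mm.
#' @param gain signal gain, intensity units per mM 19F nuclei. The default
#'   (0.1) puts the weakest loaded tube (118 mM) at SNR ~ 12 against the
#'   default noise, comfortably above the SNR > 5 delineation requirement.
#' @param sigma Gaussian noise standard deviation per channel (intensity
#'   units) of the magnitude (Rician) noise model.
#' @param seed default noise seed recorded with acquisitions.
#' @param bias optional multiplicative bias field description (attached by
#'   [apply_session_perturbation()]).
#' @return object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(shape = c(64L, 64L, 12L), spacing = c(0.55, 0.55, 1.5),
                             gain = 0.1, sigma = 1.0, seed = NULL, bias = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("grid shape must be >= 1 per axis")
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (sigma < 0) stop("noise sigma must be >= 0")
  if (gain <= 0) stop("gain must be positive")
  structure(list(shape = shape, spacing = as.numeric(spacing), gain = gain,
                 sigma = sigma, seed = seed, bias = bias),
            class = "acquisition_spec")
}

#' Session perturbation
#'
#' Describes everything that changes between two sessions with complete
#' repositioning: a rigid transform of the sample, a multiplicative
#' low-order bias field (B1-like), a global gain factor (coil retuning)
#' and a noise-sigma drift factor. The all-identity perturbation denotes
#' intrasession conditions.
#'
#' @param translation mm, length 3.
#' @param rotation degrees about the x, y, z axes (applied z, then y,
#'   then x, about the grid center).
#' @param bias_amplitude maximum fractional deviation of the bias field.
#' @param gain_factor multiplies the acquisition gain (> 0).
#' @param sigma_factor multiplies the noise sigma (> 0).
#' @param seed drives the random bias-field polynomial coefficients.
#' @return object of class `session_perturbation`.
#' @export
session_perturbation <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                                 bias_amplitude = 0, gain_factor = 1,
                                 sigma_factor = 1, seed = 1L) {
  if (gain_factor <= 0) stop("gain factor must be positive")
  if (sigma_factor <= 0) stop("sigma factor must be positive")
  if (bias_amplitude < 0) stop("bias amplitude must be >= 0")
  structure(list(translation = as.numeric(translation),
                 rotation = as.numeric(rotation),
                 bias_amplitude = bias_amplitude, gain_factor = gain_factor,
                 sigma_factor = sigma_factor, seed = as.integer(seed)),
            class = "session_perturbation")
}

is_identity_perturbation <- function(p) {
  all(p$translation == 0) && all(p$rotation == 0) &&
    p$bias_amplitude == 0 && p$gain_factor == 1 && p$sigma_factor == 1
}

rotation_matrix <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Rx %*% Ry %*% Rz
}

# Physical coordinates (mm) of voxel centers along one axis.
axis_coords <- function(n, s) (seq_len(n) - 0.5) * s

# Per-tube smooth heterogeneity field in tube-local coordinates: a short sum
# of random-phase cosines, normalized so its standard deviation over the
# tube support is about `amp`. The harmonics are a pure function of
# (texture seed, tube index), so the field travels rigidly with the tube.
tube_texture_modes <- function(texture, tube_idx) {
  child <- as.integer((as.numeric(texture$seed) * 1009 + tube_idx) %% 2147483647)
  with_seed(child, {
    m <- texture$n_modes
    # wavelengths of 2.5 - 8 mm, random directions
    wl <- runif(m, 2.5, 8)
    dir <- matrix(rnorm(3 * m), m, 3)
    dir <- dir / sqrt(rowSums(dir^2))
    list(k = dir * (2 * pi / wl), phase = runif(m, 0, 2 * pi),
         amp = runif(m, 0.5, 1))
  })
}

eval_texture <- function(modes, q, amp) {
  f <- numeric(nrow(q))
  for (m in seq_along(modes$phase))
    f <- f + modes$amp[m] * cos(q %*% modes$k[m, ] + modes$phase[m])
  f <- as.numeric(f)
  rms <- sqrt(sum(modes$amp^2) / 2)   # RMS of the cosine sum
  amp * f / rms
}

# Evaluate the multiplicative bias field (product of per-axis quadratics,
# normalized to mean 1, scaled so max |deviation| equals the amplitude)
# on the acquisition grid.
bias_field <- function(bias, shape) {
  if (is.null(bias) || bias$amplitude == 0) return(NULL)
  co <- with_seed(bias$seed, matrix(runif(6, -1, 1), 3, 2))
  ax <- lapply(1:3, function(a) {
    t <- seq(-1, 1, length.out = shape[a])
    1 + co[a, 1] * t + co[a, 2] * t^2
  })
  f <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
  f <- f / mean(f)
  dev <- f - 1
  mx <- max(abs(dev))
  if (mx < 1e-12) return(NULL)
  1 + bias$amplitude * dev / mx
}

#' Render a noiseless phantom acquisition
#'
#' Voxel intensity equals gain x local 19F nuclei concentration; partial
#' volume at tube boundaries is handled by 3 x 3 x 3 subvoxel supersampling
#' of the cylinder indicator. Background is exactly zero. If a bias field
#' is attached to the acquisition (intersession conditions) the render is
#' multiplied by it.
#'
#' @param spec a `phantom_spec`.
#' @param acq an `acquisition_spec`.
#' @return a noiseless `scan_volume`.
#' @export
render_phantom <- function(spec, acq) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(acq, "acquisition_spec"))
  sh <- acq$shape; sp <- acq$spacing
  vol <- array(0, dim = sh)
  # subvoxel offsets (centers of a 3x3x3 subdivision)
  off1 <- c(-1, 0, 1) / 3
  offs <- as.matrix(expand.grid(x = off1 * sp[1], y = off1 * sp[2], z = off1 * sp[3]))
  for (ti in seq_len(nrow(spec$tubes))) {
    tube <- spec$tubes[ti, ]
    if (tube$f19_concentration == 0) next  # contributes exactly zero signal
    O <- spec$orientations[[ti]]
    ctr <- c(tube$cx, tube$cy, tube$cz)
    # bounding box of the tube in grid coordinates
    reach <- sqrt((tube$length / 2)^2 + tube$radius^2)
    lo <- pmax(1L, floor((ctr - reach) / sp - 1))
    hi <- pmin(sh, ceiling((ctr + reach) / sp + 1))
    if (any(lo > sh) || any(hi < 1L) || any(lo > hi)) {
      warning("tube '", tube$name, "' lies entirely outside the grid")
      next
    }
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    pts <- as.matrix(expand.grid(x = axis_coords(sh[1], sp[1])[ix],
                                 y = axis_coords(sh[2], sp[2])[iy],
                                 z = axis_coords(sh[3], sp[3])[iz]))
    frac <- numeric(nrow(pts))
    texsum <- numeric(nrow(pts))
    modes <- if (!is.null(spec$texture) && spec$texture$amp > 0)
      tube_texture_modes(spec$texture, ti) else NULL
    for (oi in seq_len(nrow(offs))) {
      qq <- sweep(pts, 2, ctr, "-")
      qq <- sweep(qq, 2, -offs[oi, ], "-")           # subvoxel positions - center
      loc <- qq %*% O                                 # into tube-local frame
      inside <- (loc[, 1]^2 + loc[, 2]^2 <= tube$radius^2) &
        (abs(loc[, 3]) <= tube$length / 2)
      frac <- frac + inside
      if (!is.null(modes) && any(inside)) {
        tx <- eval_texture(modes, loc[inside, , drop = FALSE], spec$texture$amp)
        texsum[inside] <- texsum[inside] + (1 + pmax(tx, -0.9))
      }
    }
    hit <- frac > 0
    if (!any(hit)) {
      warning("tube '", tube$name, "' lies entirely outside the grid")
      next
    }
    contrib <- numeric(nrow(pts))
    if (is.null(modes)) {
      contrib[hit] <- acq$gain * tube$f19_concentration * frac[hit] / nrow(offs)
    } else {
      contrib[hit] <- acq$gain * tube$f19_concentration * texsum[hit] / nrow(offs)
    }
    vol[ix, iy, iz] <- vol[ix, iy, iz] +
      array(contrib, dim = c(length(ix), length(iy), length(iz)))
  }
  bf <- bias_field(acq$bias, sh)
  if (!is.null(bf)) vol <- vol * bf
  scan_volume(vol, sp, meta = list(agent = spec$agent, noiseless = TRUE))
}

#' Add magnitude (Rician) noise to a volume
#'
#' Each voxel S is replaced by sqrt((S + g1)^2 + g2^2) with g1, g2
#' independent zero-mean Gaussians of standard deviation `sigma`; this is
#' the magnitude reconstruction noise model of MR images. Background
#' (S = 0) voxels then follow a Rayleigh law with mean sigma * sqrt(pi/2).
#'
#' @param vol a `scan_volume`.
#' @param sigma Gaussian channel SD; `0` returns the input unchanged.
#' @param seed noise seed (deterministic output for a given seed).
#' @return a `scan_volume` with non-negative intensities.
#' @export
add_rician_noise <- function(vol, sigma, seed = 1L) {
  stopifnot(inherits(vol, "scan_volume"))
  if (sigma < 0) stop("noise sigma must be >= 0")
  if (sigma == 0) return(vol)
  n <- length(vol$intensities)
  noisy <- with_seed(seed, {
    g1 <- rnorm(n, 0, sigma)
    g2 <- rnorm(n, 0, sigma)
    sqrt((as.vector(vol$intensities) + g1)^2 + g2^2)
  })
  out <- vol
  out$intensities <- array(noisy, dim = dim(vol$intensities))
  out$meta$noiseless <- NULL
  out$meta$sigma <- sigma
  out$meta$seed <- seed
  out
}

#' Acquire a pure-noise scan
#'
#' Renders an empty phantom and adds Rician noise: the slice-by-slice
#' calibration input for the segmentation noise floor.
#'
#' @param acq an `acquisition_spec`.
#' @param seed noise seed.
#' @return a `scan_volume` flagged `noise_only` in its metadata.
#' @export
acquire_noise_scan <- function(acq, seed = 1L) {
  empty <- phantom_spec(data.frame(cx = numeric(), cy = numeric(), cz = numeric(),
                                   radius = numeric(), length = numeric(),
                                   f19_concentration = numeric()))
  v <- render_phantom(empty, acq)
  v <- add_rician_noise(v, acq$sigma, seed)
  v$meta$noise_only <- TRUE
  v
}

#' Apply a session perturbation to a phantom/acquisition pair
#'
#' Rigidly transforms the tube geometry (rotation about the grid center,
#' then translation), multiplies the gain and noise sigma by their drift
#' factors, and attaches the bias-field description for multiplication
#' into subsequent renders. The perturbed spec is re-rendered analytically,
#' so the noiseless render stays exactly linear in concentration under any
#' rigid move.
#'
#' @param spec a `phantom_spec`.
#' @param acq an `acquisition_spec`.
#' @param pert a `session_perturbation`.
#' @return list with perturbed `spec` and `acq`.
#' @export
apply_session_perturbation <- function(spec, acq, pert) {
  stopifnot(inherits(pert, "session_perturbation"))
  R <- rotation_matrix(pert$rotation)
  ctr <- acq$shape * acq$spacing / 2
  tubes <- spec$tubes
  if (nrow(tubes)) {
    p <- t(R %*% (t(as.matrix(tubes[, c("cx", "cy", "cz")])) - ctr)) +
      matrix(ctr, nrow(tubes), 3, byrow = TRUE) +
      matrix(pert$translation, nrow(tubes), 3, byrow = TRUE)
    tubes$cx <- p[, 1]; tubes$cy <- p[, 2]; tubes$cz <- p[, 3]
    extent <- acq$shape * acq$spacing
    inside <- p[, 1] > 0 & p[, 1] < extent[1] &
      p[, 2] > 0 & p[, 2] < extent[2] & p[, 3] > 0 & p[, 3] < extent[3]
    if (!any(inside)) stop("perturbation moves all tubes outside the grid")
  }
  orients <- lapply(spec$orientations, function(O) R %*% O)
  spec2 <- spec
  spec2$tubes <- tubes
  spec2$orientations <- orients
  acq2 <- acq
  acq2$gain <- acq$gain * pert$gain_factor
  acq2$sigma <- acq$sigma * pert$sigma_factor
  if (pert$bias_amplitude > 0)
    acq2$bias <- list(amplitude = pert$bias_amplitude, seed = pert$seed)
  list(spec = spec2, acq = acq2)
}

#' Simulate a test-retest scan pair
#'
#' Intrasession: identical geometry, two independent noise realizations.
#' Intersession: the retest arm uses the perturbed spec (repositioning,
#' gain/bias/noise drift) plus a new noise seed.
#'
#' @param spec a `phantom_spec`.
#' @param acq an `acquisition_spec`.
#' @param mode `"intrasession"` or `"intersession"`.
#' @param pert a `session_perturbation`; required for intersession, must be
#'   absent or identity for intrasession.
#' @param seeds integer length-2 noise seeds for (test, retest).
#' @return list with `test` and `retest` scan volumes.
#' @export
simulate_test_retest <- function(spec, acq, mode = c("intrasession", "intersession"),
                                 pert = NULL, seeds = c(1L, 2L)) {
  mode <- match.arg(mode)
  if (mode == "intrasession") {
    if (!is.null(pert) && !is_identity_perturbation(pert))
      stop("intrasession pairs cannot carry a non-identity perturbation")
    base <- render_phantom(spec, acq)
    test <- add_rician_noise(base, acq$sigma, seeds[1])
    retest <- add_rician_noise(base, acq$sigma, seeds[2])
  } else {
    if (is.null(pert)) stop("intersession mode requires a session perturbation")
    base <- render_phantom(spec, acq)
    test <- add_rician_noise(base, acq$sigma, seeds[1])
    p <- apply_session_perturbation(spec, acq, pert)
    retest <- add_rician_noise(render_phantom(p$spec, p$acq), p$acq$sigma, seeds[2])
  }
  test$meta$arm <- "test"; test$meta$trial <- mode
  retest$meta$arm <- "retest"; retest$meta$trial <- mode
  list(test = test, retest = retest)
}

#' Render an in-vivo-like scene
#'
#' Builds a three-component scene on the acquisition grid: a large
#' ellipsoidal "liver" with heterogeneous sub-lobes, a smaller ellipsoidal
#' "tumor", and a cylindrical reference tube at a fixed 5 mM PFPE
#' (210 mM 19F nuclei) concentration. Each component gets internal texture
#' from a smoothed multiplicative noise field fixed by `scene_seed`, so
#' the anatomy is identical between the test and retest arms of the
#' intrasession pair.
#'
#' @param acq an `acquisition_spec`.
#' @param pert optional perturbation; `NULL` (the default, intrasession).
#' @param seeds integer length-2 noise seeds for (test, retest).
#' @param scene_seed seed fixing the anatomy and its texture.
#' @return list with `test`, `retest`, ground-truth integer `mask`
#'   (1 = liver, 2 = tumor, 3 = reference) and `priors` (expected segment
#'   centers/roles for delineation).
#' @export
render_invivo_scene <- function(acq, pert = NULL, seeds = c(1L, 2L), scene_seed = 7L) {
  sh <- acq$shape; sp <- acq$spacing
  ext <- sh * sp
  x <- axis_coords(sh[1], sp[1]); y <- axis_coords(sh[2], sp[2]); z <- axis_coords(sh[3], sp[3])
  X <- array(rep(x, times = sh[2] * sh[3]), dim = sh)
  Y <- array(rep(rep(y, each = sh[1]), times = sh[3]), dim = sh)
  Z <- array(rep(z, each = sh[1] * sh[2]), dim = sh)
  ellipsoid <- function(c0, r0) ((X - c0[1]) / r0[1])^2 + ((Y - c0[2]) / r0[2])^2 +
    ((Z - c0[3]) / r0[3])^2 <= 1
  liver_c <- c(0.38, 0.45, 0.5) * ext
  liver <- ellipsoid(liver_c, c(9, 7, 7.5))
  lobe <- ellipsoid(liver_c + c(5, 3, 1), c(5, 4, 5))
  tumor_c <- c(0.72, 0.68, 0.5) * ext
  tumor <- ellipsoid(tumor_c, c(4.5, 4, 5.5))
  ref_c <- c(0.78, 0.22, 0.5) * ext
  ref <- ((X - ref_c[1])^2 + (Y - ref_c[2])^2 <= 2.2^2) & (abs(Z - ref_c[3]) <= 7)
  tumor[liver] <- FALSE  # disjoint components
  ref[liver | tumor] <- FALSE
  # concentration map (mM 19F nuclei): liver accumulates the most tracer,
  # tumor less, reference tube 5 mM PFPE = 210 mM 19F nuclei
  conc <- array(0, dim = sh)
  conc[liver] <- 180
  conc[liver & lobe] <- 230   # heterogeneous sub-lobe
  conc[tumor] <- 130
  conc[ref] <- 210
  # smoothed multiplicative noise texture, fixed by the scene seed
  tex <- with_seed(scene_seed, array(rnorm(prod(sh)), dim = sh))
  tex <- gauss_smooth3(tex, sigma_vox = c(1.5, 1.5, 0.8))
  tex <- 1 + 0.18 * tex / stats::sd(tex)
  noiseless <- conc * acq$gain * pmax(tex, 0.1)
  mask <- array(0L, dim = sh)
  mask[liver] <- 1L; mask[tumor] <- 2L; mask[ref] <- 3L
  if (!is.null(pert) && !is_identity_perturbation(pert))
    stop("the in-vivo arm is intrasession-only")
  base <- scan_volume(noiseless, sp, meta = list(experiment = "invivo"))
  test <- add_rician_noise(base, acq$sigma, seeds[1])
  retest <- add_rician_noise(base, acq$sigma, seeds[2])
  test$meta$arm <- "test"; retest$meta$arm <- "retest"
  test$meta$trial <- retest$meta$trial <- "intrasession"
  priors <- data.frame(
    role = c("liver", "tumor", "reference"),
    cx = c(liver_c[1], tumor_c[1], ref_c[1]),
    cy = c(liver_c[2], tumor_c[2], ref_c[2]),
    cz = c(liver_c[3], tumor_c[3], ref_c[3]),
    match_radius = c(10, 7, 5)
  )
  list(test = test, retest = retest, mask = mask, priors = priors)
}

#' Detection-limit calibration series
#'
#' Renders a single tube at each requested concentration, acquires
#' `replicates` noisy scans per concentration, and reports the mean and SD
#' of the ROI mean intensity. The detection floor is the smallest
#' concentration whose mean ROI intensity exceeds five times the standard
#' deviation of the background noise (measured on pure-noise scans).
#'
#' @param concentrations mM 19F nuclei, at least one value.
#' @param acq an `acquisition_spec`.
#' @param replicates number of noise replicates per concentration (>= 2).
#' @param seed master seed for the replicate noise seeds.
#' @return list with `table` (concentration, mean, sd, detected),
#'   `floor` (mM), and `threshold` (5 x noise SD, intensity units).
#' @export
detection_series <- function(concentrations, acq, replicates = 3L, seed = 1L) {
  if (length(concentrations) == 0) stop("empty concentration list")
  if (replicates < 2) stop("need at least 2 replicates")
  ctr <- acq$shape * acq$spacing / 2
  seeds <- expand_seeds(seed, replicates * length(concentrations) + replicates)
  # background noise SD from pure-noise scans
  nz <- unlist(lapply(seq_len(replicates), function(i)
    as.vector(acquire_noise_scan(acq, seeds[i])$intensities)))
  noise_sd <- stats::sd(nz)
  thr <- 5 * noise_sd
  rows <- lapply(seq_along(concentrations), function(ci) {
    conc <- concentrations[ci]
    tubes <- data.frame(cx = ctr[1], cy = ctr[2], cz = ctr[3], radius = 3,
                        length = 12, f19_concentration = conc)
    spec <- phantom_spec(tubes)
    base <- render_phantom(spec, acq)
    roi <- base$intensities > 0 | conc == 0
    if (conc == 0) {  # ROI where the tube would be
      tubes$f19_concentration <- 1
      roi <- render_phantom(phantom_spec(tubes), acq)$intensities > 0.5 * acq$gain
    }
    means <- vapply(seq_len(replicates), function(ri) {
      s <- seeds[replicates + (ci - 1L) * replicates + ri]
      mean(add_rician_noise(base, acq$sigma, s)$intensities[roi])
    }, 0)
    data.frame(concentration = conc, mean = mean(means), sd = stats::sd(means))
  })
  tab <- do.call(rbind, rows)
  tab$detected <- tab$mean > thr
  det <- tab$concentration[tab$detected]
  list(table = tab, floor = if (length(det)) min(det) else NA_real_,
       threshold = thr)
}
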