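#' Slice-wise noise-floor estimation
#'
#' Computes the per-slice average noise level (the threshold base
#' `N_average`) and its SD from a pure-noise acquisition, slice by slice.
#'
#' @param noise_scan a noise-only `scan_volume`.
#' @return a `noise_profile` data.frame with columns `slice`, `n_average`,
#'   `sd`.
#' @export
estimate_noise <- function(noise_scan) {
  stopifnot(inherits(noise_scan, "scan_volume"))
  d <- dim(noise_scan$intensities)
  if (prod(d[1:2]) == 0) stop("empty slice")
  prof <- data.frame(
    slice = seq_len(d[3]),
    n_average = vapply(seq_len(d[3]),
                       function(k) mean(noise_scan$intensities[, , k]), 0),
    sd = vapply(seq_len(d[3]),
                function(k) stats::sd(as.vector(noise_scan$intensities[, , k])), 0)
  )
  class(prof) <- c("noise_profile", "data.frame")
  prof
}

#' Noise-floor thresholding
#'
#' Keeps a voxel iff its intensity is at least `k` times the slice's
#' average noise level: the standard semi-automatic first step that
#' separates true 19F signal from background. The threshold is applied
#' per slice.
#'
#' @param scan a `scan_volume`.
#' @param profile a `noise_profile` with one row per slice of `scan`.
#' @param k threshold multiplier (default 3; with Rayleigh background this
#'   exceeds five times the noise SD).
#' @return binary integer array of the same dimension as the scan.
#' @export
threshold_mask <- function(scan, profile, k = 3) {
  d <- dim(scan$intensities)
  if (nrow(profile) != d[3])
    stop("noise profile has ", nrow(profile), " slices but scan has ", d[3])
  thr <- rep(profile$n_average * k, each = prod(d[1:2]))
  array(as.integer(as.vector(scan$intensities) >= thr), dim = d)
}

#' Delineate regions of interest within a thresholded mask
#'
#' Replaces the blinded observer of the two-step segmentation: connected
#' components (26-connectivity) of the threshold mask are assigned to the
#' expected region (prior) whose center is nearest to the component
#' centroid, provided the centroid falls within the prior's match radius.
#' Components matching no prior are dropped (artifact exclusion); several
#' components nearest to one prior are merged into one segment. Priors
#' matched by no component are recorded as missing segments.
#'
#' @param mask binary integer array (from [threshold_mask()]).
#' @param priors data.frame with columns `role`, `cx`, `cy`, `cz` (mm) and
#'   `match_radius` (mm).
#' @param spacing voxel spacing in mm.
#' @param min_size components below this voxel count are treated as noise
#'   specks and excluded, as an observer would.
#' @return a `segment_mask`: list with integer `labels` (0 background),
#'   `segments` (id, role), `missing` (roles), and the `support` mask.
#' @export
delineate_rois <- function(mask, priors, spacing = c(0.55, 0.55, 1.5),
                           min_size = 3L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  need <- c("role", "cx", "cy", "cz", "match_radius")
  if (!all(need %in% names(priors)))
    stop("priors must have columns ", paste(need, collapse = ", "))
  d <- dim(mask)
  comp <- .cpp_label3d(as.integer(mask != 0), as.integer(d), 26L)
  ncomp <- attr(comp, "n_components")
  labels <- array(0L, d)
  assigned <- integer(0)
  if (ncomp > 0) {
    comp <- array(comp, d)
    centers <- as.matrix(priors[, c("cx", "cy", "cz")])
    for (ci in seq_len(ncomp)) {
      idx <- which(comp == ci, arr.ind = TRUE)
      if (nrow(idx) < min_size) next
      centroid <- colMeans(sweep(idx, 2, spacing, "*") -
                             matrix(spacing / 2, nrow(idx), 3, byrow = TRUE))
      dd <- sqrt(rowSums(sweep(centers, 2, centroid, "-")^2))
      pi_ <- which.min(dd)
      if (dd[pi_] <= priors$match_radius[pi_]) {
        labels[comp == ci] <- pi_
        assigned <- union(assigned, pi_)
      }
    }
  }
  present <- sort(assigned)
  segments <- data.frame(id = present, role = priors$role[present],
                         stringsAsFactors = FALSE)
  missing <- setdiff(priors$role, segments$role)
  structure(list(labels = labels, segments = segments, missing = missing,
                 support = array(as.integer(mask != 0), d), spacing = spacing),
            class = "segment_mask")
}

#' @export
print.segment_mask <- function(x, ...) {
  cat(sprintf("<segment_mask> %d segments (%s)\n", nrow(x$segments),
              paste(x$segments$role, collapse = ", ")))
  if (length(x$missing))
    cat("  missing:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' Expected-region priors from a phantom specification
#'
#' @param spec a `phantom_spec`; each tube becomes a prior at its center
#'   with a match radius of tube radius + `slack` mm.
#' @param slack added to the tube radius (mm).
#' @return priors data.frame for [delineate_rois()].
#' @export
phantom_priors <- function(spec, slack = 2) {
  data.frame(role = spec$tubes$name, cx = spec$tubes$cx, cy = spec$tubes$cy,
             cz = spec$tubes$cz, match_radius = spec$tubes$radius + slack,
             stringsAsFactors = FALSE)
}

#' Simulated re-delineation (reader perturbation)
#'
#' Emulates a repeated manual delineation: a random fraction of each
#' segment's boundary voxels is eroded, and a random fraction of the
#' adjacent voxels still inside the threshold mask is dilated into the
#' segment. The perturbed segmentation never exceeds the threshold mask;
#' magnitude 0 returns the identical mask.
#'
#' @param segmask a `segment_mask`.
#' @param magnitude fraction in `[0, 1]` controlling boundary jitter.
#' @param seed RNG seed.
#' @return a perturbed `segment_mask`.
#' @export
reader_perturb <- function(segmask, magnitude, seed = 1L) {
  stopifnot(inherits(segmask, "segment_mask"), magnitude >= 0)
  if (magnitude == 0) return(segmask)
  labels <- segmask$labels
  with_seed(seed, {
    for (seg_id in segmask$segments$id) {
      m <- labels == seg_id
      if (!any(m)) next
      bnd <- boundary_mask(m)
      # erode: drop a random subset of boundary voxels
      bidx <- which(bnd)
      drop <- bidx[stats::runif(length(bidx)) < magnitude / 2]
      # dilate: add unlabeled support voxels 6-adjacent to the segment
      grown <- m
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        dvec <- c(0L, 0L, 0L); dvec[ax] <- s
        grown <- grown | shift_pad0(m, dvec)
      }
      cand <- which(grown & !m & segmask$support == 1L & labels == 0L)
      add <- cand[stats::runif(length(cand)) < magnitude / 2]
      labels[drop] <- 0L
      labels[add] <- seg_id
    }
  })
  out <- segmask
  out$labels <- labels
  out
}

#' Scan/segment bookkeeping manifest
#'
#' Tabulates scans and segments per experiment and trial type and forms
#' the grand totals, the way study designs report their acquisition
#' counts. Phantom scans carry one segment per loaded tube; in-vivo scans
#' carry liver, tumor and reference-tube segments.
#'
#' @param experiments data.frame with columns `experiment`, `trial`
#'   (`"intrasession"`/`"intersession"`), `scans`, `segments_per_scan`.
#' @return an `experiment_manifest` data.frame (with per-row `segments`)
#'   carrying a `totals` attribute (per-experiment and grand totals).
#' @export
build_manifest <- function(experiments = manifest_config()) {
  e <- as.data.frame(experiments)
  need <- c("experiment", "trial", "scans", "segments_per_scan")
  if (!all(need %in% names(e)))
    stop("experiments must have columns ", paste(need, collapse = ", "))
  e$segments <- e$scans * e$segments_per_scan
  per_exp <- aggregate(cbind(scans, segments) ~ experiment, data = e, FUN = sum)
  totals <- list(per_experiment = per_exp,
                 scans = sum(e$scans), segments = sum(e$segments))
  structure(e, totals = totals, class = c("experiment_manifest", "data.frame"))
}

#' Study manifest configuration matching the published design
#'
#' 18 intrasession + 36 intersession PFPE phantom scans (4 tubes each),
#' 68 + 68 PFCE phantom scans (4 tubes each), and 4 in-vivo scans
#' (3 regions each).
#'
#' @return data.frame accepted by [build_manifest()].
#' @export
manifest_config <- function() {
  data.frame(
    experiment = c("PFPE", "PFPE", "PFCE", "PFCE", "invivo"),
    trial = c("intrasession", "intersession", "intrasession", "intersession",
              "intrasession"),
    scans = c(18L, 36L, 68L, 68L, 4L),
    segments_per_scan = c(4L, 4L, 4L, 4L, 3L),
    stringsAsFactors = FALSE
  )
}

#' @export
print.experiment_manifest <- function(x, ...) {
  tt <- attr(x, "totals")
  print.data.frame(x)
  cat(sprintf("totals: %d scans, %d segments\n", tt$scans, tt$segments))
  invisible(x)
}
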