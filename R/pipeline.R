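#' Study configuration
#'
#' Describes a full simulated repeatability study: which experiments to
#' run (phantom agents and the in-vivo arm), how many test-retest pairs
#' per trial type, the acquisition, the intersession perturbation
#' magnitudes, the feature-extraction configuration and the stability
#' thresholds. The defaults are a desk-scale replica of the published
#' design: 8 intrasession and 8 intersession pairs per phantom and 2
#' in-vivo intrasession pairs (one per animal), with repositioning drawn
#' uniformly within +-1 mm in-plane, +-1.5 mm through-plane and +-1/1/3
#' degrees, a 5% bias-field amplitude, and +-5% gain and noise drift.
#'
#' @param agents phantom agents to simulate.
#' @param n_intra,n_inter test-retest pairs per phantom per trial type.
#' @param n_invivo in-vivo intrasession pairs (0 disables the arm).
#' @param acq an [acquisition_spec()].
#' @param perturbation list of intersession magnitude bounds:
#'   `translation` (mm, per axis), `rotation` (degrees, per axis),
#'   `bias_amplitude`, `gain_range`, `sigma_range` (fractional).
#' @param features an [extraction_config()].
#' @param ccc_min,ndr_min stability thresholds.
#' @param k segmentation threshold multiplier.
#' @param seed master seed; every scan-level seed derives from it.
#' @return list of class `study_config`.
#' @export
study_config <- function(agents = c("PFPE", "PFCE"), n_intra = 8L, n_inter = 8L,
                         n_invivo = 2L, acq = acquisition_spec(),
                         perturbation = list(translation = c(1, 1, 1.5),
                                             rotation = c(1, 1, 3),
                                             bias_amplitude = 0.05,
                                             gain_range = 0.05,
                                             sigma_range = 0.05),
                         features = extraction_config(),
                         ccc_min = 0.85, ndr_min = 0.90, k = 3,
                         seed = 20260101L) {
  stopifnot(n_intra >= 1 || n_inter >= 1 || n_invivo >= 1)
  if (n_inter >= 1 && is.null(perturbation))
    stop("intersession blocks require perturbation magnitudes")
  structure(list(agents = agents, n_intra = as.integer(n_intra),
                 n_inter = as.integer(n_inter), n_invivo = as.integer(n_invivo),
                 acq = acq, perturbation = perturbation, features = features,
                 ccc_min = ccc_min, ndr_min = ndr_min, k = k,
                 seed = as.integer(seed)),
            class = "study_config")
}

# Draw one concrete intersession perturbation from the magnitude bounds.
draw_perturbation <- function(mag, seed) {
  with_seed(seed, {
    session_perturbation(
      translation = stats::runif(3, -mag$translation, mag$translation),
      rotation = stats::runif(3, -mag$rotation, mag$rotation),
      bias_amplitude = mag$bias_amplitude,
      gain_factor = stats::runif(1, 1 - mag$gain_range, 1 + mag$gain_range),
      sigma_factor = stats::runif(1, 1 - mag$sigma_range, 1 + mag$sigma_range),
      seed = seed
    )
  })
}

# Segment one scan: slice-wise threshold at k x N_average, then
# prior-guided delineation. With a zero measured noise floor (noiseless
# acquisition) the threshold degenerates to 0 and would keep the empty
# background; any strictly positive voxel is then unambiguous signal.
segment_scan <- function(scan, profile, priors, k) {
  mask <- if (all(profile$n_average == 0))
    array(as.integer(scan$intensities > 0), dim(scan$intensities))
  else threshold_mask(scan, profile, k)
  delineate_rois(mask, priors, scan$spacing)
}

# Extract one arm of one pair, returning features + per-segment raw
# intensities (for the normalization check).
extract_arm <- function(scan, segmask, cfg, meta) {
  ft <- extract_all(scan, segmask, cfg$features, meta = meta)
  vals <- lapply(segmask$segments$id, function(id)
    scan$intensities[segmask$labels == id])
  names(vals) <- segmask$segments$role
  list(features = ft, values = vals)
}

run_phantom_experiment <- function(cfg, agent, exp_seed) {
  acq <- cfg$acq
  spec <- default_phantom(agent, texture_seed = exp_seed)
  priors <- phantom_priors(spec)
  base <- render_phantom(spec, acq)
  nb <- 2L * (cfg$n_intra + cfg$n_inter)  # noise seeds for the paired arms
  seeds <- expand_seeds(exp_seed, nb + 2L + cfg$n_inter)
  profile <- estimate_noise(acquire_noise_scan(acq, seeds[nb + 1L]))
  arms <- list(test = list(), retest = list())
  tables <- list()
  jsd_pairs <- list(intrasession = list(), intersession = list())
  si <- 0L
  for (trial in c("intrasession", "intersession")) {
    n_pairs <- if (trial == "intrasession") cfg$n_intra else cfg$n_inter
    if (n_pairs == 0) next
    tt <- list(); rr <- list()
    for (p in seq_len(n_pairs)) {
      s1 <- seeds[si + 1L]; s2 <- seeds[si + 2L]; si <- si + 2L
      test <- add_rician_noise(base, acq$sigma, s1)
      if (trial == "intrasession") {
        retest <- add_rician_noise(base, acq$sigma, s2)
        prof_r <- profile
        priors_r <- priors
      } else {
        pert <- draw_perturbation(cfg$perturbation, seeds[nb + 2L + p])
        pp <- apply_session_perturbation(spec, acq, pert)
        retest <- add_rician_noise(render_phantom(pp$spec, pp$acq),
                                   pp$acq$sigma, s2)
        prof_r <- estimate_noise(acquire_noise_scan(pp$acq, s2 + 1L))
        priors_r <- phantom_priors(pp$spec)
      }
      meta_t <- list(scan_id = sprintf("%s_%s_p%02d_test", agent, trial, p),
                     pair_id = p, arm = "test", trial = trial)
      meta_r <- list(scan_id = sprintf("%s_%s_p%02d_retest", agent, trial, p),
                     pair_id = p, arm = "retest", trial = trial)
      seg_t <- segment_scan(test, profile, priors, cfg$k)
      seg_r <- segment_scan(retest, prof_r, priors_r, cfg$k)
      et <- extract_arm(test, seg_t, cfg, meta_t)
      er <- extract_arm(retest, seg_r, cfg, meta_r)
      tt[[p]] <- et$features; rr[[p]] <- er$features
      common <- intersect(names(et$values), names(er$values))
      jsd_pairs[[trial]][[p]] <- list(test = et$values[common],
                                      retest = er$values[common])
    }
    test_ft <- do.call(rbind, tt)
    retest_ft <- do.call(rbind, rr)
    tables[[trial]] <- agreement_table(test_ft, retest_ft,
                                       ccc_min = cfg$ccc_min,
                                       ndr_min = cfg$ndr_min)
    arms$test[[trial]] <- test_ft
    arms$retest[[trial]] <- retest_ft
  }
  list(agent = agent, tables = tables, features = arms, jsd_pairs = jsd_pairs)
}

run_invivo_experiment <- function(cfg, exp_seed) {
  acq <- cfg$acq
  seeds <- expand_seeds(exp_seed, 3L * cfg$n_invivo + 1L)
  profile <- estimate_noise(acquire_noise_scan(acq, seeds[3L * cfg$n_invivo + 1L]))
  tt <- list(); rr <- list(); jsd <- list()
  for (p in seq_len(cfg$n_invivo)) {
    sc <- render_invivo_scene(acq, seeds = seeds[c(3L * p - 2L, 3L * p - 1L)],
                              scene_seed = seeds[3L * p])
    seg_t <- segment_scan(sc$test, profile, sc$priors, cfg$k)
    seg_r <- segment_scan(sc$retest, profile, sc$priors, cfg$k)
    et <- extract_arm(sc$test, seg_t, cfg,
                      list(scan_id = sprintf("invivo_p%02d_test", p),
                           pair_id = p, arm = "test", trial = "intrasession"))
    er <- extract_arm(sc$retest, seg_r, cfg,
                      list(scan_id = sprintf("invivo_p%02d_retest", p),
                           pair_id = p, arm = "retest", trial = "intrasession"))
    tt[[p]] <- et$features; rr[[p]] <- er$features
    common <- intersect(names(et$values), names(er$values))
    jsd[[p]] <- list(test = et$values[common], retest = er$values[common])
  }
  test_ft <- do.call(rbind, tt)
  retest_ft <- do.call(rbind, rr)
  list(agent = "invivo",
       tables = list(intrasession = agreement_table(test_ft, retest_ft,
                                                    ccc_min = cfg$ccc_min,
                                                    ndr_min = cfg$ndr_min)),
       features = list(test = list(intrasession = test_ft),
                       retest = list(intrasession = retest_ft)),
       jsd_pairs = list(intrasession = jsd))
}

# Per-class median (IQR) summary of one agreement table (Table 2 analog).
class_summary <- function(at) {
  ok <- !at$degenerate & !is.na(at$ccc)
  strata <- c(overall = list(at$ccc[ok]),
              split(at$ccc[ok], at$class[ok]))
  do.call(rbind, lapply(names(strata), function(nm) {
    v <- strata[[nm]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(stratum = nm, n = length(v), median_ccc = q[2],
               iqr_lo = q[1], iqr_hi = q[3])
  }))
}

# Stable counts and fractions per class (Table 3 analog).
stable_summary <- function(at) {
  cls <- c("overall", sort(unique(at$class)))
  do.call(rbind, lapply(cls, function(nm) {
    sub <- if (nm == "overall") at else at[at$class == nm, ]
    data.frame(class = nm, stable = sum(sub$stable), total = nrow(sub),
               fraction = sum(sub$stable) / nrow(sub))
  }))
}

#' Intersect stable-feature sets
#'
#' Computes all pairwise intersections and the full multiway core of named
#' stable-feature sets over a common feature universe.
#'
#' @param sets named list of character vectors (feature names).
#' @param universe character vector containing every feature of every set.
#' @return list with `sizes`, `pairwise` (count matrix), `core`
#'   (character), `core_size` and `proportions` (set size / universe size).
#' @export
intersect_stable_sets <- function(sets, universe) {
  stopifnot(length(sets) >= 1, !is.null(names(sets)))
  for (nm in names(sets))
    if (!all(sets[[nm]] %in% universe))
      stop("set '", nm, "' contains features outside the universe")
  k <- length(sets)
  pw <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k))
    pw[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  core <- Reduce(intersect, sets)
  list(sizes = lengths(sets), pairwise = pw, core = core,
       core_size = length(core),
       proportions = lengths(sets) / length(universe))
}

#' Stability-count sensitivity grid
#'
#' Number of stable features for every pair of thresholds on a CCC x NDR
#' grid; monotone nonincreasing along both axes by construction of the
#' conjunctive call.
#'
#' @param at an `agreement_table`.
#' @param ccc_grid,ndr_grid threshold grids within `(0, 1]`.
#' @return integer matrix (rows = CCC thresholds, columns = NDR).
#' @export
sensitivity_grid <- function(at, ccc_grid = seq(0.75, 0.90, by = 0.05),
                             ndr_grid = seq(0.85, 0.95, by = 0.05)) {
  stopifnot(all(ccc_grid > 0 & ccc_grid <= 1), all(ndr_grid > 0 & ndr_grid <= 1))
  out <- matrix(0L, length(ccc_grid), length(ndr_grid),
                dimnames = list(sprintf("ccc>=%.2f", ccc_grid),
                                sprintf("ndr>=%.2f", ndr_grid)))
  ok <- !at$degenerate
  for (i in seq_along(ccc_grid)) for (j in seq_along(ndr_grid))
    out[i, j] <- sum(stability_call(at$ccc, at$ndr, ccc_grid[i], ndr_grid[j]) &
                       ok, na.rm = TRUE)
  out
}

#' Run a full simulated repeatability study
#'
#' Simulate, segment, extract, pair, score and summarize: for every
#' configured experiment and trial type the pipeline builds test-retest
#' feature tables, per-feature CCC/NDR stability calls, per-class
#' median (IQR) CCC summaries, stable-count tables, the stable-set
#' intersection lattice, per-arm threshold sensitivity grids and the
#' histogram-normalization check. Fully deterministic given the master
#' seed.
#'
#' @param cfg a [study_config()].
#' @param verbose print stage progress.
#' @return list of class `study_result`; see the individual components
#'   (`agreement`, `class_tables`, `stable_tables`, `intersections`,
#'   `sensitivity`, `normalization`, `manifest`).
#' @export
run_study <- function(cfg = study_config(), verbose = FALSE) {
  stopifnot(inherits(cfg, "study_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  exp_seeds <- expand_seeds(cfg$seed, length(cfg$agents) + 1L)
  experiments <- list()
  for (ai in seq_along(cfg$agents)) {
    say("simulating %s phantom experiment", cfg$agents[ai])
    experiments[[cfg$agents[ai]]] <-
      run_phantom_experiment(cfg, cfg$agents[ai], exp_seeds[ai])
  }
  if (cfg$n_invivo > 0) {
    say("simulating in-vivo experiment")
    experiments$invivo <- run_invivo_experiment(cfg, exp_seeds[length(exp_seeds)])
  }
  # flat agreement tables keyed "<experiment>_<trial>"
  agreement <- list()
  for (nm in names(experiments))
    for (trial in names(experiments[[nm]]$tables))
      agreement[[paste(nm, trial, sep = "_")]] <- experiments[[nm]]$tables[[trial]]
  class_tables <- lapply(agreement, class_summary)
  stable_tables <- lapply(agreement, stable_summary)
  comparisons <- lapply(agreement, function(at) {
    ok <- !at$degenerate & !is.na(at$ccc)
    class_vs_overall(split(at$ccc[ok], at$class[ok]), at$ccc[ok])
  })
  stable_sets <- lapply(agreement, function(at) at$feature[at$stable])
  universe <- agreement[[1]]$feature
  phantom_arms <- grep("^(PFPE|PFCE)_", names(stable_sets), value = TRUE)
  intersections <- list(
    per_arm = intersect_stable_sets(stable_sets, universe),
    phantom_core = intersect_stable_sets(stable_sets[phantom_arms], universe)
  )
  if ("invivo_intrasession" %in% names(stable_sets)) {
    iv <- stable_sets$invivo_intrasession
    core <- intersections$phantom_core$core
    intersections$invivo_overlap <- list(
      phantom_core = length(core),
      also_stable_invivo = length(intersect(core, iv)),
      fraction = if (length(core)) length(intersect(core, iv)) / length(core)
                 else NA_real_)
  }
  sensitivity <- lapply(agreement, sensitivity_grid)
  normalization <- list()
  for (nm in names(experiments))
    for (trial in names(experiments[[nm]]$jsd_pairs)) {
      jp <- experiments[[nm]]$jsd_pairs[[trial]]
      if (length(jp))
        normalization[[paste(nm, trial, sep = "_")]] <- normalization_check(jp)
    }
  # bookkeeping of what was actually simulated
  rows <- list()
  for (nm in names(experiments)) {
    ex <- experiments[[nm]]
    for (trial in names(ex$features$test)) {
      ft <- rbind(ex$features$test[[trial]], ex$features$retest[[trial]])
      rows[[paste(nm, trial)]] <- data.frame(
        experiment = nm, trial = trial,
        scans = length(unique(ft$scan_id)),
        segments_per_scan = round(nrow(ft) / length(unique(ft$scan_id))))
    }
  }
  manifest <- build_manifest(do.call(rbind, rows))
  structure(list(config = cfg, agreement = agreement,
                 class_tables = class_tables, stable_tables = stable_tables,
                 comparisons = comparisons, intersections = intersections,
                 sensitivity = sensitivity, normalization = normalization,
                 manifest = manifest, features = lapply(experiments, `[[`,
                                                        "features")),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>\n")
  for (nm in names(x$agreement)) {
    at <- x$agreement[[nm]]
    ok <- !at$degenerate & !is.na(at$ccc)
    cat(sprintf("  %-22s median CCC %.3f, stable %d/%d (%.1f%%)\n", nm,
                stats::median(at$ccc[ok]), sum(at$stable), nrow(at),
                100 * mean(at$stable)))
  }
  cat(sprintf("  phantom-core stable features: %d\n",
              x$intersections$phantom_core$core_size))
  if (!is.null(x$intersections$invivo_overlap))
    cat(sprintf("  of those stable in vivo: %d (%.1f%%)\n",
                x$intersections$invivo_overlap$also_stable_invivo,
                100 * x$intersections$invivo_overlap$fraction))
  invisible(x)
}

#' Write study artifacts to disk
#'
#' Emits the manifest, per-arm agreement tables, class and stable-count
#' summaries, sensitivity grids (CSV) and an overall JSON summary into
#' `outdir`. Re-running on the same results is idempotent.
#'
#' @param results a `study_result`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
report_study <- function(results, outdir) {
  stopifnot(inherits(results, "study_result"))
  if (!dir.exists(outdir))
    if (!dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", outdir)
  w <- function(df, nm) utils::write.csv(df, file.path(outdir, nm),
                                         row.names = FALSE)
  mf <- as.data.frame(results$manifest)
  w(mf, "manifest.csv")
  for (nm in names(results$agreement))
    w(as.data.frame(results$agreement[[nm]]), sprintf("agreement_%s.csv", nm))
  w(do.call(rbind, lapply(names(results$class_tables), function(nm)
    cbind(arm = nm, results$class_tables[[nm]]))), "class_medians.csv")
  w(do.call(rbind, lapply(names(results$stable_tables), function(nm)
    cbind(arm = nm, results$stable_tables[[nm]]))), "stable_counts.csv")
  for (nm in names(results$sensitivity))
    utils::write.csv(results$sensitivity[[nm]],
                     file.path(outdir, sprintf("sensitivity_%s.csv", nm)))
  summary <- list(
    arms = lapply(results$agreement, function(at) {
      ok <- !at$degenerate & !is.na(at$ccc)
      list(median_ccc = stats::median(at$ccc[ok]), stable = sum(at$stable),
           total = nrow(at))
    }),
    phantom_core = results$intersections$phantom_core$core_size,
    invivo_overlap = results$intersections$invivo_overlap,
    normalization = results$normalization,
    seed = results$config$seed
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
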