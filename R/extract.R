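#' Feature extraction configuration
#'
#' @param filters list of [filter_spec()] objects (default [default_filters()]).
#' @param discretization a [discretization_spec()] (default 32 fixed bins).
#' @param gldm_alpha GLDM dependence tolerance.
#' @return list of class `extraction_config`.
#' @export
extraction_config <- function(filters = default_filters(),
                              discretization = discretization_spec(),
                              gldm_alpha = 0L) {
  structure(list(filters = filters, discretization = discretization,
                 gldm_alpha = as.integer(gldm_alpha)),
            class = "extraction_config")
}

texture_families <- c("GLCM", "GLRLM", "GLSZM", "GLDM", "NGTDM")

# deterministic column order of one extraction run
feature_column_names <- function(config) {
  cols <- character()
  for (f in config$filters) {
    if (f$label == "original")
      cols <- c(cols, paste0("original_shape_",
                             names(shape_features(array(1, c(2, 2, 2))))))
    cols <- c(cols, paste0(f$label, "_firstorder_",
                           names(firstorder_features(c(1, 2)))))
    for (fam in texture_families)
      cols <- c(cols, paste0(f$label, "_", tolower(fam), "_",
                             texture_feature_names(fam)))
  }
  cols
}

# features of one segment on one (already filtered) volume
segment_features_one <- function(filtered, segmask_arr, seg_id, config) {
  inseg <- segmask_arr == seg_id
  vals <- filtered$intensities[inseg]
  out <- firstorder_features(vals, voxel_volume = voxel_volume(filtered),
                             d = config$discretization)
  names(out) <- paste0("firstorder_", names(out))
  # level array restricted to the segment bounding box
  idx <- which(inseg, arr.ind = TRUE)
  rng <- apply(idx, 2, range)
  sub <- inseg[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3],
               drop = FALSE]
  # `vals` and `lev[sub]` both follow column-major order of the same voxels
  dsc <- discretize(vals, config$discretization)
  lev <- array(0L, dim(sub))
  lev[sub] <- dsc$levels
  for (fam in texture_families) {
    m <- texture_matrix(fam, lev, ng = dsc$ng, alpha = config$gldm_alpha)
    fv <- texture_features(fam, m)
    names(fv) <- paste0(tolower(fam), "_", names(fv))
    out <- c(out, fv)
  }
  out
}

#' Extract the full radiomic feature table of a scan
#'
#' For every segment and every configured filter: 18 first-order and the
#' five texture families; 14 shape features once per segment (under the
#' original filter only). Each filtered volume is computed once and reused
#' across segments. Column names follow `filter_class_name`; the column
#' set and order are deterministic for a given configuration.
#'
#' @param scan a `scan_volume`.
#' @param segmask a `segment_mask` (from [delineate_rois()]) or an integer
#'   label array aligned with `scan`.
#' @param config an [extraction_config()].
#' @param meta named list added to every row (scan id, arm, trial, ...).
#' @return a `feature_table`: data.frame with identifier columns
#'   (`scan_id`, `segment`, plus `meta` fields) and one numeric column per
#'   feature.
#' @export
extract_all <- function(scan, segmask, config = extraction_config(),
                        meta = list()) {
  arr <- if (inherits(segmask, "segment_mask")) segmask$labels else segmask
  if (!identical(dim(arr), dim(scan$intensities)))
    stop("scan and segmentation mask are misaligned")
  seg_tab <- if (inherits(segmask, "segment_mask")) segmask$segments else {
    ids <- sort(setdiff(unique(as.vector(arr)), 0L))
    data.frame(id = ids, role = paste0("segment", ids))
  }
  seg_tab <- seg_tab[!is.na(seg_tab$id), , drop = FALSE]
  filtered_list <- lapply(config$filters, function(f) apply_filter(scan, f))
  rows <- list()
  for (si in seq_len(nrow(seg_tab))) {
    seg_id <- seg_tab$id[si]
    feats <- numeric()
    for (fi in seq_along(config$filters)) {
      f <- config$filters[[fi]]
      if (f$label == "original") {
        sh <- shape_features(arr == seg_id, scan$spacing)
        names(sh) <- paste0("original_shape_", names(sh))
        feats <- c(feats, sh)
      }
      fv <- segment_features_one(filtered_list[[fi]], arr, seg_id, config)
      names(fv) <- paste0(f$label, "_", names(fv))
      feats <- c(feats, fv)
    }
    rows[[si]] <- feats
  }
  mat <- do.call(rbind, rows)
  info <- data.frame(scan_id = if (!is.null(meta$scan_id)) meta$scan_id else "scan",
                     segment = seg_tab$role, stringsAsFactors = FALSE)
  for (nm in setdiff(names(meta), "scan_id")) info[[nm]] <- meta[[nm]]
  out <- cbind(info, as.data.frame(mat))
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Feature taxonomy from column names
#'
#' Splits `filter_class_name` column labels into their filter, feature
#' class (shape / firstorder / texture family) and base name, plus the
#' coarse class stratum used in the repeatability analysis
#' (shape / intensity / texture).
#'
#' @param features character vector of feature column names.
#' @return data.frame with columns `feature`, `filter`, `family`, `name`,
#'   `class`.
#' @export
feature_taxonomy <- function(features) {
  fam_pat <- "_(firstorder|shape|glcm|glrlm|glszm|gldm|ngtdm)_"
  m <- regexpr(fam_pat, features)
  if (any(m < 0)) stop("unrecognized feature names: ",
                       paste(utils::head(features[m < 0]), collapse = ", "))
  fam <- gsub("_", "", regmatches(features, m))
  filt <- substr(features, 1, m - 1)
  name <- substr(features, m + attr(m, "match.length"), nchar(features))
  cls <- ifelse(fam == "shape", "shape",
                ifelse(fam == "firstorder", "intensity", "texture"))
  data.frame(feature = features, filter = filt, family = fam, name = name,
             class = cls, stringsAsFactors = FALSE)
}

feature_columns <- function(ft) {
  fam_pat <- "_(firstorder|shape|glcm|glrlm|glszm|gldm|ngtdm)_"
  names(ft)[grepl(fam_pat, names(ft)) & vapply(ft, is.numeric, TRUE)]
}

#' @export
print.feature_table <- function(x, ...) {
  fc <- feature_columns(x)
  cat(sprintf("<feature_table> %d segments x %d features\n", nrow(x), length(fc)))
  tx <- feature_taxonomy(fc)
  cat("  classes:", paste(sprintf("%s=%d", names(table(tx$class)),
                                  table(tx$class)), collapse = ", "), "\n")
  cat("  filters:", paste(unique(tx$filter), collapse = ", "), "\n")
  invisible(x)
}
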