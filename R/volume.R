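#' 3D scan volume
#'
#' The basic image container used throughout the package: a 3D array of
#' non-negative intensities together with the physical voxel spacing (mm)
#' and free-form acquisition metadata (experiment id, agent, session,
#' test/retest arm, seed).
#'
#' @param intensities numeric 3D array of voxel intensities.
#' @param spacing numeric length-3 vector, voxel spacing in mm
#'   (default the 19F acquisition geometry 0.55 x 0.55 x 1.5).
#' @param meta named list of metadata fields (free form).
#' @return An object of class `scan_volume`.
#' @export
scan_volume <- function(intensities, spacing = c(0.55, 0.55, 1.5), meta = list()) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive numbers (mm)")
  if (!is.list(meta)) stop("`meta` must be a list")
  structure(list(intensities = intensities, spacing = spacing, meta = meta),
            class = "scan_volume")
}

#' @export
dim.scan_volume <- function(x) dim(x$intensities)

#' @export
as.array.scan_volume <- function(x, ...) x$intensities

#' @export
print.scan_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<scan_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$intensities), max(x$intensities)))
  if (length(x$meta)) {
    keys <- names(x$meta)
    vals <- vapply(x$meta, function(v) paste(format(v), collapse = ","), "")
    cat("  meta:", paste(sprintf("%s=%s", keys, vals), collapse = ", "), "\n")
  }
  invisible(x)
}

# Voxel volume in mm^3.
voxel_volume <- function(x) prod(x$spacing)

stopifnot_same_geometry <- function(a, b) {
  if (!identical(dim(a$intensities), dim(b$intensities)))
    stop("volumes have mismatched grid dimensions")
  if (max(abs(a$spacing - b$spacing)) > 1e-9)
    stop("volumes have mismatched voxel spacing")
  invisible(TRUE)
}

## ---- seeded randomness -----------------------------------------------------

# Evaluate `expr` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Expand a master seed into per-scan seeds
#'
#' Deterministically derives `n` child seeds (integers below 2^31) from one
#' master seed, so that every acquisition in a study carries its own
#' recorded noise seed.
#'
#' @param master integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
expand_seeds <- function(master, n) {
  with_seed(as.integer(master), sample.int(.Machine$integer.max - 1L, n))
}

## ---- NRRD / NIfTI I/O ------------------------------------------------------

#' Write a scan volume to disk
#'
#' NRRD (`.nrrd`) is the primary on-disk format; NIfTI-1 (`.nii`, `.nii.gz`)
#' is supported through the RNifti package. Voxel spacing is stored in the
#' header in both cases. Integer label masks round-trip exactly.
#'
#' @param x a `scan_volume` or a 3D array (a mask, say).
#' @param path output file; the extension selects the format.
#' @param spacing spacing override when `x` is a bare array.
#' @param encoding for NRRD: "raw" (little-endian binary) or "ascii" (text).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, spacing = NULL, encoding = "raw") {
  arr <- if (inherits(x, "scan_volume")) x$intensities else x
  sp <- if (inherits(x, "scan_volume")) x$spacing else
    if (is.null(spacing)) c(1, 1, 1) else spacing
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    write_nrrd(arr, path, sp, encoding = encoding)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- sp
    RNifti::writeNifti(img, path)
  } else stop("unsupported volume format: ", path)
  invisible(path)
}

#' Read a scan volume from disk
#'
#' @param path NRRD or NIfTI file written by [write_volume()] (or any
#'   conforming 3D scalar volume).
#' @param meta metadata list to attach.
#' @return a `scan_volume`.
#' @export
read_volume <- function(path, meta = list()) {
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    v <- read_nrrd(path)
    scan_volume(v$data, v$spacing, meta)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)[1:3]
    scan_volume(array(as.numeric(img), dim = dim(img)[1:3]), sp, meta)
  } else stop("unsupported volume format: ", path)
}

# Minimal NRRD writer: detached headers and exotic fields are not supported,
# just what is needed to round-trip 3D scalar volumes with spacing.
write_nrrd <- function(arr, path, spacing, encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  is_int <- is.integer(arr) ||
    (all(is.finite(arr)) && max(abs(arr - round(arr))) == 0 &&
       max(abs(arr)) < .Machine$integer.max)
  type <- if (is_int) "int" else "double"
  hdr <- c(
    "NRRD0004",
    "# generated by f19rad",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(dim(arr), collapse = " ")),
    paste0("spacings: ", paste(format(spacing, digits = 15), collapse = " ")),
    paste0("encoding: ", encoding),
    "endian: little"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("", con)
  if (encoding == "ascii") {
    writeLines(paste(format(as.vector(arr), digits = 17), collapse = " "), con)
  } else {
    if (is_int) writeBin(as.integer(arr), con, size = 4L, endian = "little")
    else writeBin(as.double(arr), con, size = 8L, endian = "little")
  }
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3D NRRD volumes are supported")
  spacing <- if (!is.null(fields$spacings))
    as.numeric(strsplit(fields$spacings, "\\s+")[[1]]) else c(1, 1, 1)
  n <- prod(sizes)
  type <- fields$type
  enc <- tolower(fields$encoding)
  if (enc %in% c("ascii", "text", "txt")) {
    txt <- readLines(con)
    vals <- as.numeric(strsplit(paste(txt, collapse = " "), "\\s+")[[1]])
    vals <- vals[is.finite(vals) | !is.na(vals)]
    data <- vals[seq_len(n)]
  } else if (enc == "raw") {
    endian <- if (!is.null(fields$endian)) fields$endian else "little"
    data <- switch(type,
      "int" = , "int32" = , "signed int" =
        as.numeric(readBin(con, "integer", n, size = 4L, endian = endian)),
      "short" = , "int16" =
        as.numeric(readBin(con, "integer", n, size = 2L, endian = endian)),
      "uchar" = , "uint8" =
        as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE)),
      "float" = readBin(con, "double", n, size = 4L, endian = endian),
      "double" = readBin(con, "double", n, size = 8L, endian = endian),
      stop("unsupported NRRD type: ", type))
  } else stop("unsupported NRRD encoding: ", enc)
  if (type %in% c("int", "int32", "signed int", "short", "int16", "uchar", "uint8"))
    data <- as.integer(round(data))
  list(data = array(data, dim = sizes), spacing = spacing)
}
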