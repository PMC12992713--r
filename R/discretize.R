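#' Discretization specification
#'
#' @param mode `"fixed-bin-count"` (equal-width bins over the ROI range)
#'   or `"fixed-bin-width"` (bins anchored at the ROI minimum).
#' @param value bin count (>= 2) or bin width (> 0).
#' @return object of class `discretization_spec`.
#' @export
discretization_spec <- function(mode = c("fixed-bin-count", "fixed-bin-width"),
                                value = 32) {
  mode <- match.arg(mode)
  if (mode == "fixed-bin-count" && (value < 2 || value != round(value)))
    stop("bin count must be an integer >= 2")
  if (mode == "fixed-bin-width" && value <= 0)
    stop("bin width must be positive")
  structure(list(mode = mode, value = value), class = "discretization_spec")
}

#' Discretize ROI intensities to integer gray levels
#'
#' Fixed-bin-width bins are anchored at the ROI minimum
#' (`level = floor((x - min) / width) + 1`); fixed-bin-count uses equal
#' width bins over `[min, max]` with the maximum value assigned to the top
#' bin. A constant ROI collapses to a single level (`Ng = 1`), which
#' downstream texture features treat as degenerate.
#'
#' @param values numeric vector of in-ROI intensities (nonempty).
#' @param d a `discretization_spec`.
#' @return list with integer `levels` (same length as `values`) and `ng`.
#' @export
discretize <- function(values, d = discretization_spec()) {
  if (length(values) == 0) stop("empty ROI")
  rng <- range(values)
  if (d$mode == "fixed-bin-width") {
    lev <- floor((values - rng[1]) / d$value) + 1L
  } else {
    if (rng[2] - rng[1] <= 0) {
      lev <- rep(1L, length(values))
    } else {
      width <- (rng[2] - rng[1]) / d$value
      lev <- pmin(floor((values - rng[1]) / width) + 1L, as.integer(d$value))
    }
  }
  list(levels = as.integer(lev), ng = max(lev))
}
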