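# Core data containers. Conventions: off-axis positions x,y in mm; depth z
# in cm (the scan axis of depth-dose curves); doses are relative units
# (generator output normalized to 100 at the maximum) or Gy for RT Dose
# imports.

#' Central-axis depth-dose curve
#'
#' @param depths Depths along the central axis, cm, strictly increasing.
#' @param doses Dose at each depth, relative units, non-negative.
#' @param normalized Logical; \code{TRUE} when doses are percentage depth
#'   dose (100 at the depth of maximum dose). Partial scans that do not
#'   include the maximum may carry normalized values below 100; values may
#'   not exceed 100 beyond rounding.
#' @param metadata Named list of free-form metadata (energy, field size,
#'   source label, ...).
#' @return Object of class \code{depth_dose_curve}.
#' @export
depth_dose_curve <- function(depths, doses, normalized = FALSE,
                             metadata = list()) {
  depths <- as.numeric(depths)
  doses <- as.numeric(doses)
  stopifnot_increasing(depths, "`depths`")
  if (length(doses) != length(depths))
    abort_input("`depths` and `doses` must have the same length")
  if (anyNA(doses) || any(doses < 0))
    abort_input("`doses` must be non-negative and free of NA")
  if (any(depths < 0)) abort_input("`depths` must be non-negative")
  if (normalized && max(doses) > 100 + 1e-9)
    abort_input("normalized curve has doses above 100")
  structure(list(depths = depths, doses = doses,
                 normalized = isTRUE(normalized), metadata = metadata),
            class = "depth_dose_curve")
}

#' Lateral dose profile at a stated depth
#'
#' @param positions Off-axis positions, mm, strictly increasing; should span
#'   both sides of the beam axis for symmetry analysis.
#' @param doses Dose at each position, relative units, non-negative.
#' @param depth Measurement depth, cm.
#' @param metadata Named list of free-form metadata.
#' @return Object of class \code{lateral_profile}.
#' @export
lateral_profile <- function(positions, doses, depth = NA_real_,
                            metadata = list()) {
  positions <- as.numeric(positions)
  doses <- as.numeric(doses)
  stopifnot_increasing(positions, "`positions`")
  if (length(doses) != length(positions))
    abort_input("`positions` and `doses` must have the same length")
  if (anyNA(doses) || any(doses < 0))
    abort_input("`doses` must be non-negative and free of NA")
  structure(list(positions = positions, doses = doses,
                 depth = as.numeric(depth), metadata = metadata),
            class = "lateral_profile")
}

#' Dose values on a regular 1/2/3-D grid
#'
#' The common currency of the gamma analyses. Axes are physical coordinates:
#' \code{x}, \code{y} off-axis in mm and \code{z} depth in cm. A grid may be
#' 1-D (any single axis), 2-D or 3-D; \code{values} has one dimension per
#' supplied axis, in (x, y, z) order restricted to the axes present.
#'
#' @param values Numeric array (or vector for 1-D) of non-negative doses;
#'   \code{dim(values)} must match the axis lengths.
#' @param x,y,z Axis coordinates (strictly increasing, uniformly spaced);
#'   omit (NULL) axes absent from the grid.
#' @param unit_label Dose unit label, e.g. \code{"relative"} or \code{"Gy"}.
#' @param provenance Named list recording where the grid came from
#'   (generator parameters, file, seed, ...).
#' @return Object of class \code{dose_grid}.
#' @export
dose_grid <- function(values, x = NULL, y = NULL, z = NULL,
                      unit_label = "relative", provenance = list()) {
  axes <- list(x = x, y = y, z = z)
  axes <- axes[!vapply(axes, is.null, logical(1))]
  if (length(axes) == 0L) abort_input("at least one axis must be supplied")
  for (nm in names(axes)) {
    axes[[nm]] <- as.numeric(axes[[nm]])
    stopifnot_increasing(axes[[nm]], sprintf("axis `%s`", nm))
    check_uniform_spacing(axes[[nm]], nm)
  }
  values <- if (length(axes) == 1L) as.numeric(values) else as.array(values)
  dims <- vapply(axes, length, integer(1))
  if (length(axes) == 1L) {
    if (length(values) != dims) abort_input("value count does not match axis length")
  } else if (!identical(as.integer(dim(values)), as.integer(dims))) {
    abort_input("dim(values) does not match axis lengths")
  }
  if (anyNA(values) || any(values < 0))
    abort_input("dose values must be non-negative and free of NA")
  structure(list(values = values, axes = axes, unit_label = unit_label,
                 provenance = provenance),
            class = "dose_grid")
}

check_uniform_spacing <- function(coords, name) {
  if (length(coords) < 2L) return(invisible(coords))
  d <- diff(coords)
  if (max(d) - min(d) > 1e-9 * max(abs(d)))
    abort_input(sprintf("axis `%s` must be uniformly spaced", name))
  invisible(coords)
}

#' @export
print.depth_dose_curve <- function(x, ...) {
  cat(sprintf("<depth_dose_curve> %d points, %.2f-%.2f cm, %s\n",
              length(x$depths), min(x$depths), max(x$depths),
              if (x$normalized) "normalized (PDD)" else "raw"))
  invisible(x)
}

#' @export
print.lateral_profile <- function(x, ...) {
  cat(sprintf("<lateral_profile> %d points, %.1f..%.1f mm at depth %s cm\n",
              length(x$positions), min(x$positions), max(x$positions),
              format(x$depth)))
  invisible(x)
}

#' @export
print.dose_grid <- function(x, ...) {
  dims <- vapply(x$axes, length, integer(1))
  cat(sprintf("<dose_grid> %s [%s], unit %s, max %.4g\n",
              paste(names(x$axes), collapse = "x"),
              paste(dims, collapse = " x "), x$unit_label, max(x$values)))
  invisible(x)
}

# Internal: scan coordinates in mm for gamma; depth axes are cm -> mm.
scan_coords_mm <- function(obj) {
  if (inherits(obj, "depth_dose_curve")) return(obj$depths * 10)
  if (inherits(obj, "lateral_profile")) return(obj$positions)
  abort_input("expected a depth_dose_curve or lateral_profile")
}

scan_doses <- function(obj) obj$doses
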