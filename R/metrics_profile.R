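# Lateral profile analysis: field width (50% edges), flatness, symmetry,
# 80%-20% penumbra and the geometric penumbra. All level crossings use
# linear interpolation between adjacent samples; when several crossings
# exist, the one nearest the beam axis wins.

profile_cax_dose <- function(profile) {
  p <- profile$positions
  if (min(p) > 0 || max(p) < 0)
    abort_input("profile must span the beam axis (position 0)")
  stats::approx(p, profile$doses, xout = 0)$y
}

# First crossing of `level`, walking outward from the axis on one side.
# Returns the interpolated position, or NA when the dose never falls
# through the level on that side.
crossing_outward <- function(positions, doses, level, side) {
  ord <- if (side == "right") order(positions) else order(-positions)
  x <- positions[ord]
  d <- doses[ord]
  keep <- if (side == "right") x >= 0 else x <= 0
  x <- x[keep]; d <- d[keep]
  if (length(x) < 2L) return(NA_real_)
  for (k in seq_len(length(x) - 1L)) {
    if ((d[k] >= level && d[k + 1L] < level) ||
        (d[k] > level && d[k + 1L] <= level)) {
      return(x[k] + (level - d[k]) * (x[k + 1L] - x[k]) / (d[k + 1L] - d[k]))
    }
  }
  NA_real_
}

#' Field width and edge positions of a profile
#'
#' The field edges are the positions where the dose falls through 50\% of
#' the central-axis dose, one per side, nearest the axis; the field width is
#' their separation.
#'
#' @param profile A [lateral_profile()] spanning the beam axis.
#' @return Named numeric vector: \code{left}, \code{right} (edge positions,
#'   mm) and \code{width} (mm).
#' @export
field_width <- function(profile) {
  stopifnot(inherits(profile, "lateral_profile"))
  cax <- profile_cax_dose(profile)
  if (!is.finite(cax) || cax <= 0) abort_input("central-axis dose must be positive")
  left <- crossing_outward(profile$positions, profile$doses, 0.5 * cax, "left")
  right <- crossing_outward(profile$positions, profile$doses, 0.5 * cax, "right")
  if (is.na(left) || is.na(right))
    abort_input("50% field edges not found on both sides")
  c(left = left, right = right, width = right - left)
}

central_region <- function(profile) {
  fw <- field_width(profile)
  mid <- (fw[["left"]] + fw[["right"]]) / 2
  half <- 0.4 * fw[["width"]]             # central 80% of the field width
  c(lo = mid - half, hi = mid + half)
}

#' Profile flatness
#'
#' Ratio of the maximum to the minimum dose within the central 80\% of the
#' field width (50\%-50\% edge separation), times 100. A perfectly uniform
#' central region gives 100\%.
#'
#' @param profile A [lateral_profile()].
#' @return Flatness, percent (>= 100).
#' @export
flatness <- function(profile) {
  stopifnot(inherits(profile, "lateral_profile"))
  reg <- central_region(profile)
  inside <- profile$doses[profile$positions >= reg[["lo"]] &
                          profile$positions <= reg[["hi"]]]
  if (!length(inside)) abort_input("no samples inside the central 80% region")
  if (min(inside) <= 0) abort_input("zero dose inside the central region")
  max(inside) / min(inside) * 100
}

#' Profile symmetry
#'
#' Worst mirrored point-pair dose ratio within the central 80\% region,
#' oriented so the result is at least 100\%: for each sampled position x in
#' the region, D(x) is compared with the linearly interpolated D(-x).
#'
#' @param profile A [lateral_profile()] covering the mirror of every sample
#'   in the central region.
#' @return Symmetry, percent (>= 100).
#' @export
symmetry <- function(profile) {
  stopifnot(inherits(profile, "lateral_profile"))
  reg <- central_region(profile)
  keep <- profile$positions >= reg[["lo"]] & profile$positions <= reg[["hi"]]
  x <- profile$positions[keep]
  d <- profile$doses[keep]
  if (!length(x)) abort_input("no samples inside the central 80% region")
  if (min(-x) < min(profile$positions) - 1e-9 ||
      max(-x) > max(profile$positions) + 1e-9)
    abort_input("mirror positions fall outside the measured profile")
  dm <- stats::approx(profile$positions, profile$doses, xout = -x)$y
  if (any(d <= 0) || any(dm <= 0))
    abort_input("zero dose inside the central region")
  max(pmax(d / dm, dm / d)) * 100
}

#' Penumbra widths (80\%-20\% fall-off)
#'
#' Per side, the lateral distance between the crossings of 80\% and 20\% of
#' the central-axis dose (linear interpolation between samples).
#'
#' @param profile A [lateral_profile()] whose dose crosses both levels on
#'   each side.
#' @return Named numeric vector: \code{left}, \code{right},
#'   \code{average}, mm.
#' @export
penumbra_widths <- function(profile) {
  stopifnot(inherits(profile, "lateral_profile"))
  cax <- profile_cax_dose(profile)
  if (!is.finite(cax) || cax <= 0) abort_input("central-axis dose must be positive")
  one_side <- function(side) {
    x80 <- crossing_outward(profile$positions, profile$doses, 0.8 * cax, side)
    x20 <- crossing_outward(profile$positions, profile$doses, 0.2 * cax, side)
    if (is.na(x80) || is.na(x20))
      abort_input(sprintf("80%%/20%% crossings not found on the %s side", side))
    abs(x20 - x80)
  }
  left <- one_side("left")
  right <- one_side("right")
  c(left = left, right = right, average = (left + right) / 2)
}

#' Geometric penumbra from source size and distances
#'
#' \eqn{P = s (SSD + d - SDD) / SDD}: the shadow cast by a source of finite
#' size s beyond the beam-defining diaphragm.
#'
#' @param s Source size, mm (> 0).
#' @param ssd Source-to-surface distance, mm (> 0).
#' @param sdd Source-to-diaphragm distance, mm (> 0).
#' @param depth Depth of the dose plane, mm (> 0); \code{ssd + depth} must
#'   not be smaller than \code{sdd}.
#' @return Geometric penumbra, mm.
#' @export
#' @examples
#' geometric_penumbra(s = 1, ssd = 1000, sdd = 500, depth = 100)  # 1.2 mm
geometric_penumbra <- function(s, ssd, sdd, depth) {
  if (any(c(s, ssd, sdd, depth) <= 0))
    abort_input("all geometry parameters must be positive")
  if (ssd + depth < sdd)
    abort_input("ssd + depth must not be smaller than sdd")
  s * (ssd + depth - sdd) / sdd
}

#' All profile metrics in one summary
#'
#' @param profile A [lateral_profile()].
#' @return Object of class \code{profile_summary} with fields
#'   \code{flatness_percent}, \code{symmetry_percent},
#'   \code{penumbra_left_mm}, \code{penumbra_right_mm},
#'   \code{penumbra_avg_mm} and \code{field_width_mm}.
#' @export
profile_summary <- function(profile) {
  pen <- penumbra_widths(profile)
  fw <- field_width(profile)
  structure(list(flatness_percent = flatness(profile),
                 symmetry_percent = symmetry(profile),
                 penumbra_left_mm = pen[["left"]],
                 penumbra_right_mm = pen[["right"]],
                 penumbra_avg_mm = pen[["average"]],
                 field_width_mm = fw[["width"]]),
            class = "profile_summary")
}

#' @export
print.profile_summary <- function(x, ...) {
  cat(sprintf("<profile_summary> flatness %.2f%%, symmetry %.2f%%, penumbra %.2f mm (L %.2f / R %.2f), width %.1f mm\n",
              x$flatness_percent, x$symmetry_percent, x$penumbra_avg_mm,
              x$penumbra_left_mm, x$penumbra_right_mm, x$field_width_mm))
  invisible(x)
}
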