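# Depth-dose analysis: depth of maximum dose, PDD normalization, and the
# Table-style summary metrics (PDD at 5/10/20 cm, D20/D5).

#' Depth of maximum dose
#'
#' Locates the maximum dose sample (ties broken toward the smallest depth),
#' then refines by a parabola through the maximum and its two neighbours
#' when the maximum is interior and not part of a plateau. The result is
#' snapped to the curve's grid resolution, so a smooth model curve sampled
#' at 0.1 cm reports d_max to 0.1 cm.
#'
#' @param curve A [depth_dose_curve()] with at least 3 points.
#' @return Depth of maximum dose, cm.
#' @export
#' @examples
#' find_dmax(make_pdd_curve(beam_model_params("6MV"), seq(0, 30, 0.1)))
find_dmax <- function(curve) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  z <- curve$depths
  d <- curve$doses
  if (length(z) < 3L) abort_input("d_max search needs at least 3 points")
  i0 <- which.max(d)                       # which.max takes the first tie
  h <- stats::median(diff(z))
  snap <- function(x) z[1] + round((x - z[1]) / h) * h
  if (i0 == 1L || i0 == length(z)) return(z[i0])
  if (d[i0 + 1L] == d[i0]) return(z[i0])   # plateau: keep the shallow edge
  y1 <- d[i0 - 1L]; y2 <- d[i0]; y3 <- d[i0 + 1L]
  denom <- y1 - 2 * y2 + y3
  if (denom >= 0) return(z[i0])            # no curvature information
  vertex <- z[i0] + 0.5 * h * (y1 - y3) / denom
  vertex <- min(max(vertex, z[i0 - 1L]), z[i0 + 1L])
  snap(vertex)
}

#' Normalize a depth-dose curve to percentage depth dose
#'
#' Rescales so the maximum sampled dose is 100 (the reference dose D_P at
#' the depth of maximum dose) and flags the curve as normalized. Curves
#' already flagged normalized are returned unchanged, so partial scans that
#' carry tabulated PDD values (maximum below 100) are preserved.
#'
#' @param curve A [depth_dose_curve()] with a positive maximum.
#' @return A normalized [depth_dose_curve()].
#' @export
normalize_pdd <- function(curve) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  if (curve$normalized) return(curve)
  peak <- max(curve$doses)
  if (peak <= 0) abort_degenerate("cannot normalize an all-zero curve")
  depth_dose_curve(curve$depths, curve$doses / peak * 100,
                   normalized = TRUE, metadata = curve$metadata)
}

#' Summary metrics of a depth-dose curve
#'
#' Computes the depth of maximum dose, PDD at 5, 10 and 20 cm (linear
#' interpolation on the normalized curve) and the beam-quality index
#' D20/D5 = PDD(20)/PDD(5).
#'
#' @param curve A [depth_dose_curve()] covering depths 5 to 20 cm.
#' @return Object of class \code{pdd_summary} with fields \code{d_max}
#'   (cm), \code{pdd5}, \code{pdd10}, \code{pdd20} (percent) and
#'   \code{d20_d5} (unrounded; report formatting rounds to 3 decimals).
#' @export
pdd_summary <- function(curve) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  if (min(curve$depths) > 5 || max(curve$depths) < 20)
    abort_input("curve must cover depths 5 to 20 cm")
  norm <- normalize_pdd(curve)
  at <- stats::approx(norm$depths, norm$doses, xout = c(5, 10, 20))$y
  structure(list(d_max = find_dmax(norm),
                 pdd5 = at[1], pdd10 = at[2], pdd20 = at[3],
                 d20_d5 = at[3] / at[1]),
            class = "pdd_summary")
}

#' @export
print.pdd_summary <- function(x, ...) {
  cat(sprintf("<pdd_summary> d_max %.1f cm | PDD5 %.1f PDD10 %.1f PDD20 %.1f | D20/D5 %.3f\n",
              x$d_max, x$pdd5, x$pdd10, x$pdd20, x$d20_d5))
  invisible(x)
}
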