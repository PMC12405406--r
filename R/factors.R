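# Relative dosimetric factors. Each is a pure ratio of two central-axis
# readings taken under identical geometry, so all three are invariant under
# a common rescaling of their inputs.

check_ratio_inputs <- function(a, b, what) {
  if (length(a) != 1L || length(b) != 1L || !is.finite(a) || !is.finite(b))
    abort_input(sprintf("%s inputs must be finite scalars", what))
  if (a <= 0 || b <= 0)
    abort_input(sprintf("%s inputs must be positive", what))
}

#' Phantom output factor S_cp
#'
#' Ratio of the central-axis dose for a field size to that of the reference
#' field (conventionally 10 x 10 cm2), same depth and geometry.
#'
#' @param dose_field Central-axis dose for the field of interest.
#' @param dose_reference_field Same reading for the reference field.
#' @return S_cp, dimensionless.
#' @export
scp_factor <- function(dose_field, dose_reference_field) {
  check_ratio_inputs(dose_field, dose_reference_field, "S_cp")
  dose_field / dose_reference_field
}

#' Head scatter factor S_c
#'
#' Ratio of the in-air reading with the treatment head scatter present to
#' the reading in the reference setup.
#'
#' @param reading_with_head_scatter In-air reading with head scatter.
#' @param reading_reference Reference reading.
#' @return S_c, dimensionless.
#' @export
sc_factor <- function(reading_with_head_scatter, reading_reference) {
  check_ratio_inputs(reading_with_head_scatter, reading_reference, "S_c")
  reading_with_head_scatter / reading_reference
}

#' Wedge factor
#'
#' Ratio of the central-axis dose with the physical wedge in the beam to
#' the open-field dose at the same depth and field size.
#'
#' @param dose_wedged Central-axis dose with the wedge.
#' @param dose_open Open-field central-axis dose.
#' @return Wedge factor, dimensionless.
#' @export
wedge_factor <- function(dose_wedged, dose_open) {
  check_ratio_inputs(dose_wedged, dose_open, "wedge factor")
  dose_wedged / dose_open
}

#' @export
print.factor_table <- function(x, ...) {
  cat(sprintf("<factor_table> %d rows\n", nrow(x)))
  y <- as.data.frame(x)
  for (col in c("s_cp", "s_c", "wedge_factor"))
    if (col %in% names(y)) y[[col]] <- round(y[[col]], 3)
  print(y, row.names = FALSE)
  invisible(x)
}
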