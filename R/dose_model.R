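# Analytic beam simulator. Emulates the statistical structure of
# Monte-Carlo megavoltage photon-beam dose data: a build-up region peaking
# at d_max followed by quasi-exponential fall-off, flat-core profiles with
# error-function penumbrae, field-size-dependent output, optional wedge
# transmission and multiplicative noise. It is an exercise harness for the
# analysis code, explicitly not a transport model.

#' Square-field width projected to depth
#'
#' @param params A [beam_model_params()] object.
#' @param depth Depth, cm.
#' @return Field width at depth, mm (divergent projection from the source).
#' @export
field_width_at_depth <- function(params, depth) {
  10 * params$field_size * (params$ssd + depth) / params$ssd
}

# Unnormalized central-axis model dose at depth z (cm): build-up times
# effective exponential attenuation times the field-size output multiplier.
model_axis_dose <- function(params, z) {
  (1 - exp(-params$k_buildup * z)) * exp(-params$mu * z) *
    (1 + params$scatter_slope * (params$field_size - 10))
}

# Unnormalized lateral shape at off-axis x (mm), depth (cm): difference of
# standard normal CDFs for the two field edges, in-field horns, and (when a
# wedge gradient is set) transmission anchored at the thin field edge so the
# central axis is attenuated too.
model_profile_dose <- function(params, depth, x) {
  w <- field_width_at_depth(params, depth)
  s <- params$penumbra_sigma
  d <- (stats::pnorm((x + w / 2) / s) - stats::pnorm((x - w / 2) / s)) *
    (1 + params$horn_amplitude * (2 * x / w)^2)
  g <- params$wedge_transmission_gradient
  if (g != 0) d <- d * exp(-g * (x + w / 2) / 10)
  d
}

# Multiplicative Gaussian noise under a private RNG stream; doses stay >= 0.
apply_mc_noise <- function(values, noise_sd, seed) {
  if (noise_sd == 0) return(values)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  pmax(values * (1 + stats::rnorm(length(values), 0, noise_sd)), 0)
}

#' Generate a central-axis depth-dose curve
#'
#' Evaluates the analytic beam model on a depth grid, scales the noiseless
#' curve so its maximum is exactly 100, then (if \code{noise_sd > 0}) applies
#' multiplicative Gaussian noise under the parameter seed. The closed-form
#' depth of maximum dose is \eqn{\ln(1 + k/\mu)/k}; see [dmax_closed_form()].
#'
#' @param params A [beam_model_params()] object.
#' @param depths Non-negative, strictly increasing depths, cm.
#' @return A [depth_dose_curve()] (normalized when noiseless).
#' @export
#' @examples
#' crv <- make_pdd_curve(beam_model_params("6MV"), seq(0, 30, 0.1))
#' find_dmax(crv)
make_pdd_curve <- function(params, depths) {
  stopifnot(inherits(params, "beam_model_params"))
  depths <- as.numeric(depths)
  stopifnot_increasing(depths, "`depths`")
  if (any(depths < 0)) abort_input("`depths` must be non-negative")
  dose <- model_axis_dose(params, depths)
  peak <- max(dose)
  if (peak <= 0) abort_degenerate("degenerate model: all-zero dose")
  dose <- dose / peak * 100
  noisy <- params$noise_sd > 0
  if (noisy) dose <- apply_mc_noise(dose, params$noise_sd, params$seed)
  depth_dose_curve(depths, dose, normalized = !noisy,
                   metadata = list(energy = params$energy_label,
                                   field_size = params$field_size,
                                   ssd = params$ssd))
}

#' Generate a lateral dose profile at depth
#'
#' Flat-core profile with error-function-shaped penumbrae at the projected
#' field edges, optional in-field horns and wedge transmission. The noiseless
#' profile is scaled to 100 at its maximum unless \code{normalize = FALSE}
#' (raw model output, needed for output-factor work).
#'
#' @param params A [beam_model_params()] object.
#' @param depth Depth of the scan, cm (non-negative).
#' @param positions Strictly increasing off-axis positions, mm.
#' @param normalize Scale the noiseless profile to max 100 (default TRUE).
#' @return A [lateral_profile()].
#' @export
make_profile <- function(params, depth, positions, normalize = TRUE) {
  stopifnot(inherits(params, "beam_model_params"))
  if (depth < 0) abort_input("`depth` must be non-negative")
  positions <- as.numeric(positions)
  stopifnot_increasing(positions, "`positions`")
  dose <- model_profile_dose(params, depth, positions)
  if (normalize) {
    peak <- max(dose)
    if (peak <= 0) abort_degenerate("degenerate model: all-zero profile")
    dose <- dose / peak * 100
  }
  dose <- apply_mc_noise(dose, params$noise_sd, params$seed)
  lateral_profile(positions, dose, depth = depth,
                  metadata = list(energy = params$energy_label,
                                  field_size = params$field_size,
                                  ssd = params$ssd))
}

#' Axis specification for a generated dose grid
#'
#' @param x,y Off-axis coordinates, mm, strictly increasing, uniform spacing.
#' @param z Depths, cm, strictly increasing, uniform spacing, non-negative.
#' @return Object of class \code{grid_spec}.
#' @export
grid_spec <- function(x, y, z) {
  axes <- list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  for (nm in names(axes)) {
    stopifnot_increasing(axes[[nm]], sprintf("axis `%s`", nm))
    check_uniform_spacing(axes[[nm]], nm)
  }
  if (any(axes$z < 0)) abort_input("axis `z` must be non-negative")
  structure(axes, class = "grid_spec")
}

#' Generate a separable 3-D dose grid
#'
#' Builds \code{dose(x, y, z) = pdd(z) * profile(x; z) * profile(y; z)} from
#' the analytic model (the y profile is always open-field; a wedge gradient
#' acts along x), scaled to 100 at the grid maximum when noiseless.
#'
#' @param params A [beam_model_params()] object.
#' @param spec A [grid_spec()].
#' @param max_nodes Resource guard on the total node count.
#' @return A [dose_grid()].
#' @export
make_dose_grid <- function(params, spec, max_nodes = 2e6) {
  stopifnot(inherits(params, "beam_model_params"), inherits(spec, "grid_spec"))
  n <- prod(vapply(spec, length, integer(1)))
  if (n > max_nodes)
    abort_resource(sprintf("grid has %g nodes; limit is %g", n, max_nodes))
  open <- params
  open$wedge_transmission_gradient <- 0
  pz <- model_axis_dose(params, spec$z)
  vals <- array(0, dim = c(length(spec$x), length(spec$y), length(spec$z)))
  for (iz in seq_along(spec$z)) {
    px <- model_profile_dose(params, spec$z[iz], spec$x)
    py <- model_profile_dose(open, spec$z[iz], spec$y)
    vals[, , iz] <- outer(px, py) * pz[iz]
  }
  peak <- max(vals)
  if (peak <= 0) abort_degenerate("degenerate model: all-zero grid")
  vals <- vals / peak * 100
  vals <- apply_mc_noise(vals, params$noise_sd, params$seed)
  dose_grid(vals, x = spec$x, y = spec$y, z = spec$z,
            unit_label = "relative",
            provenance = list(generator = "beamqa analytic model",
                              energy = params$energy_label,
                              field_size = params$field_size,
                              seed = params$seed,
                              noise_sd = params$noise_sd))
}

#' Perturb a dose grid (shift, rescale, add noise)
#'
#' Test harness for the gamma engine: returns the grid resampled at
#' coordinates shifted by \code{shift} (linear interpolation, edge values
#' held), multiplied by \code{scale}, then by multiplicative Gaussian noise.
#' The input grid is not modified.
#'
#' @param grid A [dose_grid()].
#' @param shift Named numeric vector of per-axis shifts (units of each axis:
#'   mm for x/y, cm for z); missing axes shift by 0. A shifted distribution
#'   moves in the +axis direction by the stated amount.
#' @param scale Global dose multiplier.
#' @param noise_sd Relative SD of multiplicative noise (0 = none).
#' @param seed Seed for the noise stream.
#' @return A new [dose_grid()].
#' @export
perturb_grid <- function(grid, shift = c(), scale = 1, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(grid, "dose_grid"))
  if (length(shift)) {
    bad <- setdiff(names(shift), names(grid$axes))
    if (length(bad))
      abort_input(sprintf("shift names not grid axes: %s", paste(bad, collapse = ", ")))
  }
  vals <- grid$values
  if (length(grid$axes) == 1L) vals <- array(vals, dim = length(vals))
  for (ai in seq_along(grid$axes)) {
    nm <- names(grid$axes)[ai]
    s <- if (nm %in% names(shift)) unname(shift[[nm]]) else 0
    if (s == 0) next
    coords <- grid$axes[[nm]]
    extent <- max(coords) - min(coords)
    if (extent > 0 && abs(s) >= extent)
      abort_input(sprintf("shift %g exceeds extent of axis `%s`", s, nm))
    # dose_new(p) = dose_old(p - s): sample the old grid at p - s, clamped.
    at <- pmin(max(coords), pmax(min(coords), coords - s))
    vals <- interp_along_axis(vals, ai, coords, at)
  }
  out <- vals * scale
  out <- apply_mc_noise(out, noise_sd, seed)
  if (length(grid$axes) == 1L) out <- as.numeric(out)
  prov <- grid$provenance
  prov$perturbation <- list(shift = shift, scale = scale,
                            noise_sd = noise_sd, seed = seed)
  args <- c(list(values = out), grid$axes,
            list(unit_label = grid$unit_label, provenance = prov))
  do.call(dose_grid, args)
}

# Linear interpolation of an array along one axis at new coordinates `at`
# (same length as the axis), vectorized over all other axes.
interp_along_axis <- function(vals, axis, coords, at) {
  n <- length(coords)
  if (n == 1L) return(vals)
  idx <- findInterval(at, coords, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), n - 1L)
  frac <- (at - coords[idx]) / (coords[idx + 1L] - coords[idx])
  d <- dim(vals)
  perm <- c(axis, seq_along(d)[-axis])
  v <- aperm(vals, perm)
  m <- matrix(v, nrow = d[axis])
  out <- m[idx, , drop = FALSE] * (1 - frac) +
    m[idx + 1L, , drop = FALSE] * frac
  out <- array(out, dim = d[perm])
  aperm(out, order(perm))
}

#' Synthetic relative dosimetric factor table
#'
#' Emits phantom output factors (S_cp), head scatter factors (S_c) and --
#' for wedged parameter sets -- wedge factors for a list of beam
#' configurations, as central-axis dose ratios to the 10 x 10 cm2 reference
#' field of the same energy at the reference depth. S_c is modelled as the
#' head-scatter share (35\%) of the total output variation with field size,
#' a stated convention of the simulator.
#'
#' @param params_list List of [beam_model_params()] objects; must contain a
#'   10 x 10 cm2 entry per energy present.
#' @param reference_depth Depth of the central-axis reading, cm.
#' @return A \code{factor_table}: data frame with columns
#'   \code{energy_label}, \code{field_size}, \code{s_cp}, \code{s_c},
#'   \code{wedge_factor}.
#' @export
model_factor_table <- function(params_list, reference_depth = 10) {
  if (inherits(params_list, "beam_model_params")) params_list <- list(params_list)
  if (!length(params_list)) abort_input("`params_list` is empty")
  stopifnot(all(vapply(params_list, inherits, logical(1), "beam_model_params")))
  energy <- vapply(params_list, `[[`, character(1), "energy_label")
  fs <- vapply(params_list, `[[`, numeric(1), "field_size")
  rows <- lapply(seq_along(params_list), function(i) {
    p <- params_list[[i]]
    ref <- params_list[energy == p$energy_label & fs == 10]
    if (!length(ref))
      abort_input(sprintf("no 10 x 10 reference field for energy %s", p$energy_label))
    ref <- ref[[1L]]
    axis <- function(q) model_axis_dose(q, reference_depth)
    head_scatter <- function(q) 1 + 0.35 * q$scatter_slope * (q$field_size - 10)
    g <- p$wedge_transmission_gradient
    wf <- if (g != 0)
      exp(-g * field_width_at_depth(p, reference_depth) / 20) else NA_real_
    data.frame(energy_label = p$energy_label, field_size = p$field_size,
               s_cp = axis(p) / axis(ref),
               s_c = head_scatter(p) / head_scatter(ref),
               wedge_factor = wf, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$energy_label, out$field_size), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("factor_table", "data.frame")
  out
}
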