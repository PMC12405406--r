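#' Analytic beam model parameters
#'
#' Bundle the free parameters of the analytic megavoltage photon-beam model.
#' The central-axis depth dose is modelled as
#' \deqn{D(z) \propto (1 - e^{-k z})\, e^{-\mu z}\,(1 + s\,(A - 10))}
#' where \eqn{\mu} is an effective linear attenuation coefficient (per cm),
#' \eqn{k} the build-up rate constant (per cm), \eqn{A} the square field side
#' (cm) and \eqn{s} the fractional output change per cm of field-size growth.
#' The form has a closed-form depth of maximum dose,
#' \eqn{z^* = \ln(1 + k/\mu)/k}, used throughout as a test oracle.
#'
#' Defaults for the \code{"6MV"} and \code{"12MV"} presets are calibrated so
#' that the noiseless model reproduces the clinical depth of maximum dose
#' (1.4 cm and 2.5 cm) and a 10x10 cm2 D20/D5 ratio of 0.415 and 0.497
#' respectively; \code{mu} is therefore an effective fall-off coefficient,
#' not a narrow-beam attenuation coefficient.
#'
#' @param energy_label Beam preset, \code{"6MV"} or \code{"12MV"}, or any
#'   label for a custom beam (then supply \code{mu} and either
#'   \code{k_buildup} or \code{d_max}).
#' @param mu Effective linear attenuation coefficient, per cm.
#' @param k_buildup Build-up rate constant, per cm. Exactly one of
#'   \code{k_buildup} or \code{d_max} may be given; with \code{d_max},
#'   \code{k_buildup} is solved so the closed-form maximum sits there.
#' @param d_max Target depth of maximum dose, cm (alternative to
#'   \code{k_buildup}).
#' @param field_size Side of the square field, cm.
#' @param ssd Source-to-surface distance, cm.
#' @param penumbra_sigma Profile edge width parameter (standard-normal sigma
#'   of the edge), mm.
#' @param scatter_slope Fractional output change per cm of field-size growth
#'   relative to the 10x10 reference, dimensionless.
#' @param horn_amplitude Fractional off-axis over-dose at the edge of the
#'   central 80\% region, shaping flatness, dimensionless.
#' @param wedge_transmission_gradient Fractional dose change per cm across
#'   the wedged (x) axis; 0 means open field.
#' @param noise_sd Relative standard deviation of multiplicative
#'   Monte-Carlo-like noise; 0 disables noise.
#' @param seed Integer seed for the noise generator.
#'
#' @return An object of class \code{beam_model_params} (a named list with the
#'   fields above plus the solved \code{k_buildup}).
#' @seealso [make_pdd_curve()], [make_profile()], [make_dose_grid()],
#'   [dmax_closed_form()]
#' @export
#' @examples
#' p <- beam_model_params("6MV")
#' dmax_closed_form(p)  # 1.4 cm by calibration
beam_model_params <- function(energy_label = "6MV",
                              mu = NULL,
                              k_buildup = NULL,
                              d_max = NULL,
                              field_size = 10,
                              ssd = 100,
                              penumbra_sigma = NULL,
                              scatter_slope = 0.007,
                              horn_amplitude = 0.08,
                              wedge_transmission_gradient = 0,
                              noise_sd = 0,
                              seed = 1L) {
  preset <- switch(energy_label,
    # mu = -ln(D20/D5)/15 cm with the 10x10 ratio; d_max per clinical value
    "6MV"  = list(mu = -log(0.415) / 15, d_max = 1.4, sigma = 3.2),
    "12MV" = list(mu = -log(0.497) / 15, d_max = 2.5, sigma = 4.5),
    NULL)
  if (is.null(mu)) {
    if (is.null(preset))
      abort_input("custom energy_label requires an explicit `mu`")
    mu <- preset$mu
  }
  if (is.null(k_buildup) && is.null(d_max)) {
    if (is.null(preset))
      abort_input("custom energy_label requires `k_buildup` or `d_max`")
    d_max <- preset$d_max
  }
  if (!is.null(k_buildup) && !is.null(d_max))
    abort_input("give either `k_buildup` or `d_max`, not both")
  if (is.null(penumbra_sigma))
    penumbra_sigma <- if (is.null(preset)) 3.2 else preset$sigma
  if (!is.null(d_max)) {
    if (d_max <= 0) abort_input("`d_max` must be positive")
    k_buildup <- solve_buildup_rate(mu, d_max)
  }
  if (mu <= 0) abort_input("`mu` must be positive")
  if (k_buildup <= 0) abort_input("`k_buildup` must be positive")
  if (field_size <= 0) abort_input("`field_size` must be positive")
  if (ssd <= 0) abort_input("`ssd` must be positive")
  if (penumbra_sigma <= 0) abort_input("`penumbra_sigma` must be positive")
  if (noise_sd < 0) abort_input("`noise_sd` must be non-negative")
  structure(
    list(energy_label = energy_label,
         mu = mu,
         k_buildup = k_buildup,
         field_size = field_size,
         ssd = ssd,
         penumbra_sigma = penumbra_sigma,
         scatter_slope = scatter_slope,
         horn_amplitude = horn_amplitude,
         wedge_transmission_gradient = wedge_transmission_gradient,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "beam_model_params")
}

#' Solve the build-up rate for a target depth of maximum dose
#'
#' Inverts the closed form \eqn{z^* = \ln(1 + k/\mu)/k} for \eqn{k} given
#' \eqn{\mu} and the target \eqn{z^*}.
#'
#' @param mu Effective attenuation coefficient, per cm.
#' @param d_max Target depth of maximum dose, cm.
#' @return Build-up rate constant \eqn{k}, per cm.
#' @export
solve_buildup_rate <- function(mu, d_max) {
  if (mu <= 0 || d_max <= 0) abort_input("`mu` and `d_max` must be positive")
  # z*(k) is strictly decreasing in k; bracket then root-find.
  f <- function(k) log1p(k / mu) / k - d_max
  upper <- 1
  while (f(upper) > 0) upper <- upper * 2
  lower <- upper / 2
  while (f(lower) < 0) lower <- lower / 2
  stats::uniroot(f, c(lower, upper), tol = 1e-13)$root
}

#' Closed-form depth of maximum dose of the analytic model
#'
#' @param params A [beam_model_params()] object.
#' @return Depth of maximum dose \eqn{z^* = \ln(1 + k/\mu)/k}, cm.
#' @export
dmax_closed_form <- function(params) {
  stopifnot(inherits(params, "beam_model_params"))
  log1p(params$k_buildup / params$mu) / params$k_buildup
}

#' @export
print.beam_model_params <- function(x, ...) {
  cat(sprintf("<beam_model_params> %s, %g x %g cm2 field, SSD %g cm\n",
              x$energy_label, x$field_size, x$field_size, x$ssd))
  cat(sprintf("  mu %.5f /cm, k_buildup %.4f /cm (d_max %.3f cm)\n",
              x$mu, x$k_buildup, dmax_closed_form(x)))
  cat(sprintf("  penumbra sigma %.2f mm, scatter slope %.4f /cm, horns %.3f\n",
              x$penumbra_sigma, x$scatter_slope, x$horn_amplitude))
  if (x$wedge_transmission_gradient != 0)
    cat(sprintf("  wedge gradient %.3f /cm\n", x$wedge_transmission_gradient))
  cat(sprintf("  noise sd %.3g, seed %d\n", x$noise_sd, x$seed))
  invisible(x)
}

#' Load beam model parameters from a YAML or JSON configuration block
#'
#' @param source Path to a YAML/JSON file, or a named list already parsed.
#'   Recognised keys are the arguments of [beam_model_params()].
#' @return A [beam_model_params()] object.
#' @export
beam_params_from_config <- function(source) {
  cfg <- if (is.character(source)) read_config_file(source) else source
  if (!is.list(cfg)) abort_config("beam parameter config must be a named list")
  known <- names(formals(beam_model_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    abort_config(sprintf("unknown beam parameter key(s): %s",
                         paste(unknown, collapse = ", ")))
  do.call(beam_model_params, cfg)
}

read_config_file <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("config file not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}
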