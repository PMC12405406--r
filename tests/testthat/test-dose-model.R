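# Analytic beam simulator: calibration, shapes, determinism.

test_that("depth of maximum dose follows the closed form across parameter sets", {
  cases <- expand.grid(mu = c(0.03, 0.046, 0.0586), d_max = c(1.2, 1.4, 2.5))
  for (i in seq_len(nrow(cases))) {
    mu <- cases$mu[i]; dm <- cases$d_max[i]
    k <- solve_buildup_rate(mu, dm)
    expect_equal(log1p(k / mu) / k, dm, tolerance = 1e-10)
    p <- beam_model_params("custom", mu = mu, k_buildup = k)
    crv <- make_pdd_curve(p, seq(0, 30, 0.05))
    expect_lt(abs(crv$depths[which.max(crv$doses)] - dm), 0.05 + 1e-12)
  }
})

test_that("noiseless curves normalize to 100 and degenerate inputs error", {
  p <- beam_model_params("6MV")
  crv <- make_pdd_curve(p, seq(0, 30, 0.1))
  expect_equal(max(crv$doses), 100)
  expect_true(crv$normalized)
  # a single sampled depth is its own maximum
  single <- make_pdd_curve(p, dmax_closed_form(p))
  expect_equal(single$doses, 100)
  expect_error(make_pdd_curve(p, c(2, 1)), class = "beamqa_input_error")
  expect_error(make_pdd_curve(p, numeric()), class = "beamqa_input_error")
})

test_that("default 6 MV beam lands in the clinical D20/D5 band", {
  crv <- make_pdd_curve(beam_model_params("6MV"), seq(0, 30, 0.1))
  s <- pdd_summary(crv)
  expect_gt(s$d20_d5, 0.40)
  expect_lt(s$d20_d5, 0.44)
  # 12 MV is a more penetrating beam: strictly higher ratio
  s12 <- pdd_summary(make_pdd_curve(beam_model_params("12MV"), seq(0, 30, 0.1)))
  expect_gt(s12$d20_d5, s$d20_d5)
})

test_that("open symmetric profiles are even to machine precision", {
  p <- beam_model_params("6MV", horn_amplitude = 0)
  x <- seq(-80, 80, 0.5)
  pr <- make_profile(p, 10, x)
  expect_equal(pr$doses, rev(pr$doses), tolerance = 1e-12)
  # horns preserve evenness; a wedge gradient breaks it
  prh <- make_profile(beam_model_params("6MV"), 10, x)
  expect_equal(prh$doses, rev(prh$doses), tolerance = 1e-12)
  prw <- make_profile(beam_model_params("6MV", wedge_transmission_gradient = 0.3),
                      10, x)
  expect_gt(max(abs(prw$doses - rev(prw$doses))), 1)
})

test_that("vanishing penumbra width approaches a top-hat of the projected width", {
  p <- beam_model_params("custom", mu = 0.05, d_max = 1.4, field_size = 10,
                         ssd = 100, penumbra_sigma = 1e-6, horn_amplitude = 0)
  pr <- make_profile(p, 0, seq(-80, 80, 0.5))   # at the surface w = 100 mm
  expect_equal(pr$doses[abs(pr$positions) < 49.5],
               rep(100, sum(abs(pr$positions) < 49.5)), tolerance = 1e-9)
  expect_equal(pr$doses[abs(pr$positions) > 50.5],
               rep(0, sum(abs(pr$positions) > 50.5)), tolerance = 1e-9)
})

test_that("dose grids are separable, normalized, and seed-deterministic", {
  p <- beam_model_params("6MV")
  spec <- grid_spec(x = seq(-80, 80, 4), y = seq(-80, 80, 4), z = seq(0, 25, 1))
  g <- make_dose_grid(p, spec)
  expect_equal(max(g$values), 100)
  ax <- g$values[g$axes$x == 0, g$axes$y == 0, ]
  ax <- ax / max(ax) * 100
  expect_equal(ax, make_pdd_curve(p, spec$z)$doses, tolerance = 1e-9)
  pn <- beam_model_params("6MV", noise_sd = 0.02, seed = 77)
  expect_identical(make_dose_grid(pn, spec)$values,
                   make_dose_grid(pn, spec)$values)
  expect_error(make_dose_grid(p, grid_spec(x = seq(-80, 80, 0.1),
                                           y = seq(-80, 80, 0.1),
                                           z = seq(0, 25, 0.1))),
               class = "beamqa_resource_error")
})

test_that("noise generation leaves the session RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(make_pdd_curve(beam_model_params("6MV", noise_sd = 0.01, seed = 5),
                           seq(0, 30, 0.5)))
  expect_identical(.Random.seed, before)
})

test_that("perturb_grid is the identity at null settings and validates shifts", {
  p <- beam_model_params("6MV")
  g <- make_dose_grid(p, grid_spec(x = seq(-60, 60, 4), y = seq(-60, 60, 4),
                                   z = seq(0, 20, 1)))
  expect_identical(perturb_grid(g)$values, g$values)
  shifted <- perturb_grid(g, shift = c(x = 2))
  expect_identical(dim(shifted$values), dim(g$values))
  expect_false(identical(shifted$values, g$values))
  expect_identical(g$values, make_dose_grid(p, grid_spec(x = seq(-60, 60, 4),
    y = seq(-60, 60, 4), z = seq(0, 20, 1)))$values)  # original untouched
  expect_error(perturb_grid(g, shift = c(x = 500)), class = "beamqa_input_error")
  expect_error(perturb_grid(g, shift = c(w = 1)), class = "beamqa_input_error")
})

test_that("a pure lateral shift within the DTA passes gamma everywhere", {
  p <- beam_model_params("6MV")
  x <- seq(-80, 80, 1)
  ref <- make_profile(p, 10, x)
  ev <- lateral_profile(x, stats::approx(x + 2, ref$doses, xout = x, rule = 2)$y,
                        depth = 10)
  g <- compute_gamma(ref, ev, gamma_criteria(3, 3))
  expect_equal(summarize_gamma(g)$pass_rate, 1)
})

test_that("synthetic factor table is anchored, monotone and inside the clinical band", {
  mk <- function(f) beam_model_params("6MV", field_size = f)
  solo <- model_factor_table(list(mk(10)))
  expect_identical(solo$s_cp, 1)
  fields <- c(1, 2, 3, 4, 5, 7, 10, 15, 20, 25, 30, 35, 40)
  tab <- model_factor_table(lapply(fields, mk))
  expect_true(all(tab$s_cp >= 0.55 & tab$s_cp <= 1.22))
  expect_true(all(diff(tab$s_cp) >= 0))
  expect_true(all(diff(tab$s_c) >= 0))
  expect_equal(tab$s_cp[tab$field_size == 10], 1)
  expect_error(model_factor_table(list(mk(5))), class = "beamqa_input_error")
})

test_that("synthetic wedge factors are below one and decrease with the gradient", {
  mk <- function(g) beam_model_params("6MV",
                                      wedge_transmission_gradient = g,
                                      field_size = 10)
  wf <- vapply(c(0.02, 0.05, 0.1), function(g)
    model_factor_table(list(mk(g)))$wedge_factor, numeric(1))
  expect_true(all(wf < 1))
  expect_true(all(diff(wf) < 0))
})

test_that("parameters load from config blocks and reject unknown keys", {
  p <- beam_params_from_config(list(energy_label = "12MV", field_size = 20))
  expect_equal(p$field_size, 20)
  expect_equal(dmax_closed_form(p), 2.5, tolerance = 1e-9)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("energy_label: 6MV", "field_size: 5", "noise_sd: 0.01"), path)
  expect_equal(beam_params_from_config(path)$field_size, 5)
  expect_error(beam_params_from_config(list(energy_label = "6MV", fieldsize = 5)),
               class = "beamqa_config_error")
})
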