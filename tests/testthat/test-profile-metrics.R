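# Profile metrics: flatness, symmetry, penumbra, geometric penumbra.

erf_edge_profile <- function(sigma_l, sigma_r, w = 100, spacing = 0.1,
                             tilt = 0) {
  x <- seq(-w, w, spacing)
  d <- 100 * (pnorm((x + w / 2) / sigma_l) + pnorm((w / 2 - x) / sigma_r) - 1)
  if (tilt != 0) d <- d * (1 + tilt * x)
  lateral_profile(x, pmax(d, 0), depth = 10)
}

test_that("flatness is 100 for uniform cores and recovers constructed ratios", {
  # sigma = 1 mm: the edge is 10 sigma outside the central 80% region, so
  # the core really is uniform to machine precision
  flat <- erf_edge_profile(1, 1)
  expect_equal(flatness(flat), 100, tolerance = 1e-6)
  # constructed horns: max/min = 1 + a*(0.8)^2 at the edge of the region
  x <- seq(-80, 80, 0.5)
  w <- 100
  base <- pnorm((x + w / 2) / 1) + pnorm((w / 2 - x) / 1) - 1
  horn <- 100 * base * (1 + 0.1 * (2 * x / w)^2)
  pr <- lateral_profile(x, pmax(horn, 0), depth = 10)
  expect_equal(flatness(pr), 100 * (1 + 0.1 * 0.64), tolerance = 0.05)
  # invariance under global rescaling
  pr2 <- lateral_profile(x, pmax(horn, 0) * 7.3, depth = 10)
  expect_equal(flatness(pr2), flatness(pr), tolerance = 1e-9)
})

test_that("symmetry is 100 for even profiles and catches point asymmetries", {
  even <- erf_edge_profile(3, 3)
  expect_equal(symmetry(even), 100, tolerance = 1e-9)
  # single perturbed sample: D(5) = 102 vs D(-5) = 100
  x <- seq(-80, 80, 1)
  d <- rep(100, length(x))
  d[abs(x) > 50] <- 0
  d[x == 5] <- 102
  pr <- lateral_profile(x, d, depth = 10)
  expect_equal(symmetry(pr), 102, tolerance = 1e-9)
})

test_that("a linear tilt yields the analytic worst-pair ratio", {
  tilt <- 0.001   # +0.1% per mm
  pr <- erf_edge_profile(3, 3, tilt = tilt)
  fw <- field_width(pr)
  xa <- 0.4 * fw[["width"]]  # worst pair sits at the edge of the 80% region
  analytic <- (1 + tilt * xa) / (1 - tilt * xa) * 100
  expect_equal(symmetry(pr), analytic, tolerance = 0.05)
})

test_that("penumbra widths match the error-function closed form within 1%", {
  width_80_20 <- function(sigma) (qnorm(0.8) - qnorm(0.2)) * sigma
  for (sigma in c(2, 3.2, 4.5)) {
    pr <- erf_edge_profile(sigma, sigma)
    pen <- penumbra_widths(pr)
    expect_equal(pen[["left"]], width_80_20(sigma),
                 tolerance = 0.01 * width_80_20(sigma))
    expect_equal(pen[["right"]], width_80_20(sigma),
                 tolerance = 0.01 * width_80_20(sigma))
  }
  # asymmetric edges average the per-side closed forms
  pr <- erf_edge_profile(2, 4)
  pen <- penumbra_widths(pr)
  expect_equal(pen[["average"]], (width_80_20(2) + width_80_20(4)) / 2,
               tolerance = 0.01 * width_80_20(4))
  # sharp edges: the width vanishes with sigma (sampled finely enough to
  # resolve the edge)
  sharp <- erf_edge_profile(0.01, 0.01, spacing = 0.01)
  expect_lt(penumbra_widths(sharp)[["average"]], 0.05)
})

test_that("penumbra scales linearly with the generator edge width", {
  widths <- vapply(c(2, 4, 6), function(s) {
    p <- beam_model_params("6MV", penumbra_sigma = s, horn_amplitude = 0)
    penumbra_widths(make_profile(p, 10, seq(-120, 120, 0.2)))[["average"]]
  }, numeric(1))
  expect_equal(widths[2] / widths[1], 2, tolerance = 0.02)
  expect_equal(widths[3] / widths[1], 3, tolerance = 0.02)
})

test_that("missing crossings raise side-specific input errors", {
  x <- seq(-40, 40, 1)
  d <- 100 * pnorm((20 - x) / 3)   # falls only on the right side
  pr <- lateral_profile(x, d, depth = 10)
  err <- tryCatch(penumbra_widths(pr), error = identity)
  expect_s3_class(err, "beamqa_input_error")
  expect_match(conditionMessage(err), "left")
})

test_that("geometric penumbra follows the source-projection formula", {
  expect_equal(geometric_penumbra(s = 1, ssd = 1000, sdd = 500, depth = 100), 1.2)
  expect_equal(geometric_penumbra(s = 2, ssd = 1000, sdd = 500, depth = 100), 2.4)
  expect_equal(geometric_penumbra(s = 1, ssd = 900, sdd = 1000, depth = 100), 0)
  expect_error(geometric_penumbra(s = -1, ssd = 1000, sdd = 500, depth = 100),
               class = "beamqa_input_error")
  expect_error(geometric_penumbra(s = 1, ssd = 800, sdd = 1000, depth = 100),
               class = "beamqa_input_error")
})

test_that("profile summaries collect all metrics coherently", {
  pr <- make_profile(beam_model_params("6MV"), 10, seq(-120, 120, 0.5))
  s <- profile_summary(pr)
  expect_gte(s$flatness_percent, 100)
  expect_gte(s$symmetry_percent, 100)
  expect_gt(s$penumbra_avg_mm, 0)
  expect_equal(s$penumbra_avg_mm,
               (s$penumbra_left_mm + s$penumbra_right_mm) / 2)
  # projected 10 cm field at depth 10 cm: 110 mm between 50% edges
  expect_equal(s$field_width_mm, 110, tolerance = 1)
})
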