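# Gamma engine: analytic single-point cases, invariances, oracle agreement.

test_that("criteria objects validate their invariants", {
  expect_error(gamma_criteria(dose_tolerance_percent = 0),
               class = "beamqa_input_error")
  expect_error(gamma_criteria(dta_mm = -1), class = "beamqa_input_error")
  expect_error(gamma_criteria(search_limit_factor = 0.5),
               class = "beamqa_input_error")
  expect_error(gamma_criteria(dose_threshold_percent = 100),
               class = "beamqa_input_error")
  expect_error(gamma_criteria(interp_step_mm = 5, dta_mm = 3),
               class = "beamqa_input_error")
})

test_that("identical distributions give gamma exactly zero everywhere", {
  pr <- make_profile(beam_model_params("6MV"), 10, seq(-70, 70, 1))
  g <- compute_gamma(pr, pr)
  expect_identical(unique(g$gamma), 0)
  s <- summarize_gamma(g)
  expect_equal(s$pass_rate, 1)
  expect_equal(s$frac_excellent, 1)
  # the oracle agrees up to its optimizer tolerance
  go <- gamma_oracle(pr, pr)
  expect_lt(max(go$gamma), 1e-6)
})

test_that("single-point dose and distance offsets hit the criterion exactly", {
  ref <- lateral_profile(0, 100)
  # co-located point at the dose tolerance: gamma = dose term = 1
  expect_equal(compute_gamma(ref, lateral_profile(0, 103),
                             gamma_criteria(3, 3))$gamma, 1)
  # matching dose at the DTA: gamma = distance term = 1
  expect_equal(compute_gamma(ref, lateral_profile(3, 100),
                             gamma_criteria(3, 3))$gamma, 1)
  # both offsets combine in quadrature
  expect_equal(compute_gamma(ref, lateral_profile(3, 103),
                             gamma_criteria(3, 3))$gamma, sqrt(2))
})

test_that("engine matches the brute-force oracle on random 1-D and 2-D cases", {
  crit1 <- gamma_criteria(3, 3, interp_step_mm = 0.3)
  for (s in 1:10) {
    pair <- random_scan_pair(s)
    g <- compute_gamma(pair$reference, pair$evaluated, crit1)
    go <- gamma_oracle(pair$reference, pair$evaluated, crit1)
    expect_lt(max(abs(g$gamma - go$gamma)), 1e-6)
  }
  crit2 <- gamma_criteria(3, 3, interp_step_mm = 1)
  for (s in 101:102) {
    pair <- random_grid_pair(s, n = 10, spacing = 2.2)
    g <- compute_gamma(pair$reference, pair$evaluated, crit2)
    go <- gamma_oracle(pair$reference, pair$evaluated, crit2)
    expect_lt(max(abs(g$gamma - go$gamma)), 1e-6)
  }
})

test_that("gamma is monotone in both tolerances", {
  pair <- random_scan_pair(42)
  base <- compute_gamma(pair$reference, pair$evaluated,
                        gamma_criteria(3, 3))$gamma
  tol <- 1e-7   # refinement precision
  for (crit in list(gamma_criteria(4, 3), gamma_criteria(3, 4),
                    gamma_criteria(6, 6))) {
    wider <- compute_gamma(pair$reference, pair$evaluated, crit)$gamma
    expect_true(all(wider <= base + tol))
  }
  for (crit in list(gamma_criteria(2, 3), gamma_criteria(3, 2))) {
    tighter <- compute_gamma(pair$reference, pair$evaluated, crit)$gamma
    expect_true(all(tighter >= base - tol))
  }
})

test_that("global-normalization gamma is invariant under joint rescaling", {
  pair <- random_scan_pair(7)
  g1 <- compute_gamma(pair$reference, pair$evaluated)$gamma
  scale_scan <- function(scan, c) lateral_profile(scan$positions,
                                                  scan$doses * c,
                                                  depth = scan$depth)
  g2 <- compute_gamma(scale_scan(pair$reference, 3.7),
                      scale_scan(pair$evaluated, 3.7))$gamma
  expect_equal(g1, g2, tolerance = 1e-9)
})

test_that("local normalization penalizes low-dose discrepancies harder", {
  x <- seq(0, 40, 1)
  ref <- lateral_profile(x, 100 * exp(-x / 15))
  ev <- lateral_profile(x, 103 * exp(-x / 15))
  gl <- compute_gamma(ref, ev, gamma_criteria(3, 3, "global"))$gamma
  ll <- compute_gamma(ref, ev, gamma_criteria(3, 3, "local"))$gamma
  expect_true(all(ll >= gl - 1e-9))
  zero_ref <- lateral_profile(c(0, 1), c(0, 100))
  expect_error(compute_gamma(zero_ref, zero_ref,
                             gamma_criteria(3, 3, "local")),
               class = "beamqa_input_error")
})

test_that("the dose threshold masks low-dose reference points", {
  x <- seq(0, 40, 1)
  ref <- lateral_profile(x, 100 * exp(-x / 8))
  g <- compute_gamma(ref, ref, gamma_criteria(dose_threshold_percent = 10))
  expect_true(any(!g$evaluated_mask))
  expect_true(all(is.na(g$gamma[!g$evaluated_mask])))
  expect_identical(g$evaluated_mask, ref$doses >= 10)
  all_masked <- structure(list(gamma = rep(NA_real_, 3),
                               evaluated_mask = rep(FALSE, 3),
                               criteria = gamma_criteria()),
                          class = "gamma_map")
  expect_error(summarize_gamma(all_masked), class = "beamqa_input_error")
})

test_that("mismatched input kinds are rejected", {
  pr <- make_profile(beam_model_params("6MV"), 10, seq(-50, 50, 2))
  g <- make_dose_grid(beam_model_params("6MV"),
                      grid_spec(x = seq(-50, 50, 10), y = seq(-50, 50, 10),
                                z = seq(0, 10, 2)))
  expect_error(compute_gamma(pr, g), class = "beamqa_input_error")
  g1 <- dose_grid(c(1, 2), x = c(0, 1))
  expect_error(compute_gamma(g, g1), class = "beamqa_input_error")
})

test_that("summary bins count as specified", {
  s <- summarize_gamma(c(0.4, 0.4, 0.7, 1.2))
  expect_equal(s$frac_excellent, 0.5)
  expect_equal(s$frac_good, 0.25)
  expect_equal(s$frac_poor, 0.25)
  expect_equal(s$pass_rate, 0.75)
  expect_equal(s$frac_excellent + s$frac_good + s$frac_poor, 1,
               tolerance = 1e-12)
  # boundary conventions: 0.5 is excellent, 1.0 is poor and fails
  b <- summarize_gamma(c(0.5, 1.0))
  expect_equal(b$frac_excellent, 0.5)
  expect_equal(b$frac_poor, 0.5)
  expect_equal(b$pass_rate, 0.5)
})

test_that("a binned map reproduces the conventional agreement pattern", {
  g <- c(rep(0.2, 34), rep(0.7, 5), rep(1.3, 1))   # 85% / 12.5% / 2.5%
  s <- summarize_gamma(g)
  expect_equal(100 * s$frac_excellent, 85)
  expect_equal(100 * s$frac_good, 12.5)
  expect_equal(100 * s$frac_poor, 2.5)
  expect_equal(100 * s$pass_rate, 97.5)
})

test_that("tightening the DTA never lowers gamma (oracle superset property)", {
  pair <- random_scan_pair(13)
  g3 <- gamma_oracle(pair$reference, pair$evaluated, gamma_criteria(3, 3))$gamma
  g2 <- gamma_oracle(pair$reference, pair$evaluated, gamma_criteria(3, 2))$gamma
  expect_true(all(g2 >= g3 - 1e-7))
  expect_error(gamma_oracle(pair$reference, pair$evaluated, max_points = 10),
               class = "beamqa_resource_error")
})
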