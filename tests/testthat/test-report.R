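# Comparative reporting: beam tables, deviations, gamma reports, config runs.

test_that("beam tables assemble scan summaries under unique keys", {
  p <- beam_model_params("6MV", field_size = 5)
  scan <- make_pdd_curve(p, seq(0, 30, 0.1))
  tab <- build_beam_table(list(scan),
                          data.frame(energy_label = "6MV", field_size = 5,
                                     source_label = "model"))
  expect_s3_class(tab, "beam_summary_table")
  expect_identical(nrow(tab), 1L)
  expect_equal(tab$d_max, 1.4)
  expect_named(tab, c("energy_label", "field_size", "source_label", "d_max",
                      "pdd5", "pdd10", "pdd20", "d20_d5"))
  expect_error(build_beam_table(list(scan, scan),
                                data.frame(energy_label = c("6MV", "6MV"),
                                           field_size = c(5, 5),
                                           source_label = c("model", "model"))),
               class = "beamqa_input_error")
  empty <- build_beam_table(list())
  expect_identical(nrow(empty), 0L)
})

test_that("tables from tabulated PDD values reproduce the tabulated reference ratios", {
  tabulated <- list(
    list(fs = 5, pdd = c(89.5, 71.4, 36.8), ratio = 0.411),
    list(fs = 10, pdd = c(90.1, 72.2, 37.4), ratio = 0.415),
    list(fs = 20, pdd = c(90.8, 73.0, 38.1), ratio = 0.420))
  scans <- lapply(tabulated, function(row)
    tabulated_pdd_curve(row$pdd[1], row$pdd[2], row$pdd[3]))
  labels <- data.frame(energy_label = "6MV",
                       field_size = vapply(tabulated, `[[`, numeric(1), "fs"),
                       source_label = "tabulated")
  tab <- build_beam_table(scans, labels)
  expect_equal(round(tab$d20_d5, 3),
               vapply(tabulated, `[[`, numeric(1), "ratio"))
})

test_that("self-comparison reports are identically zero", {
  fields <- c(5, 10, 20)
  tab <- model_factor_table(lapply(fields, function(f)
    beam_model_params("6MV", field_size = f)))
  rep <- compare_tables(tab, tab)
  expect_equal(rep$max_abs_deviation, 0)
  expect_true(all(rep$deviations$deviation == 0))
})

test_that("tabulated wedge factors deviate by the tabulated margin", {
  mk_tab <- function(values) {
    tab <- data.frame(energy_label = "6MV", field_size = c(5, 10),
                      wedge_factor = values)
    class(tab) <- c("factor_table", "data.frame")
    tab
  }
  rep <- compare_tables(mk_tab(c(0.686, 0.695)), mk_tab(c(0.689, 0.698)))
  expect_equal(rep$deviations$deviation, c(0.003, 0.003), tolerance = 1e-9)
  expect_equal(rep$max_abs_deviation, 0.003, tolerance = 1e-9)
  expect_error(compare_tables(mk_tab(c(0.7, 0.7)),
                              model_factor_table(list(beam_model_params("12MV")))),
               class = "beamqa_input_error")
})

test_that("gamma reports tabulate pair summaries and handle empty input", {
  p <- beam_model_params("6MV")
  pr <- make_profile(p, 10, seq(-70, 70, 1))
  rep <- gamma_report(list(list(reference = pr, evaluated = pr,
                                label = "self")))
  expect_equal(rep$pct_lt_1, 100)
  expect_equal(rep$pct_le_0.5, 100)
  empty <- gamma_report(list())
  expect_identical(nrow(empty), 0L)
})

test_that("config-driven runs are complete, deterministic and validated", {
  cfg <- list(
    seed = 7,
    output_dir = file.path(tempdir(), "beamqa-run-a"),
    beams = list(list(label = "6MV-10x10", energy_label = "6MV", field_size = 10),
                 list(label = "12MV-10x10", energy_label = "12MV", field_size = 10)),
    gamma = list(dose_tolerance_percent = 3, dta_mm = 3,
                 noise_sd = 0.01, shift_mm = 1))
  files <- run_config(cfg)
  expect_true(all(file.exists(unlist(files))))
  tab <- utils::read.csv(files[["beam_table.csv"]])
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$d_max, c(1.4, 2.5))
  gam <- utils::read.csv(files[["gamma_report.csv"]])
  expect_true(all(gam$pct_lt_1 >= 94))
  # byte-identical rerun into a second directory
  cfg_b <- cfg
  cfg_b$output_dir <- file.path(tempdir(), "beamqa-run-b")
  files_b <- run_config(cfg_b)
  for (nm in names(files)) {
    expect_identical(readLines(unlist(files_b[[nm]])),
                     readLines(unlist(files[[nm]])))
  }
  bad <- cfg
  bad$bogus_key <- 1
  expect_error(run_config(bad), class = "beamqa_config_error")
  bad2 <- cfg
  bad2$gamma$unknown <- 2
  expect_error(run_config(bad2), class = "beamqa_config_error")
})
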