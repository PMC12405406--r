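# Comparative QA reporting: beam summary tables, source-vs-source deviation
# reports, gamma reports over distribution pairs, and a config-driven
# end-to-end run writing all artifacts to disk.

#' Build a beam summary table from depth-dose scans
#'
#' Runs [pdd_summary()] on each scan and assembles the rows into a table
#' keyed by (energy, field size, source).
#'
#' @param scans List of [depth_dose_curve()]s, each covering 5-20 cm.
#' @param labels Optional data frame (or list of lists) with one row per
#'   scan and columns \code{energy_label}, \code{field_size},
#'   \code{source_label}; defaults to each scan's metadata.
#' @return A \code{beam_summary_table} (data frame) with columns
#'   energy_label, field_size, source_label, d_max, pdd5, pdd10, pdd20,
#'   d20_d5. An empty scan list yields an empty table.
#' @export
build_beam_table <- function(scans, labels = NULL) {
  if (!length(scans)) {
    out <- data.frame(energy_label = character(), field_size = numeric(),
                      source_label = character(), d_max = numeric(),
                      pdd5 = numeric(), pdd10 = numeric(), pdd20 = numeric(),
                      d20_d5 = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("beam_summary_table", "data.frame")
    return(out)
  }
  if (!is.null(labels) && !is.data.frame(labels))
    labels <- do.call(rbind, lapply(labels, as.data.frame))
  rows <- lapply(seq_along(scans), function(i) {
    scan <- scans[[i]]
    lab <- if (!is.null(labels)) as.list(labels[i, , drop = FALSE]) else scan$metadata
    s <- pdd_summary(scan)
    data.frame(energy_label = as.character(lab$energy_label %||% lab$energy %||% NA),
               field_size = as.numeric(lab$field_size %||% NA),
               source_label = as.character(lab$source_label %||% lab$source %||% "model"),
               d_max = s$d_max, pdd5 = s$pdd5, pdd10 = s$pdd10,
               pdd20 = s$pdd20, d20_d5 = s$d20_d5, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  key <- paste(out$energy_label, out$field_size, out$source_label)
  if (anyDuplicated(key))
    abort_input(sprintf("duplicate (energy, field, source) keys: %s",
                        paste(unique(key[duplicated(key)]), collapse = "; ")))
  class(out) <- c("beam_summary_table", "data.frame")
  out
}

#' @export
print.beam_summary_table <- function(x, ...) {
  cat(sprintf("<beam_summary_table> %d rows\n", nrow(x)))
  y <- as.data.frame(x)
  if (nrow(y)) {
    for (col in c("pdd5", "pdd10", "pdd20")) y[[col]] <- round(y[[col]], 1)
    y$d20_d5 <- round(y$d20_d5, 3)
    y$d_max <- round(y$d_max, 1)
  }
  print(y, row.names = FALSE)
  invisible(x)
}

table_kind <- function(x) {
  if (inherits(x, "beam_summary_table")) "beam_summary_table"
  else if (inherits(x, "factor_table")) "factor_table"
  else if (is.data.frame(x) &&
           all(c("energy_label", "field_size") %in% names(x))) "metric_table"
  else abort_input("expected a beam_summary_table, factor_table, or a data frame keyed by energy_label and field_size")
}

#' Compare two summary tables from different sources
#'
#' Joins two tables of the same kind on (energy, field size) and reports,
#' per shared key and numeric metric, the deviation \code{b - a} and its
#' absolute value, plus max/mean absolute deviation summaries. A table
#' compared with itself reports identically zero deviations.
#'
#' @param a,b Two \code{beam_summary_table}s, two \code{factor_table}s, or
#'   two plain data frames keyed by \code{energy_label} and
#'   \code{field_size} (any numeric columns are compared as metrics).
#' @return Object of class \code{comparison_report}: a list with
#'   \code{deviations} (long data frame), \code{max_abs_deviation},
#'   \code{mean_abs_deviation} and the table \code{kind}.
#' @export
compare_tables <- function(a, b) {
  kind <- table_kind(a)
  if (!identical(kind, table_kind(b)))
    abort_input("tables must be of the same kind")
  keys <- c("energy_label", "field_size")
  metrics <- setdiff(names(a)[vapply(a, is.numeric, logical(1))], "field_size")
  ka <- paste(a$energy_label, a$field_size)
  kb <- paste(b$energy_label, b$field_size)
  shared <- intersect(ka, kb)
  if (!length(shared)) abort_input("tables share no (energy, field size) keys")
  rows <- list()
  for (k in shared) {
    ia <- which(ka == k)[1]
    ib <- which(kb == k)[1]
    for (m in metrics) {
      va <- a[[m]][ia]; vb <- b[[m]][ib]
      if (is.na(va) && is.na(vb)) next
      rows[[length(rows) + 1L]] <- data.frame(
        energy_label = a$energy_label[ia], field_size = a$field_size[ia],
        metric = m, a = va, b = vb, deviation = vb - va,
        abs_deviation = abs(vb - va), stringsAsFactors = FALSE)
    }
  }
  dev <- do.call(rbind, rows)
  structure(list(deviations = dev,
                 max_abs_deviation = max(dev$abs_deviation),
                 mean_abs_deviation = mean(dev$abs_deviation),
                 kind = kind),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s, %d comparisons: max |dev| %.4g, mean |dev| %.4g\n",
              x$kind, nrow(x$deviations), x$max_abs_deviation,
              x$mean_abs_deviation))
  invisible(x)
}

#' Gamma agreement report over distribution pairs
#'
#' Runs [compute_gamma()] and [summarize_gamma()] for each labelled
#' (reference, evaluated) pair and tabulates the binned agreement
#' percentages: \code{pct_lt_1} (gamma < 1.0, the passing rate) and
#' \code{pct_le_0.5} (gamma <= 0.5), plus the good/poor bins.
#'
#' @param pairs List of lists with elements \code{reference},
#'   \code{evaluated} and \code{label}.
#' @param criteria A [gamma_criteria()].
#' @return A \code{gamma_report} data frame with one row per pair;
#'   percentages are stored unrounded (report formatting uses one decimal).
#' @export
gamma_report <- function(pairs, criteria = gamma_criteria()) {
  rows <- lapply(pairs, function(pr) {
    s <- summarize_gamma(compute_gamma(pr$reference, pr$evaluated, criteria))
    data.frame(label = pr$label %||% "", n = s$n,
               pct_lt_1 = 100 * s$pass_rate,
               pct_le_0.5 = 100 * s$frac_excellent,
               pct_good = 100 * s$frac_good,
               pct_poor = 100 * s$frac_poor, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(label = character(), n = integer(),
                         pct_lt_1 = numeric(), pct_le_0.5 = numeric(),
                         pct_good = numeric(), pct_poor = numeric(),
                         stringsAsFactors = FALSE)
  attr(out, "criteria") <- criteria
  class(out) <- c("gamma_report", "data.frame")
  out
}

#' @export
print.gamma_report <- function(x, ...) {
  crit <- attr(x, "criteria")
  cat(sprintf("<gamma_report> %d pairs, %g%%/%gmm (%s), reference -> evaluated\n",
              nrow(x), crit$dose_tolerance_percent, crit$dta_mm,
              crit$normalization))
  y <- as.data.frame(x)
  if (nrow(y)) {
    names(y) <- sub("^pct_lt_1$", "GI < 1.0 (%)", names(y))
    names(y) <- sub("^pct_le_0.5$", "GI <= 0.5 (%)", names(y))
    for (col in 3:6) y[[col]] <- sprintf("%.1f", y[[col]])
  }
  print(y, row.names = FALSE)
  invisible(x)
}

# ---- config-driven end-to-end run ------------------------------------------

#' Run a full QA analysis from a configuration
#'
#' Generates beams from the configured parameters and writes beam summary,
#' profile, gamma and factor tables (CSV + JSON) plus a parameter log to the
#' output directory. Outputs are deterministic given the configured seed.
#'
#' Recognised top-level keys: \code{seed}, \code{output_dir}, \code{beams}
#' (list of [beam_model_params()] argument blocks, each optionally with a
#' \code{label}), \code{analyses} (subset of \code{"pdd"},
#' \code{"profile"}, \code{"gamma"}, \code{"factors"}; default all),
#' \code{gamma} (criteria arguments plus optional \code{shift_mm},
#' \code{scale}, \code{noise_sd} describing the synthetic evaluated
#' distribution) and \code{profile_depth} (cm, default 10).
#'
#' @param config Path to a YAML/JSON file or an equivalent named list.
#' @return Invisibly, a named list of the file paths written.
#' @export
run_config <- function(config) {
  cfg <- if (is.character(config)) read_config_file(config) else config
  if (!is.list(cfg)) abort_config("config must be a named list")
  known <- c("seed", "output_dir", "beams", "analyses", "gamma", "profile_depth")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    abort_config(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  if (is.null(cfg$output_dir)) abort_config("config requires `output_dir`")
  if (is.null(cfg$beams) || !length(cfg$beams)) abort_config("config requires `beams`")
  seed <- as.integer(cfg$seed %||% 1L)
  analyses <- cfg$analyses %||% c("pdd", "profile", "gamma", "factors")
  bad <- setdiff(analyses, c("pdd", "profile", "gamma", "factors"))
  if (length(bad))
    abort_config(sprintf("unknown analyses: %s", paste(bad, collapse = ", ")))
  out_dir <- cfg$output_dir
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    beamqa_abort(sprintf("cannot create output directory %s", out_dir),
                 "beamqa_io_error")
  depth <- as.numeric(cfg$profile_depth %||% 10)

  beams <- lapply(seq_along(cfg$beams), function(i) {
    blk <- cfg$beams[[i]]
    label <- blk$label %||% sprintf("beam%d", i)
    blk$label <- NULL
    blk$seed <- blk$seed %||% (seed + i)
    list(label = label, params = beam_params_from_config(blk))
  })

  gcfg <- cfg$gamma %||% list()
  crit_keys <- intersect(names(gcfg), names(formals(gamma_criteria)))
  criteria <- do.call(gamma_criteria, gcfg[crit_keys])
  extra <- setdiff(names(gcfg), c(crit_keys, "shift_mm", "scale", "noise_sd"))
  if (length(extra))
    abort_config(sprintf("unknown gamma key(s): %s", paste(extra, collapse = ", ")))

  depths <- seq(0, 30, 0.1)
  positions_for <- function(p) {
    half <- field_width_at_depth(p, depth) / 2 + 8 * p$penumbra_sigma
    seq(-ceiling(half), ceiling(half), by = 1)
  }
  written <- list()
  emit <- function(df, name, round_cols = list()) {
    y <- as.data.frame(df)
    for (col in names(round_cols))
      if (col %in% names(y)) y[[col]] <- round(y[[col]], round_cols[[col]])
    csv <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(y, csv, row.names = FALSE)
    js <- file.path(out_dir, paste0(name, ".json"))
    jsonlite::write_json(as.data.frame(df), js, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written[[paste0(name, ".csv")]] <<- csv
    written[[paste0(name, ".json")]] <<- js
  }

  if ("pdd" %in% analyses) {
    scans <- lapply(beams, function(b) make_pdd_curve(b$params, depths))
    labels <- data.frame(
      energy_label = vapply(beams, function(b) b$params$energy_label, character(1)),
      field_size = vapply(beams, function(b) b$params$field_size, numeric(1)),
      source_label = vapply(beams, `[[`, character(1), "label"),
      stringsAsFactors = FALSE)
    emit(build_beam_table(scans, labels), "beam_table",
         list(d_max = 1, pdd5 = 1, pdd10 = 1, pdd20 = 1, d20_d5 = 3))
  }
  if ("profile" %in% analyses) {
    rows <- lapply(beams, function(b) {
      s <- profile_summary(make_profile(b$params, depth, positions_for(b$params)))
      data.frame(source_label = b$label, energy_label = b$params$energy_label,
                 field_size = b$params$field_size, depth_cm = depth,
                 flatness = s$flatness_percent, symmetry = s$symmetry_percent,
                 penumbra_avg = s$penumbra_avg_mm,
                 field_width = s$field_width_mm, stringsAsFactors = FALSE)
    })
    emit(do.call(rbind, rows), "profile_table",
         list(flatness = 2, symmetry = 2, penumbra_avg = 2, field_width = 1))
  }
  if ("gamma" %in% analyses) {
    pairs <- lapply(beams, function(b) {
      ref <- make_pdd_curve(b$params, depths)
      noisy <- b$params
      noisy$noise_sd <- as.numeric(gcfg$noise_sd %||% 0.01)
      ev <- make_pdd_curve(noisy, depths)
      shift <- as.numeric(gcfg$shift_mm %||% 0) / 10   # mm -> depth cm
      if (shift != 0) {
        shifted <- stats::approx(ev$depths + shift, ev$doses, xout = ev$depths,
                                 rule = 2)$y
        ev <- depth_dose_curve(ev$depths, shifted, metadata = ev$metadata)
      }
      scl <- as.numeric(gcfg$scale %||% 1)
      if (scl != 1) ev <- depth_dose_curve(ev$depths, ev$doses * scl,
                                           metadata = ev$metadata)
      list(reference = ref, evaluated = ev, label = b$label)
    })
    emit(gamma_report(pairs, criteria), "gamma_report",
         list(pct_lt_1 = 1, `pct_le_0.5` = 1, pct_good = 1, pct_poor = 1))
  }
  if ("factors" %in% analyses) {
    energies <- unique(vapply(beams, function(b) b$params$energy_label, character(1)))
    plist <- list()
    for (en in energies) {
      fields <- sort(unique(c(10, vapply(beams[vapply(beams, function(b)
        b$params$energy_label == en, logical(1))],
        function(b) b$params$field_size, numeric(1)))))
      tmpl <- beams[[which(vapply(beams, function(b)
        b$params$energy_label == en, logical(1)))[1]]]$params
      for (f in fields) {
        q <- tmpl
        q$field_size <- f
        plist[[length(plist) + 1L]] <- q
      }
    }
    emit(model_factor_table(plist), "factor_table",
         list(s_cp = 3, s_c = 3, wedge_factor = 3))
  }

  log_path <- file.path(out_dir, "run_log.txt")
  log <- c("beamqa run log",
           sprintf("seed: %d", seed),
           sprintf("analyses: %s", paste(analyses, collapse = ", ")),
           sprintf("gamma criteria: %g%%/%gmm, %s normalization, threshold %g%%, search %gx, interp %g mm",
                   criteria$dose_tolerance_percent, criteria$dta_mm,
                   criteria$normalization, criteria$dose_threshold_percent,
                   criteria$search_limit_factor, criteria$interp_step_mm),
           sprintf("profile depth: %g cm", depth),
           "beams:",
           vapply(beams, function(b)
             sprintf("  %s: %s field %g cm, mu %.6f /cm, k %.4f /cm, sigma %.2f mm, noise %g, seed %d",
                     b$label, b$params$energy_label, b$params$field_size,
                     b$params$mu, b$params$k_buildup, b$params$penumbra_sigma,
                     b$params$noise_sd, b$params$seed), character(1)))
  writeLines(log, log_path)
  written[["run_log.txt"]] <- log_path
  invisible(written)
}
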