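# Plain-text formats. Both dialects are self-describing, diff-able CSV-style
# text with `#`-prefixed metadata, and serialize doses with 17 significant
# digits so write/read round-trips are value-exact.

fmt17 <- function(x) sprintf("%.17g", x)

#' Write / read a dose grid as self-describing text
#'
#' Dialect: one `#axis <name> <unit> <n> <values...>` header line per axis
#' (axis order x, y, z restricted to the axes present), optional
#' `#unit <label>` and `#meta <key> <value>` lines, then one dose value per
#' line with the x index varying fastest, then y, then z.
#'
#' @param grid A [dose_grid()].
#' @param destination,source File path.
#' @return `read_dose_grid` returns a [dose_grid()]; `write_dose_grid`
#'   invisibly returns the path.
#' @export
write_dose_grid <- function(grid, destination) {
  stopifnot(inherits(grid, "dose_grid"))
  units <- c(x = "mm", y = "mm", z = "cm")
  hdr <- vapply(names(grid$axes), function(nm) {
    coords <- grid$axes[[nm]]
    paste("#axis", nm, units[[nm]], length(coords),
          paste(fmt17(coords), collapse = " "))
  }, character(1))
  hdr <- c(hdr, paste("#unit", grid$unit_label))
  meta <- grid$provenance
  meta <- meta[vapply(meta, function(v) is.character(v) || is.numeric(v), logical(1))]
  hdr <- c(hdr, vapply(names(meta), function(k)
    paste("#meta", k, paste(format(meta[[k]]), collapse = " ")), character(1)))
  writeLines(c(hdr, fmt17(as.vector(grid$values))), destination)
  invisible(destination)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(source) {
  if (!file.exists(source)) abort_format(sprintf("no such file: %s", source))
  lines <- readLines(source, warn = FALSE)
  axes <- list()
  unit_label <- "relative"
  provenance <- list()
  i <- 0L
  for (ln in lines) {
    if (!startsWith(ln, "#")) break
    i <- i + 1L
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (tok[1] == "#axis") {
      if (length(tok) < 5L)
        abort_format(sprintf("line %d: malformed axis header: %s", i, ln))
      nm <- tok[2]
      if (!nm %in% c("x", "y", "z"))
        abort_format(sprintf("line %d: unknown axis name `%s`", i, nm))
      n <- suppressWarnings(as.integer(tok[4]))
      coords <- suppressWarnings(as.numeric(tok[-(1:4)]))
      if (is.na(n) || anyNA(coords) || length(coords) != n)
        abort_format(sprintf("line %d: axis header declares %s values but carries %d",
                             i, tok[4], length(coords)))
      axes[[nm]] <- coords
    } else if (tok[1] == "#unit") {
      unit_label <- paste(tok[-1], collapse = " ")
    } else if (tok[1] == "#meta" && length(tok) >= 3L) {
      provenance[[tok[2]]] <- paste(tok[-(1:2)], collapse = " ")
    } else {
      abort_format(sprintf("line %d: unrecognised header line: %s", i, ln))
    }
  }
  if (!length(axes)) abort_format("no #axis header lines found")
  body <- lines[-seq_len(i)]
  body <- body[nzchar(trimws(body))]
  values <- suppressWarnings(as.numeric(body))
  if (anyNA(values)) {
    bad <- which(is.na(values))[1]
    abort_format(sprintf("line %d: non-numeric dose value: %s", i + bad, body[bad]))
  }
  expected <- prod(vapply(axes, length, integer(1)))
  if (length(values) != expected)
    abort_format(sprintf("header declares %d values but file carries %d data rows",
                         expected, length(values)))
  if (any(values < 0)) {
    bad <- which(values < 0)[1]
    abort_format(sprintf("line %d: negative dose %s", i + bad, body[bad]))
  }
  vals <- if (length(axes) == 1L) values
          else array(values, dim = unname(vapply(axes, length, integer(1))))
  args <- c(list(values = vals), axes,
            list(unit_label = unit_label, provenance = provenance))
  tryCatch(do.call(dose_grid, args),
           beamqa_input_error = function(e) abort_format(conditionMessage(e)))
}

#' Write / read a 1-D scan (depth-dose curve or lateral profile) as CSV
#'
#' Two-column CSV `abscissa,dose` preceded by `#<key> <value>` metadata
#' comments. The `#kind` key (`pdd` or `profile`) selects the object type on
#' read; depth-dose abscissae are depths in cm, profile abscissae off-axis
#' positions in mm.
#'
#' @param scan A [depth_dose_curve()] or [lateral_profile()].
#' @param destination,source File path.
#' @return `read_scan_table` returns a [depth_dose_curve()] or
#'   [lateral_profile()]; `write_scan_table` invisibly returns the path.
#' @export
write_scan_table <- function(scan, destination) {
  if (inherits(scan, "depth_dose_curve")) {
    kind <- "pdd"
    abscissa <- scan$depths
    extra <- c(normalized = tolower(as.character(scan$normalized)))
  } else if (inherits(scan, "lateral_profile")) {
    kind <- "profile"
    abscissa <- scan$positions
    extra <- if (is.finite(scan$depth)) c(depth = fmt17(scan$depth)) else c()
  } else abort_input("`scan` must be a depth_dose_curve or lateral_profile")
  meta <- scan$metadata
  meta <- meta[vapply(meta, function(v) length(v) == 1L &&
                        (is.character(v) || is.numeric(v)), logical(1))]
  hdr <- c(paste("#kind", kind),
           if (length(extra)) paste0("#", names(extra), " ", unname(extra)),
           if (length(meta)) vapply(names(meta), function(k)
             paste0("#", k, " ", format(meta[[k]])), character(1)))
  body <- paste(fmt17(abscissa), fmt17(scan$doses), sep = ",")
  writeLines(c(hdr, "abscissa,dose", body), destination)
  invisible(destination)
}

#' @rdname write_scan_table
#' @export
read_scan_table <- function(source) {
  if (!file.exists(source)) abort_format(sprintf("no such file: %s", source))
  lines <- readLines(source, warn = FALSE)
  meta <- list()
  i <- 0L
  for (ln in lines) {
    if (!startsWith(ln, "#")) break
    i <- i + 1L
    tok <- strsplit(sub("^#", "", trimws(ln)), "[[:space:]]+")[[1]]
    if (length(tok) >= 2L) meta[[tok[1]]] <- paste(tok[-1], collapse = " ")
  }
  body <- lines[-seq_len(i)]
  body <- body[nzchar(trimws(body))]
  if (length(body) && tolower(body[1]) == "abscissa,dose") body <- body[-1]
  if (!length(body)) abort_format("scan table has no data rows")
  parts <- strsplit(body, ",", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    abort_format(sprintf("line %d: expected two comma-separated values",
                         i + which(lengths(parts) != 2L)[1] + 1L))
  abscissa <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 1L)))
  dose <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  if (anyNA(abscissa) || anyNA(dose)) abort_format("non-numeric scan value")
  if (length(abscissa) > 1L && any(diff(abscissa) <= 0))
    abort_format("scan abscissa must be strictly increasing")
  if (any(dose < 0)) abort_format("scan doses must be non-negative")
  kind <- meta$kind %||% "pdd"
  meta$kind <- NULL
  wrap <- function(e) abort_format(conditionMessage(e))
  if (identical(kind, "profile")) {
    depth <- suppressWarnings(as.numeric(meta$depth %||% NA_real_))
    meta$depth <- NULL
    tryCatch(lateral_profile(abscissa, dose, depth = depth, metadata = meta),
             beamqa_input_error = wrap)
  } else if (identical(kind, "pdd")) {
    normalized <- identical(tolower(meta$normalized %||% "false"), "true")
    meta$normalized <- NULL
    tryCatch(depth_dose_curve(abscissa, dose, normalized = normalized,
                              metadata = meta),
             beamqa_input_error = wrap)
  } else abort_format(sprintf("unknown scan kind `%s`", kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
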