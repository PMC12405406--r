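# Minimal DICOM RT Dose importer. Parses just enough of the DICOM binary
# encoding (explicit or implicit VR, little endian, uncompressed) to
# recover the dose grid: pixel matrix, dose-grid scaling, pixel spacing,
# image position and the frame offset vector. Undefined-length items,
# sequences and compressed transfer syntaxes are out of scope.

TAG <- function(group, element) sprintf("%04X,%04X", group, element)

read_u16 <- function(raw, off) {
  as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
}
read_u32 <- function(raw, off) {
  sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
}
bytes_to_str <- function(b) trimws(rawToChar(b[b != as.raw(0)]))

#' Import a DICOM RT Dose file as a dose grid
#'
#' Reads an uncompressed little-endian DICOM RT Dose object, applies the
#' dose-grid scaling factor, builds the depth axis from the grid frame
#' offset vector (patient-space mm converted to the toolkit's z convention,
#' cm) and the in-plane axes from pixel spacing and image position (mm).
#'
#' @param source Path to a DICOM RT Dose file.
#' @return A [dose_grid()] with unit label \code{"Gy"}; single-frame files
#'   yield a z axis of length 1.
#' @export
read_rtdose <- function(source) {
  if (!file.exists(source)) abort_format(sprintf("no such file: %s", source))
  raw <- readBin(source, "raw", n = file.info(source)$size)
  off <- 0L
  if (length(raw) >= 132L && rawToChar(raw[129:132]) == "DICM") off <- 132L
  n <- length(raw)
  explicit <- TRUE        # meta group is always explicit; reassessed after it
  ts <- NULL
  el <- list()
  long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")
  while (off + 8L <= n) {
    group <- read_u16(raw, off)
    element <- read_u16(raw, off + 2L)
    if (group != 0x0002 && !is.null(ts)) {
      explicit <- !identical(ts, "1.2.840.10008.1.2")
      if (!ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
        abort_format(sprintf("unsupported transfer syntax %s", ts))
      ts <- NULL
    }
    if (explicit || group == 0x0002) {
      vr <- rawToChar(raw[off + 5:6])
      if (vr %in% long_vrs) {
        len <- read_u32(raw, off + 8L)
        hdr <- 12L
      } else {
        len <- read_u16(raw, off + 6L)
        hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- read_u32(raw, off + 4L)
      hdr <- 8L
    }
    if (len == 4294967295)
      abort_format("undefined-length element: unsupported dialect")
    start <- off + hdr
    if (start + len > n)
      abort_format("truncated DICOM element")
    key <- TAG(group, element)
    keep <- c("0002,0010", "0028,0008", "0028,0010", "0028,0011",
              "0028,0030", "0028,0100", "0028,0103", "0020,0032",
              "3004,000C", "3004,000E", "7FE0,0010")
    if (key %in% keep)
      el[[key]] <- list(vr = vr, bytes = raw[seq.int(start + 1L, length.out = len)])
    if (key == "0002,0010")
      ts <- bytes_to_str(el[[key]]$bytes)
    off <- start + len
  }

  as_str <- function(e) bytes_to_str(e$bytes)
  as_us <- function(e) read_u16(e$bytes, 0L)
  as_ds <- function(e) as.numeric(strsplit(as_str(e), "\\\\")[[1]])

  need <- function(key, what) {
    if (is.null(el[[key]]))
      abort_format(sprintf("missing %s (%s)", what, key))
    el[[key]]
  }
  rows <- as_us(need("0028,0010", "Rows"))
  cols <- as_us(need("0028,0011", "Columns"))
  frames <- if (!is.null(el[["0028,0008"]]))
    as.integer(as_str(el[["0028,0008"]])) else 1L
  scaling <- as_ds(need("3004,000E", "dose grid scaling"))[1]
  spacing <- as_ds(need("0028,0030", "pixel spacing"))   # row (y), col (x) mm
  ipp <- as_ds(need("0020,0032", "image position (patient)"))
  bits <- if (!is.null(el[["0028,0100"]])) as_us(el[["0028,0100"]]) else 16L
  signed <- if (!is.null(el[["0028,0103"]])) as_us(el[["0028,0103"]]) == 1L else FALSE
  pix <- need("7FE0,0010", "pixel data")$bytes

  if (frames > 1L) {
    offs <- as_ds(need("3004,000C", "grid frame offset vector"))
    if (length(offs) != frames)
      abort_format("grid frame offset vector length does not match frames")
    d <- diff(offs)
    if (any(d <= 0) || (max(d) - min(d)) > 1e-6 * max(abs(d)))
      abort_format("non-uniform or non-increasing frame offsets: unsupported dialect")
  } else {
    offs <- if (!is.null(el[["3004,000C"]])) as_ds(el[["3004,000C"]])[1] else 0
  }

  npix <- rows * cols * frames
  if (bits == 16L) {
    stored <- readBin(pix, "integer", n = npix, size = 2L,
                      signed = FALSE, endian = "little")
  } else if (bits == 32L) {
    stored <- readBin(pix, "integer", n = npix, size = 4L, endian = "little")
    stored <- ifelse(stored < 0, stored + 4294967296, as.numeric(stored))
  } else abort_format(sprintf("unsupported bits allocated: %d", bits))
  if (signed) abort_format("signed pixel data: unsupported dialect")
  if (length(stored) < npix) abort_format("pixel data shorter than declared grid")

  x <- ipp[1] + (seq_len(cols) - 1L) * spacing[2]
  y <- ipp[2] + (seq_len(rows) - 1L) * spacing[1]
  z <- (ipp[3] + offs) / 10   # patient-space mm -> toolkit depth cm
  vals <- array(stored * scaling, dim = c(cols, rows, frames))
  dose_grid(vals, x = x, y = y, z = z, unit_label = "Gy",
            provenance = list(source = source, format = "DICOM RT Dose",
                              dose_grid_scaling = scaling))
}
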