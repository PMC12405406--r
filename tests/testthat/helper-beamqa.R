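# Shared fixtures, all generated in code.

# Smooth random 1-D dose pair on a fine grid (positions mm).
random_scan_pair <- function(seed, n = 60, spacing = 0.5) {
  set.seed(seed)
  x <- seq(0, by = spacing, length.out = n)
  base <- 70 + 25 * sin(x / runif(1, 6, 12) + runif(1, 0, 3)) +
    8 * cos(x / runif(1, 3, 5))
  base <- pmax(base, 1)
  pert <- base * (1 + 0.02 * sin(x / runif(1, 4, 9) + runif(1, 0, 3))) +
    rnorm(1, 0, 0.5)
  list(reference = lateral_profile(x, base, depth = 10),
       evaluated = lateral_profile(x, pmax(pert, 0), depth = 10))
}

# Smooth random 2-D dose pair (small, for oracle cross-checks).
random_grid_pair <- function(seed, n = 12, spacing = 2) {
  set.seed(seed)
  x <- seq(0, by = spacing, length.out = n)
  f <- function(x, y) 60 + 30 * sin(x / runif(1, 7, 11) + runif(1, 0, 3)) *
    cos(y / runif(1, 8, 13) + runif(1, 0, 3)) + 5 * sin(x * y / 120)
  a <- pmax(outer(x, x, f), 1)
  b <- a * (1 + 0.02 * sin(outer(x, x, "+") / runif(1, 5, 9) + runif(1, 0, 3)))
  list(reference = dose_grid(a, x = x, y = x),
       evaluated = dose_grid(pmax(b, 0), x = x, y = x))
}

# Depth-dose curve reconstructed from tabulated PDD points (depths cm, PDD %).
tabulated_pdd_curve <- function(pdd5, pdd10, pdd20, d_max = 1.4) {
  depth_dose_curve(c(d_max, 5, 10, 20), c(100, pdd5, pdd10, pdd20),
                   normalized = TRUE)
}

# ---- synthetic DICOM RT Dose writer (explicit/implicit VR little endian) ---

u16r <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32r <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_el <- function(group, element, vr, payload, explicit = TRUE) {
  if (length(payload) %% 2 == 1)
    payload <- c(payload, if (vr %in% c("OB", "OW")) as.raw(0) else charToRaw(" "))
  if (!explicit)
    return(c(u16r(group), u16r(element), u32r(length(payload)), payload))
  head <- c(u16r(group), u16r(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
    c(head, raw(2), u32r(length(payload)), payload)
  else
    c(head, u16r(length(payload)), payload)
}

dcm_str <- function(x) charToRaw(paste(x, collapse = "\\"))

# Writes a minimal RT Dose file; `drop` removes named elements to provoke
# format errors. Returns the path.
write_synthetic_rtdose <- function(path, stored, rows, cols, frames = 1L,
                                   scaling = 0.01, spacing = c(2, 2),
                                   ipp = c(-10, -10, 0),
                                   offsets = (seq_len(frames) - 1L) * 2,
                                   implicit = FALSE, drop = character()) {
  ts <- if (implicit) "1.2.840.10008.1.2" else "1.2.840.10008.1.2.1"
  ex <- !implicit
  els <- list(
    ipp      = dcm_el(0x0020, 0x0032, "DS", dcm_str(ipp), ex),
    frames   = dcm_el(0x0028, 0x0008, "IS", charToRaw(as.character(frames)), ex),
    rows     = dcm_el(0x0028, 0x0010, "US", u16r(rows), ex),
    cols     = dcm_el(0x0028, 0x0011, "US", u16r(cols), ex),
    spacing  = dcm_el(0x0028, 0x0030, "DS", dcm_str(spacing), ex),
    bits     = dcm_el(0x0028, 0x0100, "US", u16r(16), ex),
    pixrep   = dcm_el(0x0028, 0x0103, "US", u16r(0), ex),
    offsets  = dcm_el(0x3004, 0x000C, "DS", dcm_str(offsets), ex),
    scaling  = dcm_el(0x3004, 0x000E, "DS", dcm_str(format(scaling, digits = 10)), ex),
    pixels   = dcm_el(0x7FE0, 0x0010, "OW",
                      writeBin(as.integer(stored), raw(), size = 2,
                               endian = "little"), ex))
  els <- els[setdiff(names(els), drop)]
  bytes <- c(raw(128), charToRaw("DICM"),
             dcm_el(0x0002, 0x0010, "UI", charToRaw(ts), TRUE),
             do.call(c, unname(els)))
  writeBin(bytes, path)
  path
}
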