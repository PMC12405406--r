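#!/usr/bin/env Rscript
# Profile analysis at 10 cm depth: flatness, symmetry and 80%-20% penumbra
# per energy and field size, the standard commissioning triple.

library(beamqa)

data_dir <- file.path("results", "data")
out <- file.path("results", "tables")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

files <- list.files(data_dir, pattern = "^profile_", full.names = TRUE)
stopifnot(length(files) > 0)

rows <- lapply(files, function(f) {
  pr <- read_scan_table(f)
  s <- profile_summary(pr)
  data.frame(energy_label = sub("^profile_([^_]+)_.*$", "\\1", basename(f)),
             field_size = as.numeric(sub("^profile_[^_]+_(\\d+)\\.csv$", "\\1",
                                         basename(f))),
             flatness = round(s$flatness_percent, 2),
             symmetry = round(s$symmetry_percent, 2),
             penumbra_left = round(s$penumbra_left_mm, 2),
             penumbra_right = round(s$penumbra_right_mm, 2),
             penumbra_avg = round(s$penumbra_avg_mm, 2),
             field_width = round(s$field_width_mm, 1))
})
tab <- do.call(rbind, rows)
tab <- tab[order(tab$energy_label, tab$field_size), ]
write.csv(tab, file.path(out, "profile_table.csv"), row.names = FALSE,
          quote = FALSE)

print(tab, row.names = FALSE)
cat(sprintf("\npenumbra %.2f-%.2f mm: set by the model edge width (wider for 12 MV),\n",
            min(tab$penumbra_avg), max(tab$penumbra_avg)))
cat("nearly constant across field sizes -- the fixed-sigma edge model omits\n")
cat("the scatter-driven growth measured profiles show on large fields.\n")
cat("flatness sits a few percent above 100 (in-field horns); symmetry is\n")
cat("100 up to the simulated noise, as expected for a mirror-symmetric beam.\n")
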