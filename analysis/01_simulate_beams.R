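#!/usr/bin/env Rscript
# Generate the synthetic beam dataset used by the downstream analyses:
# central-axis depth-dose scans and lateral profiles for 6 and 12 MV beams
# over the clinical range of square field sizes, plus one 3-D dose grid.
# Everything is seeded, so the whole workflow is reproducible bit for bit.

library(beamqa)

out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

field_sizes <- c(5, 10, 20, 30, 40)   # cm, the usual commissioning set
energies <- c("6MV", "12MV")
depths <- seq(0, 30, 0.1)             # cm
seed0 <- 20260930L

for (en in energies) {
  for (fs in field_sizes) {
    p <- beam_model_params(en, field_size = fs,
                           noise_sd = 0.005, seed = seed0 + fs)
    crv <- make_pdd_curve(p, depths)
    write_scan_table(crv, file.path(out, sprintf("pdd_%s_%02d.csv", en, fs)))
    half <- field_width_at_depth(p, 10) / 2 + 8 * p$penumbra_sigma
    prof <- make_profile(p, 10, seq(-ceiling(half), ceiling(half), 0.5))
    write_scan_table(prof, file.path(out, sprintf("profile_%s_%02d.csv", en, fs)))
  }
}

# one noiseless 3-D reference grid (6 MV, 10x10) for the gamma exercises
g <- make_dose_grid(beam_model_params("6MV"),
                    grid_spec(x = seq(-80, 80, 2), y = seq(-80, 80, 2),
                              z = seq(0, 25, 0.5)))
write_dose_grid(g, file.path(out, "grid_6MV_10.csv"))

cat(sprintf("wrote %d scan files and 1 dose grid to %s\n",
            2 * length(energies) * length(field_sizes), out))
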