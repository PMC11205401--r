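#!/usr/bin/env Rscript
# Lamellar repeat distances from 1-D scattering curves.
#
# Generates three-order lamellar curves at the reference saturated-PC
# d-spacings (59.6 A in the low-temperature gel phase, 64.6 A in the
# ripple phase, 60.0 A in the fluid phase) plus the silver-stearate
# calibration reference (48.8 A), detects the reflections and indexes
# them as 1:2:3 to recover each repeat distance.

suppressPackageStartupMessages(library(bilayerlab))
seed <- as.integer(commandArgs(TRUE)[1])
if (is.na(seed)) seed <- 1L
dir.create("results", showWarnings = FALSE)

# detector calibration: the reference first-order peak anchors channel
# -> s; its d must round-trip
s_axis <- calibrate_axis(0:500, ref_peak_channel = 250, d_ref = 48.8)
cat(sprintf("calibration: channel 250 -> s = %.5f 1/A (d = %.1f A)\n",
            s_axis[251], 1 / s_axis[251]))

cases <- data.frame(condition = c("gel_7C", "ripple_18C", "fluid_34C",
                                  "silver_stearate"),
                    d_true = c(59.6, 64.6, 60.0, 48.8),
                    n_orders = c(3, 3, 3, 1))
rows <- lapply(seq_len(nrow(cases)), function(i) {
  cv <- gen_scattering_curve(cases$d_true[i],
                             n_orders = cases$n_orders[i],
                             noise_sd = 20, seed = seed + i)
  idx <- index_lamellar(find_reflections(cv))
  print(idx)
  data.frame(condition = cases$condition[i], d_true = cases$d_true[i],
             d_recovered = idx$d_spacing,
             ratio_residual = idx$ratio_residual,
             lamellar = idx$lamellar)
})
tab <- do.call(rbind, rows)
utils::write.csv(tab, "results/saxs_dspacings.csv", row.names = FALSE)
stopifnot(all(abs(tab$d_recovered - tab$d_true) < 0.5))
cat("wrote results/saxs_dspacings.csv\n")
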