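#!/usr/bin/env Rscript
# Dye-leakage kinetics and the influence of head-group composition.
#
# Simulates carboxyfluorescein release traces under the mono-exponential
# synthetic model at three compositions: a PC baseline, a PG-like
# membrane (rate doubled) and a PE-like membrane (rate halved), then
# summarizes extent, initial rate and plateau. The expected ordering —
# anionic PG enhances leakage, PE protects — must show in every column.

suppressPackageStartupMessages(library(bilayerlab))
seed <- as.integer(commandArgs(TRUE)[1])
if (is.na(seed)) seed <- 1L
dir.create("results", showWarnings = FALSE)

t_grid <- seq(0, 600, by = 2)
mods <- c(PC_PE = 0.5, PC = 1.0, PC_PG = 2.0)
rows <- lapply(names(mods), function(nm) {
  par <- leakage_sim_params(plateau_percent = 80, rate_constant = 0.01,
                            composition_modifier = mods[[nm]],
                            noise_sd = 2, seed = seed)
  tr <- gen_leakage_trace(par, t_grid, label = nm)
  s <- summarize_trace(tr, t_report = 300)
  print(s)
  data.frame(label = nm, modifier = mods[[nm]],
             extent_300s = s$extent_percent,
             initial_rate = s$initial_rate,
             plateau = s$plateau_percent)
})
tab <- do.call(rbind, rows)
utils::write.csv(tab, "results/leakage_summary.csv", row.names = FALSE)

ord <- order(tab$modifier)
stopifnot(all(diff(tab$extent_300s[ord]) > 0),
          all(diff(tab$initial_rate[ord]) > 0))
cat("composition ordering PG > PC > PE confirmed in extent and rate\n")
cat("wrote results/leakage_summary.csv\n")
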