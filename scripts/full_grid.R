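#!/usr/bin/env Rscript
# Full-scale reproduction of the grid analyses. NOT part of the test
# suite: the 4^9 sweep takes hours on one CPU. Usage:
#
#   Rscript scripts/full_grid.R --steps 3 --out results/grid3   # ~20 min
#   Rscript scripts/full_grid.R --steps 4 --out results/grid4   # hours
#
# Writes sweep.csv + impacts.csv + a summary of the distribution figures
# (RMSD min/median/max, fraction RMSD < 0.5, fraction Q10(spiking cost)
# < 1, fraction of square-root fits with R^2 > 0.97).

suppressMessages(library(thermospike))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(steps = 3, out = "results/grid")
i <- 1
while (i <= length(args)) {
  if (args[i] == "--steps") { opt$steps <- as.integer(args[i + 1]); i <- i + 2 }
  else if (args[i] == "--out") { opt$out <- args[i + 1]; i <- i + 2 }
  else stop("unknown argument: ", args[i])
}

grid <- q10_grid(opt$steps)
message("sweeping ", grid$n, " models ...")
sw <- run_sweep(grid, progress = TRUE)
write_sweep(sw, opt$out)

imp <- impact_scores(sw, "rmsd")
write_impacts_csv(imp, file.path(opt$out, "impacts_rmsd.csv"))

summary <- list(
  n_models = nrow(sw),
  rmsd_min = min(sw$rmsd, na.rm = TRUE),
  rmsd_median = median(sw$rmsd, na.rm = TRUE),
  rmsd_max = max(sw$rmsd, na.rm = TRUE),
  frac_rmsd_below_0.5 = mean(sw$rmsd < 0.5, na.rm = TRUE),
  frac_spike_cost_q10_below_1 = mean(sw$q10_spike_cost < 1, na.rm = TRUE),
  frac_r2_above_0.97 = mean(sw$r2_cold > 0.97 & sw$r2_hot > 0.97,
                            na.rm = TRUE),
  frac_rest_na_q10_below_1 = mean(sw$q10_rest_na < 1, na.rm = TRUE),
  top_impacts = imp$parameter[order(-abs(imp$impact))][1:3])
jsonlite::write_json(summary, file.path(opt$out, "summary.json"),
                     auto_unbox = TRUE, digits = NA)
print(summary)
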