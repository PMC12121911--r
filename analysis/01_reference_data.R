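#!/usr/bin/env Rscript
# Builds the calibration inputs: CBS-core reference trajectories at 10
# and 1.5 ng/ml TGFbeta, the printed dlc1/snail1 ratio constraints and
# the stable-knockdown fold-change block, assembled into the training
# dataset and exported both as tidy CSV and as a PEtab-style problem.
#
# Outputs (results/): cbs_reference_10.csv, cbs_reference_1.5.csv,
#   calibration_dataset.csv, petab/, manifest_01.json

library(cbsd)
dir.create("results", showWarnings = FALSE)

core <- cbs_core_params(cbsd_params(ks1 = 0.05))
t_grid <- seq(0, 1000, by = 25)

for (dose in c(10, 1.5)) {
  ref <- cbs_simulate(core, dose, t_grid)
  df <- data.frame(time = rep(t_grid, length(cbs_species())),
                   species = rep(cbs_species(), each = length(t_grid)),
                   value = as.vector(ref[, cbs_species()]),
                   condition_id = sprintf("cbs_control_%g", dose))
  out <- sprintf("results/cbs_reference_%g.csv", dose)
  write.csv(df, out, row.names = FALSE, quote = FALSE)
  message("wrote ", out)
}

ds <- build_dataset(core)
write.csv(ds, "results/calibration_dataset.csv", row.names = FALSE,
          quote = FALSE)
message(sprintf(
  "dataset: %d records over %d conditions (%d knockdown fold-change points)",
  nrow(ds), nrow(attr(ds, "conditions")),
  sum(ds$condition == "knockdown_10")))

write_petab(ds, cbsd_params(), "results/petab")
write_manifest("results/manifest_01.json",
               config = list(t_grid = range(t_grid),
                             ratios = c(0.77, 0.99),
                             fold_changes = c(dlc1 = 0.44, snail1 = 0.12)))
message("PEtab problem exported to results/petab/")
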