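#!/usr/bin/env Rscript
# Simulate a synthetic community survey and write it in the package's CSV
# layout (plus truth tables), or run the DAR -> SAR slope experiment.
#
# Usage:
#   Rscript scripts/simulate_community.R --mode abundance --n-species 30 \
#     --n-patches 15 --f-neg 0 --seed 1 --out-dir sim/
#   Rscript scripts/simulate_community.R --mode abundance --experiment \
#     --f-neg-grid 0,0.4,0.8 --replicates 50 --seed 1 --out-dir exp/

suppressPackageStartupMessages({
  library(optparse)
  library(commsar)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--mode", type = "character", default = "abundance"),
  make_option("--n-species", type = "integer", default = NULL),
  make_option("--n-patches", type = "integer", default = NULL),
  make_option("--f-neg", type = "double", default = 0),
  make_option("--experiment", action = "store_true", default = FALSE),
  make_option("--f-neg-grid", type = "character", default = "0,0.4,0.8"),
  make_option("--replicates", type = "integer", default = 50L),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out-dir", type = "character", default = "sim"))))

design <- simulation_design(opts$mode, n_species = opts[["n-species"]],
                            n_patches = opts[["n-patches"]],
                            f_neg = opts[["f-neg"]])
dir.create(opts[["out-dir"]], recursive = TRUE, showWarnings = FALSE)

if (opts$experiment) {
  grid <- as.numeric(strsplit(opts[["f-neg-grid"]], ",")[[1]])
  ex <- run_dar_experiment(design, grid, replicates = opts$replicates,
                           seed = opts$seed)
  write.csv(ex, file.path(opts[["out-dir"]], "dar_experiment.csv"),
            row.names = FALSE)
  write.csv(attr(ex, "summary"),
            file.path(opts[["out-dir"]], "dar_experiment_summary.csv"),
            row.names = FALSE)
  message("experiment report written to ", opts[["out-dir"]])
} else {
  sim <- simulate_community(design, seed = opts$seed)
  write_dataset(sim$data, opts[["out-dir"]],
                metadata = list(seed = opts$seed, f_neg = design$f_neg))
  truth <- data.frame(species_id = sim$truth$species_id,
                      beta0 = sim$truth$beta0, beta1 = sim$truth$beta1,
                      detected = sim$truth$detected,
                      negative_dar = sim$truth$negative_dar)
  if (!is.null(sim$truth$p)) truth$p <- sim$truth$p
  if (!is.null(sim$truth$group)) truth$group <- sim$truth$group
  write.csv(truth, file.path(opts[["out-dir"]], "truth_species.csv"),
            row.names = FALSE)
  write.csv(sim$truth$z, file.path(opts[["out-dir"]], "truth_z.csv"),
            row.names = FALSE)
  message("simulated dataset written to ", opts[["out-dir"]])
}
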