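#!/usr/bin/env Rscript
# Simulate the synthetic EJC experiment: toy genome, annotation, deposition
# ground truth, and seeded eCLIP / SMInput / ipaRt / mRNA-seq libraries.
source("analysis/00_config.R")

sim <- simulate_ejc_experiment(study_config)
paths <- write_simulation(sim, sim_dir)

tr <- sim$truth
cat(sprintf("genes: %d, exons: %d\n", study_config$n_genes, nrow(tr)))
cat(sprintf("loaded exons (truth): %d of %d first/internal\n",
            sum(tr$loaded), sum(tr$cls %in% c("first", "internal"))))
cat("written:\n")
cat(paste(" ", paths, collapse = "\n"), "\n")
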