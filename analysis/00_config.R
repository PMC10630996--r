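# Shared configuration for the numbered analysis drivers.
# Run the scripts in order from the repository root:
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_profiles.R
#   ...
suppressPackageStartupMessages({
  library(ejcmap)
  library(data.table)
})

results_dir <- "results"
sim_dir <- file.path(results_dir, "sim")
dir.create(results_dir, showWarnings = FALSE)

# the study condition: a 500-gene synthetic genome at default geometry
study_config <- sim_config(seed = 2026L)

# reload the on-disk simulated experiment written by 01_simulate.R
load_experiment <- function() {
  if (!dir.exists(sim_dir))
    stop("run analysis/01_simulate.R first (missing ", sim_dir, ")")
  models <- parse_gtf(file.path(sim_dir, "annotation.gtf"))
  genome <- read_genome_fasta(file.path(sim_dir, "genome.fa"))
  reads <- lapply(c(eclip = "eclip", sminput = "sminput",
                    ipart = "ipart", rna = "rna"), function(grp) {
    paths <- sort(Sys.glob(file.path(sim_dir, paste0(grp, "_rep*.bed"))))
    lapply(paths, read_bed6)
  })
  list(models = models,
       genome = genome,
       exons = exon_table(models),
       truth = fread(file.path(sim_dir, "truth.tsv")),
       reads = reads)
}
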