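#!/usr/bin/env Rscript
# ipaRt scoring: windowed median coverage per library, IP / mRNA-seq
# enrichment ratios, threshold calibration on last exons, loading calls.
source("analysis/00_config.R")

exp <- load_experiment()

res <- ipart_score(exp$reads$ipart, exp$reads$rna, exp$exons)
fwrite(res$scores, file.path(results_dir, "ipart_scores.tsv"), sep = "\t")
jsonlite::write_json(
  list(threshold = res$calibration$threshold,
       percentile = res$calibration$percentile,
       n_calibration_exons = res$calibration$n),
  file.path(results_dir, "ipart_calibration.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)

sc <- res$scores
cat(sprintf("calibrated threshold: %.3f (95th percentile of %d last exons)\n",
            res$calibration$threshold, res$calibration$n))
cat(sprintf("consistently detected exons: %d of %d\n",
            sum(sc$consistently_detected), nrow(sc)))
cat(sprintf("loaded first/internal exons: %d of %d consistently detected\n",
            sc[cls %in% c("first", "internal") & loaded == TRUE, .N],
            sc[cls %in% c("first", "internal") &
                 consistently_detected == TRUE, .N]))
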