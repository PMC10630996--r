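#!/usr/bin/env Rscript
# Stop Rate Difference detection: per-position replicate-integrated
# chi-square tests against the merged SMInput, exon scores over the
# canonical -32..-23 window, and the secondary -18 window check.
source("analysis/00_config.R")

exp <- load_experiment()

res <- srd_detect(exp$reads$eclip, exp$reads$sminput, exp$exons)
fwrite(res$positions, file.path(results_dir, "srd_positions.tsv"), sep = "\t")
fwrite(res$exons, file.path(results_dir, "srd_exons.tsv"), sep = "\t")

det <- res$exons[detected == TRUE]
cat(sprintf("exons with SRD detection: %d of %d first/internal (%.1f%%)\n",
            nrow(det), res$exons[cls %in% c("first", "internal"), .N],
            100 * nrow(det) / res$exons[cls %in% c("first", "internal"), .N]))
cat(sprintf("last-exon detections: %d of %d (%.2f%%)\n",
            res$exons[cls == "last" & detected == TRUE, .N],
            res$exons[cls == "last", .N],
            100 * res$exons[cls == "last", mean(detected)]))

# secondary, more junction-proximal window (all-replicate stringency)
sec <- srd_detect(exp$reads$eclip, exp$reads$sminput, exp$exons,
                  window = c(-22L, -13L), min_reps = 3L)
ov <- secondary_window_overlap(sec$exons[detected == TRUE, exon_id],
                               det$exon_id)
cat(sprintf("secondary -18 window detections: %d (overlap with canonical: %s)\n",
            sec$exons[detected == TRUE, .N],
            ifelse(is.na(ov), "NA", sprintf("%.2f", ov))))
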