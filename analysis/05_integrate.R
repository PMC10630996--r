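#!/usr/bin/env Rscript
# Integration: expression deciles, footprint uridine strata, combined
# eCLIP + ipaRt calls over the expressed-in-both universe, peak-set Jaccard
# agreement, and evaluation against the simulation's ground truth.
source("analysis/00_config.R")

exp <- load_experiment()
exons <- exp$exons
truth <- exp$truth

ecl <- fread(file.path(results_dir, "srd_exons.tsv"))[
  , .(exon_id, cls, detected)]
ipa <- fread(file.path(results_dir, "ipart_scores.tsv"))[
  , .(exon_id, cls, detected = loaded)]

# expression deciles over the EJC-eligible universe
rna_pool <- rbindlist(exp$reads$rna)
counts <- exon_read_counts(rna_pool, exons)
expr <- data.table(exon_id = exons$exon_id,
                   rpkm = rpkm(counts$count, exons$length, nrow(rna_pool)))
universe <- exons[cls %in% c("first", "internal"), exon_id]
bins <- expression_bins(expr[exon_id %in% universe])
deciles <- data.table(exon_id = bins$exon_id, stratum = bins$decile)

# footprint uridine strata (0 / 1 / 2 / 3+)
uc <- footprint_u_counts(exons, exp$genome, study_config$footprint)
u_strata <- data.table(exon_id = uc$exon_id, stratum = pmin(uc$u_count, 3L))

rates <- list(
  eclip_by_decile = detection_rate_by_stratum(ecl, deciles),
  eclip_by_u = detection_rate_by_stratum(ecl, u_strata,
                                         exclude_cls = c("last", "single")),
  ipart_by_decile = detection_rate_by_stratum(ipa, deciles),
  ipart_by_u = detection_rate_by_stratum(ipa, u_strata,
                                         exclude_cls = c("last", "single")))
for (nm in names(rates))
  fwrite(rates[[nm]], file.path(results_dir, paste0("rates_", nm, ".tsv")),
         sep = "\t")

# combined calls over genes expressed and detected in both assays
expressed <- expressed_genes(exons, rna_pool, rbindlist(exp$reads$sminput))
expressed_exons <- exons[gene_id %in% expressed &
                           cls %in% c("first", "internal"), exon_id]
comb <- combine_calls(ecl, ipa, expressed_exons)
fwrite(comb, file.path(results_dir, "combined_calls.tsv"), sep = "\t")

# Jaccard agreement of the two methods' detection windows (slop 5 nt)
window_peaks <- function(ids, window) {
  ex <- exons[exon_id %in% ids]
  g1 <- genomic_position_vec(window[1], ex$start, ex$end, ex$strand)
  g2 <- genomic_position_vec(window[2], ex$start, ex$end, ex$strand)
  data.table(chrom = ex$chrom, start = pmin(g1, g2),
             end = pmax(g1, g2) + 1L, strand = ex$strand)
}
jac <- jaccard_peaks(window_peaks(ecl[detected == TRUE, exon_id],
                                  c(-32L, -23L)),
                     window_peaks(ipa[detected == TRUE, exon_id],
                                  c(-36L, -10L)))

# truth-based evaluation (available because the data are simulated)
eval_calls <- function(calls) {
  m <- setNames(calls$detected, calls$exon_id)
  pos <- truth[loaded == TRUE, exon_id]
  neg <- truth[loaded == FALSE & cls == "internal", exon_id]
  last <- truth[cls == "last", exon_id]
  list(sensitivity = mean(m[pos] %in% TRUE),
       # NA when the config deposits on every eligible exon (no negatives)
       fpr_unloaded_internal = if (length(neg)) mean(m[neg] %in% TRUE)
                               else NA_real_,
       fpr_last = mean(m[last] %in% TRUE))
}

summary <- list(
  n_exons = nrow(exons),
  combined_counts = as.list(table(comb$combined)),
  union_detected = sum(comb$union_detected),
  jaccard = jac,
  truth_eval = list(eclip = eval_calls(ecl), ipart = eval_calls(ipa)))
jsonlite::write_json(summary, file.path(results_dir, "summary.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat("combined calls (expressed-in-both universe):\n")
print(table(comb$combined))
cat(sprintf("union detected: %d\n", summary$union_detected))
cat(sprintf("Jaccard(eCLIP windows, ipaRt windows) = %.3f (%d / %d)\n",
            jac$jaccard, jac$intersection, jac$union))
fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.3f", x))
cat(sprintf("eCLIP: sensitivity %s, FPR internal %s, FPR last %s\n",
            fmt(summary$truth_eval$eclip$sensitivity),
            fmt(summary$truth_eval$eclip$fpr_unloaded_internal),
            fmt(summary$truth_eval$eclip$fpr_last)))
cat(sprintf("ipaRt: sensitivity %s, FPR internal %s, FPR last %s\n",
            fmt(summary$truth_eval$ipart$sensitivity),
            fmt(summary$truth_eval$ipart$fpr_unloaded_internal),
            fmt(summary$truth_eval$ipart$fpr_last)))
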