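#' Median coverage of a junction-relative window
#'
#' Median of the per-position read depths over the window positions that have
#' nonzero depth (positions with zero coverage are filtered out first, so a
#' sparse window is summarized by its covered positions only). Returns `NA`
#' when every window position has depth zero: the exon is not detected in this
#' library, which is distinct from being unloaded.
#'
#' @param depths Numeric vector of per-position depths over the window
#'   (including zeros).
#' @return Scalar median of the positive depths, or `NA`.
#' @export
window_median_coverage <- function(depths) {
  d <- depths[depths > 0]
  if (length(d) == 0) return(NA_real_)
  as.numeric(median(d))
}

# per-exon, per-window-position depth from read-exon overlap spans
window_depths <- function(reads, exons, window) {
  window <- check_window(window)
  spans <- assign_read_spans(reads, exons)
  wlo <- window[1]; whi <- window[2]
  spans <- spans[rel_hi >= wlo & rel_lo <= whi]
  spans[, rel_lo := pmax(rel_lo, wlo)]
  spans[, rel_hi := pmin(rel_hi, whi)]
  npos <- whi - wlo + 1L
  out <- spans[, {
    t5 <- tabulate(rel_lo - wlo + 1L, nbins = npos)
    t3 <- tabulate(rel_hi - wlo + 1L, nbins = npos)
    covv <- cumsum(t5) - c(0L, cumsum(t3)[-npos])
    .(position = wlo:whi, depth = covv)
  }, by = exon_id]
  out
}

#' Windowed median coverage of every exon in one library
#'
#' Computes per-position depth in the window (default `[-36, -10]`, the
#' ipaRt-protected region) for each exon from the read intervals and
#' summarizes it with [window_median_coverage()]. Exons shorter than the far
#' window bound are evaluated on the positions the exon actually has.
#'
#' @param reads Alignment table of one library.
#' @param exons Exon table.
#' @param window Inclusive relative interval (default `c(-36, -10)`).
#' @return `data.table` with `exon_id` and `median_cov` (`NA` when the window
#'   has no covered position).
#' @export
ipart_window_medians <- function(reads, exons, window = c(-36L, -10L)) {
  wd <- window_depths(reads, exons, window)
  med <- wd[, .(median_cov = window_median_coverage(depth)), by = exon_id]
  out <- merge(data.table(exon_id = exons$exon_id), med,
               by = "exon_id", all.x = TRUE, sort = FALSE)
  out
}

#' Enrichment ratio of IP over control window medians
#'
#' `mean(ip_medians) / mean(ctrl_medians)`. Any undefined (`NA`) median makes
#' the ratio undefined: the exon is excluded from scoring (undetected, not
#' unloaded).
#'
#' @param ip_medians,ctrl_medians Numeric vectors of per-library window
#'   medians.
#' @return Scalar ratio, or `NA`.
#' @export
enrichment_ratio <- function(ip_medians, ctrl_medians) {
  if (anyNA(ip_medians) || anyNA(ctrl_medians)) return(NA_real_)
  mean(ip_medians) / mean(ctrl_medians)
}

#' Calibrate the loading threshold on last exons
#'
#' Last exons lack a downstream splicing event and therefore carry no EJC;
#' their enrichment ratios form an empirical null. The threshold is the 95th
#' percentile (linear interpolation between order statistics,
#' `quantile(type = 7)`) of the consistently detected last-exon ratios.
#'
#' @param ratios Numeric vector of last-exon enrichment ratios (no `NA`), or a
#'   data.frame with `exon_id` and `ratio`.
#' @param percentile Percentile used (default 95).
#' @param min_n Minimum calibration exons required (default 20).
#' @return List of class `threshold_calibration`: `threshold`, `percentile`,
#'   `n`, `calibration_set` (exon ids when supplied).
#' @export
calibrate_threshold <- function(ratios, percentile = 95, min_n = 20L) {
  ids <- NULL
  if (is.data.frame(ratios)) {
    ids <- ratios$exon_id
    ratios <- ratios$ratio
  }
  keep <- !is.na(ratios)
  ratios <- ratios[keep]
  if (!is.null(ids)) ids <- ids[keep]
  if (length(ratios) < min_n)
    stop("only ", length(ratios), " consistently detected last exons; ",
         "at least ", min_n, " are needed to calibrate the threshold ",
         "(more sequencing depth or exons required)")
  structure(list(threshold = unname(quantile(ratios, percentile / 100,
                                             type = 7)),
                 percentile = percentile, n = length(ratios),
                 calibration_set = ids),
            class = "threshold_calibration")
}

#' Loaded/unloaded call for one exon score
#'
#' An exon is loaded iff it is consistently detected (defined window medians
#' in every IP replicate and every mRNA-seq control when
#' `require_all_replicates`) and its enrichment ratio strictly exceeds the
#' calibrated threshold.
#'
#' @param score One-row score record with `ratio` and `consistently_detected`.
#' @param calib A `threshold_calibration` (or scalar threshold).
#' @param require_all_replicates Require a defined median in every replicate
#'   (default `TRUE`; this is what `consistently_detected` encodes).
#' @return Logical.
#' @export
call_loaded <- function(score, calib, require_all_replicates = TRUE) {
  thr <- if (inherits(calib, "threshold_calibration")) calib$threshold else calib
  detected <- if (require_all_replicates) isTRUE(score$consistently_detected)
    else !is.na(score$ratio)
  detected && !is.na(score$ratio) && score$ratio > thr
}

#' ipaRt exon scoring over a full experiment
#'
#' Windowed median coverage per library, enrichment ratio of mean IP median
#' over mean mRNA-seq median, threshold calibration on last exons, and
#' loaded/unloaded calls.
#'
#' @param ipart_reps List of ipaRt replicate read tables.
#' @param rna_controls List of mRNA-seq control read tables.
#' @param exons Exon table.
#' @param window Scoring window (default `c(-36, -10)`).
#' @param calib_percentile Percentile of the last-exon null (default 95).
#' @return List with `scores` (per-exon table: per-library medians, `ip_mean`,
#'   `ctrl_mean`, `ratio`, `consistently_detected`, `loaded`, `cls`) and
#'   `calibration` (a `threshold_calibration`).
#' @export
ipart_score <- function(ipart_reps, rna_controls, exons,
                        window = c(-36L, -10L), calib_percentile = 95) {
  window <- check_window(window)
  ipm <- lapply(ipart_reps, ipart_window_medians, exons = exons, window = window)
  rnm <- lapply(rna_controls, ipart_window_medians, exons = exons, window = window)
  sc <- data.table(exon_id = exons$exon_id, cls = exons$cls)
  for (i in seq_along(ipm)) sc[, (sprintf("med_ip_%d", i)) := ipm[[i]]$median_cov]
  for (i in seq_along(rnm)) sc[, (sprintf("med_rna_%d", i)) := rnm[[i]]$median_cov]
  ipcols <- sprintf("med_ip_%d", seq_along(ipm))
  rncols <- sprintf("med_rna_%d", seq_along(rnm))
  ipmat <- as.matrix(sc[, ..ipcols])
  rnmat <- as.matrix(sc[, ..rncols])
  sc[, consistently_detected := rowSums(is.na(ipmat)) == 0 &
       rowSums(is.na(rnmat)) == 0]
  sc[, ip_mean := rowMeans(ipmat)]
  sc[, ctrl_mean := rowMeans(rnmat)]
  sc[, ratio := ifelse(consistently_detected, ip_mean / ctrl_mean, NA_real_)]
  calib <- calibrate_threshold(sc[cls == "last" & consistently_detected,
                                  .(exon_id, ratio)],
                               percentile = calib_percentile)
  sc[, loaded := consistently_detected & !is.na(ratio) &
       ratio > calib$threshold]
  list(scores = sc[], calibration = calib,
       params = list(window = window, calib_percentile = calib_percentile))
}
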