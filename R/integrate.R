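#' Reads per kilobase per million mapped reads
#'
#' @param read_count Reads assigned to the exon.
#' @param exon_length Exon length, nt.
#' @param library_size Total mapped reads of the library.
#' @return RPKM (vectorized).
#' @export
rpkm <- function(read_count, exon_length, library_size) {
  stopifnot(all(exon_length > 0), all(library_size > 0))
  read_count / (exon_length / 1000) / (library_size / 1e6)
}

#' Equal-count expression bins
#'
#' Ranks exons by RPKM (ties broken by `exon_id` order, a stable declared
#' convention) and assigns them to `k` quantile bins of equal membership
#' (sizes within one of each other). Bin 1 is the lowest-expressed.
#'
#' @param table data.frame with `exon_id` and `rpkm` (or a named numeric
#'   vector of RPKM).
#' @param k Number of bins (default 10).
#' @return `data.table` with `exon_id`, `rpkm`, `decile` (integer 1..k).
#' @export
expression_bins <- function(table, k = 10L) {
  if (!is.data.frame(table))
    table <- data.table(exon_id = names(table), rpkm = as.numeric(table))
  dt <- data.table(exon_id = table$exon_id, rpkm = table$rpkm)
  n <- nrow(dt)
  if (k > n) stop("k = ", k, " bins but only ", n, " exons")
  ord <- order(dt$rpkm, dt$exon_id, method = "radix")
  bin <- integer(n)
  bin[ord] <- as.integer(floor((seq_len(n) - 1) * k / n) + 1)
  dt[, decile := bin]
  dt[]
}

#' Detection rate per stratum
#'
#' Fraction of detected exons within each stratum (expression decile, U count,
#' exon class, ...). Last and single exons can be excluded, matching the
#' convention of reporting loading among exons that can carry an EJC.
#'
#' @param calls data.frame with `exon_id` and a logical `detected` column (its
#'   name configurable via `flag`).
#' @param strata Named vector or data.frame (`exon_id`, `stratum`) mapping
#'   exons to stratum labels.
#' @param exclude_cls Classes dropped before tallying (requires a `cls`
#'   column in `calls`); default none.
#' @param flag Name of the logical column in `calls` (default `"detected"`).
#' @return `data.table` with `stratum`, `n`, `n_detected`, `rate` (NaN when
#'   `n = 0`).
#' @export
detection_rate_by_stratum <- function(calls, strata,
                                      exclude_cls = character(0),
                                      flag = "detected") {
  stopifnot(nrow(calls) > 0)
  dt <- data.table(exon_id = calls$exon_id,
                   detected = as.logical(calls[[flag]]))
  if (length(exclude_cls)) {
    stopifnot("cls" %in% names(calls))
    dt <- dt[!calls$cls %in% exclude_cls]
  }
  if (is.data.frame(strata)) {
    smap <- setNames(strata$stratum, strata$exon_id)
  } else smap <- strata
  dt[, stratum := smap[exon_id]]
  dt <- dt[!is.na(stratum)]
  out <- dt[, .(n = .N, n_detected = sum(detected)), by = stratum]
  out[, rate := n_detected / n]
  setorder(out, stratum)
  out[]
}

#' Combine eCLIP and ipaRt calls per exon
#'
#' Classifies each exon of the expressed-in-both universe as detected by
#' `both` methods, exactly `one`, or `neither`; exons outside the universe are
#' `excluded`.
#'
#' @param eclip,ipart Named logical vectors (exon_id -> detected) or
#'   data.frames with `exon_id` and `detected`/`loaded`.
#' @param expressed_both Character vector of exon ids whose genes are
#'   expressed and detected in both datasets.
#' @return `data.table` with `exon_id`, `eclip_detected`, `ipart_loaded`,
#'   `combined` (factor both/one/neither/excluded), and `union_detected`.
#' @export
combine_calls <- function(eclip, ipart, expressed_both) {
  as_map <- function(x, flags = c("detected", "loaded")) {
    if (is.data.frame(x)) {
      fl <- intersect(flags, names(x))[1]
      setNames(as.logical(x[[fl]]), x$exon_id)
    } else x
  }
  e <- as_map(eclip); p <- as_map(ipart)
  ids <- union(names(e), names(p))
  dt <- data.table(exon_id = ids,
                   eclip_detected = unname(e[ids]) %in% TRUE,
                   ipart_loaded = unname(p[ids]) %in% TRUE)
  dt[, combined := ifelse(!exon_id %in% expressed_both, "excluded",
                   ifelse(eclip_detected & ipart_loaded, "both",
                   ifelse(eclip_detected | ipart_loaded, "one", "neither")))]
  dt[, combined := factor(combined,
                          levels = c("both", "one", "neither", "excluded"))]
  dt[, union_detected := eclip_detected | ipart_loaded]
  setorder(dt, exon_id)
  dt[]
}

#' Jaccard agreement of two peak sets
#'
#' Each peak is extended by `slop` nt on both ends; the intersection is the
#' number of peaks of `a` overlapping (>= 1 bp, same strand) at least one
#' extended peak of `b`, and the union is `|a| + |b| - intersection`
#' (inclusion-exclusion, Venn-style counting from `a`'s perspective — the
#' definition is count-based and its asymmetry under many-to-many overlaps is
#' reported, not hidden).
#'
#' @param a,b Peak tables (`chrom`, `start`, `end`, `strand`; 0-based
#'   half-open).
#' @param slop Extension in nt (default 5).
#' @return List with `intersection`, `union`, `jaccard` (`NA` when both sets
#'   are empty).
#' @export
jaccard_peaks <- function(a, b, slop = 5L) {
  na <- nrow(a); nb <- nrow(b)
  if (na + nb == 0) {
    message("both peak sets are empty; Jaccard undefined")
    return(list(intersection = 0L, union = 0L, jaccard = NA_real_))
  }
  if (na == 0 || nb == 0)
    return(list(intersection = 0L, union = na + nb, jaccard = 0))
  ext <- function(p) GenomicRanges::GRanges(
    p$chrom, IRanges::IRanges(pmax(p$start + 1L - slop, 1L), p$end + slop),
    strand = p$strand)
  hits <- GenomicRanges::findOverlaps(ext(a), ext(b))
  inter <- length(unique(S4Vectors::queryHits(hits)))
  uni <- na + nb - inter
  list(intersection = inter, union = uni, jaccard = inter / uni)
}

#' Genes expressed and detected in both assays
#'
#' The minimal zero/nonzero reading of "expressed and detected in both
#' datasets": genes with at least `min_reads` mRNA-seq reads (nonzero RPKM in
#' the ipaRt control) and at least `min_reads` SMInput reads (nonzero eCLIP
#' background coverage).
#'
#' @param exons Exon table.
#' @param rna_reads mRNA-seq read table (controls pooled as desired).
#' @param sminput_reads SMInput read table.
#' @param min_reads Minimum read count per gene in each assay (default 1).
#' @return Character vector of gene ids.
#' @export
expressed_genes <- function(exons, rna_reads, sminput_reads, min_reads = 1L) {
  per_gene <- function(reads) {
    cnt <- exon_read_counts(reads, exons)
    cnt[, gene_id := exons$gene_id[match(exon_id, exons$exon_id)]]
    cnt[, .(count = sum(count)), by = gene_id]
  }
  r <- per_gene(rna_reads)
  s <- per_gene(sminput_reads)
  intersect(r[count >= min_reads, gene_id], s[count >= min_reads, gene_id])
}

#' Read a BED6 peak file as a peak set
#' @param path BED6 path.
#' @param label Optional label attached as attribute.
#' @return Peak `data.table` (0-based half-open) for [jaccard_peaks()].
#' @export
read_peaks_bed <- function(path, label = basename(path)) {
  p <- read_bed6(path)
  setattr(p, "label", label)
  p
}
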