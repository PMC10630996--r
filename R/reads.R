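#' Read a 6-column BED file of single-end alignments
#'
#' The alignment's 5' end (interpreted as the crosslink / truncation site) is
#' `start` on `+` and `end - 1` on `-` (0-based half-open BED convention).
#'
#' @param path Path to a BED6 file.
#' @return `data.table` with `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed6 <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "start", "end", "name", "score", "strand"))
  dt[, `:=`(chrom = as.character(chrom), start = as.integer(start),
            end = as.integer(end), name = as.character(name),
            strand = as.character(strand))]
  if (any(!dt$strand %in% c("+", "-")))
    stop("BED6 strand column must be '+' or '-': ", path)
  dt
}

#' Write alignments as BED6
#' @param reads `data.table`/`data.frame` with `chrom`, `start`, `end`, `strand`
#'   (and optionally `name`, `score`).
#' @param path Output path.
#' @export
write_bed6 <- function(reads, path) {
  out <- data.table(chrom = reads$chrom, start = reads$start, end = reads$end,
                    name = if ("name" %in% names(reads)) reads$name else
                      sprintf("r%d", seq_len(nrow(reads))),
                    score = if ("score" %in% names(reads)) reads$score else 0L,
                    strand = reads$strand)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read / write a genome FASTA
#' @param path FASTA path.
#' @return Named `DNAStringSet`.
#' @export
read_genome_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_genome_fasta
#' @param genome Named `DNAStringSet` or named character vector.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

exons_granges <- function(exons) {
  GenomicRanges::GRanges(exons$chrom,
                         IRanges::IRanges(exons$start + 1L, exons$end),
                         strand = exons$strand)
}

# 5' base genomic position (0-based) of each read
fiveprime_base <- function(reads) {
  ifelse(reads$strand == "+", reads$start, reads$end - 1L)
}

# Assign reads to exons by an anchor base (strand-matched overlap) and return
# junction-relative coordinates of the read's 5' and 3' ends in that exon.
# anchor: "fiveprime" or "midpoint". rel3 is clipped at -1 (the junction).
assign_reads <- function(reads, exons, anchor = c("fiveprime", "midpoint")) {
  anchor <- match.arg(anchor)
  g5 <- fiveprime_base(reads)
  g3 <- ifelse(reads$strand == "+", reads$end - 1L, reads$start)
  ab <- if (anchor == "fiveprime") g5 else
    ifelse(reads$strand == "+",
           (g5 + g3) %/% 2L,          # floor of the mean
           -((-g5 - g3) %/% 2L))      # ceiling of the mean
  q <- GenomicRanges::GRanges(reads$chrom, IRanges::IRanges(ab + 1L, ab + 1L),
                              strand = reads$strand)
  hits <- GenomicRanges::findOverlaps(q, exons_granges(exons))
  i <- S4Vectors::queryHits(hits)
  j <- S4Vectors::subjectHits(hits)
  rel5 <- rel_position_vec(g5[i], exons$start[j], exons$end[j], exons$strand[j])
  width <- (reads$end - reads$start)[i]
  data.table(read = i,
             exon_id = exons$exon_id[j],
             exon_len = (exons$end - exons$start)[j],
             rel5 = rel5,
             rel3 = pmin(rel5 + width - 1L, -1L))
}

# Junction-relative [lo, hi] span of the overlap of each read with each exon
# it intersects (strand-matched). Used for coverage-based (ipaRt) scoring.
assign_read_spans <- function(reads, exons) {
  q <- GenomicRanges::GRanges(reads$chrom,
                              IRanges::IRanges(reads$start + 1L, reads$end),
                              strand = reads$strand)
  hits <- GenomicRanges::findOverlaps(q, exons_granges(exons))
  i <- S4Vectors::queryHits(hits)
  j <- S4Vectors::subjectHits(hits)
  ds <- pmax(reads$start[i], exons$start[j])        # overlap, 0-based half-open
  de <- pmin(reads$end[i], exons$end[j])
  lo <- ifelse(exons$strand[j] == "+", ds - exons$end[j],
               exons$start[j] - de)
  hi <- ifelse(exons$strand[j] == "+", de - 1L - exons$end[j],
               exons$start[j] - ds - 1L)
  data.table(read = i, exon_id = exons$exon_id[j],
             exon_len = (exons$end - exons$start)[j],
             rel_lo = lo, rel_hi = hi)
}

#' Per-exon read counts (5' end within the exon)
#'
#' @param reads Alignment table (BED6 columns).
#' @param exons Exon table.
#' @return `data.table` with `exon_id` and `count` (zero for exons with no
#'   assigned reads).
#' @export
exon_read_counts <- function(reads, exons) {
  asn <- assign_reads(reads, exons, "fiveprime")
  cnt <- asn[, .(count = .N), by = exon_id]
  out <- merge(data.table(exon_id = exons$exon_id), cnt,
               by = "exon_id", all.x = TRUE, sort = FALSE)
  out[is.na(count), count := 0L]
  out
}
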