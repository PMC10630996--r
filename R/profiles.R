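#' Meta-exon profile of read 5' ends
#'
#' Distribution of read 5' ends (the crosslink / truncation proxy) relative to
#' the downstream exon junction, pooled over all exons. The raw count at each
#' relative position `d` is normalized by the number of exons long enough to
#' contain that position and by the library size:
#' `signal(d) = count(d) / (n_exons(length >= |d|) * library_size) * 1e6`
#' (the 1e6 factor only rescales for readability; all downstream uses are
#' shape-based). Reads whose 5' end falls outside every exon are dropped and
#' counted in the `n_dropped` attribute.
#'
#' @param reads Alignment table (`chrom`, `start`, `end`, `strand`).
#' @param exons Exon table (see [exon_table()]).
#' @param library_size Total mapped reads of the library; defaults to
#'   `nrow(reads)`.
#' @return `data.table` of class `meta_exon_profile` with columns `position`,
#'   `raw_count`, `n_exons`, `signal`; attributes `n_reads_used`, `n_dropped`,
#'   `library_size`, `normalization`, `mode`.
#' @export
fiveprime_profile <- function(reads, exons, library_size = nrow(reads)) {
  stopifnot(library_size > 0)
  asn <- assign_reads(reads, exons, "fiveprime")
  build_profile(asn$rel5, exons, library_size,
                n_total = nrow(reads), mode = "fiveprime")
}

#' Meta-exon profile of read midpoints
#'
#' As [fiveprime_profile()], but positions are read midpoints,
#' `floor((rel5 + rel3) / 2)` in junction-relative coordinates (the floor pulls
#' even-length reads to the deterministic integer position). A read is assigned
#' to the exon containing its midpoint. This is the coverage-based readout used
#' for ipaRt-style protected fragments, which lack nucleotide resolution.
#'
#' @inheritParams fiveprime_profile
#' @return See [fiveprime_profile()].
#' @export
midpoint_profile <- function(reads, exons, library_size = nrow(reads)) {
  stopifnot(library_size > 0)
  asn <- assign_reads(reads, exons, "midpoint")
  mid <- (asn$rel5 + asn$rel3) %/% 2L   # integer floor division
  build_profile(mid, exons, library_size,
                n_total = nrow(reads), mode = "midpoint")
}

build_profile <- function(rel, exons, library_size, n_total, mode) {
  cnt <- data.table(position = rel)[, .(raw_count = .N), by = position]
  setorder(cnt, position)
  lens <- sort(exons$end - exons$start)
  # exons with length >= |d|
  cnt[, n_exons := length(lens) - findInterval(abs(position) - 0.5, lens)]
  stopifnot(all(cnt$n_exons > 0))
  cnt[, signal := raw_count / (n_exons * library_size) * 1e6]
  setattr(cnt, "n_reads_used", sum(cnt$raw_count))
  setattr(cnt, "n_dropped", n_total - sum(cnt$raw_count))
  setattr(cnt, "library_size", library_size)
  setattr(cnt, "normalization", "per-exon-and-library")
  setattr(cnt, "mode", mode)
  setattr(cnt, "class", c("meta_exon_profile", class(cnt)))
  cnt[]
}

#' Position of the meta-exon profile maximum
#'
#' Argmax of the normalized signal within a search interval; ties are broken
#' toward the junction (the larger, less negative position).
#'
#' @param profile A `meta_exon_profile`.
#' @param search Inclusive relative interval to search (default `c(-100, -1)`).
#' @return Integer position of the maximum.
#' @export
peak_position <- function(profile, search = c(-100L, -1L)) {
  search <- check_window(search)
  p <- profile[profile$position >= search[1] & profile$position <= search[2], ]
  if (nrow(p) == 0 || all(p$signal == 0))
    stop("profile has no signal in the search interval")
  max(p$position[p$signal == max(p$signal)])
}

#' Write a meta-exon profile as TSV
#' @param profile A `meta_exon_profile`.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  fwrite(profile, path, sep = "\t")
  invisible(path)
}
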