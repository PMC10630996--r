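#' Transcript model
#'
#' A minimal strand-aware gene model: one transcript with its exons stored as
#' 0-based half-open genomic intervals, ordered 5' to 3' in transcript
#' orientation (ascending genomic coordinate on `+`, descending on `-`).
#'
#' @param gene_id,transcript_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors of 0-based half-open exon
#'   intervals (any order; they are sorted into transcript orientation).
#' @return An object of class `TranscriptModel`.
#' @export
transcript_model <- function(gene_id, transcript_id, chrom, strand,
                             exon_starts, exon_ends) {
  stopifnot(length(exon_starts) == length(exon_ends), length(exon_starts) >= 1,
            strand %in% c("+", "-"))
  exon_starts <- as.integer(exon_starts)
  exon_ends <- as.integer(exon_ends)
  if (any(exon_ends <= exon_starts))
    stop("exon intervals must be non-empty half-open [start, end)")
  ord <- order(exon_starts)
  if (strand == "-") ord <- rev(ord)
  exon_starts <- exon_starts[ord]
  exon_ends <- exon_ends[ord]
  # non-overlap check in genomic order
  gs <- sort(exon_starts); ge <- exon_ends[order(exon_starts)]
  if (length(gs) > 1 && any(gs[-1] < ge[-length(ge)]))
    stop("exons of one transcript must not overlap")
  structure(
    list(gene_id = gene_id, transcript_id = transcript_id, chrom = chrom,
         strand = strand,
         exons = data.frame(start = exon_starts, end = exon_ends)),
    class = "TranscriptModel")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (%s) %s:%s %d exon(s), %d nt exonic\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), sum(x$exons$end - x$exons$start)))
  invisible(x)
}

n_exons <- function(model) nrow(model$exons)
exonic_length <- function(model) sum(model$exons$end - model$exons$start)

#' Parse a GTF file into transcript models
#'
#' Reads exon features (Ensembl attribute dialect: `gene_id`, `transcript_id`)
#' and returns one [transcript_model()] per transcript. GTF's 1-based closed
#' coordinates are converted to the package-wide 0-based half-open convention.
#' Exon records without a `transcript_id` attribute are dropped with a warning.
#'
#' @param path Path to a GTF file.
#' @return Named list of `TranscriptModel` (names = transcript ids).
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 9)) {
    bad <- which(body)[which(nfield < 9)[1]]
    stop("malformed GTF line ", bad, " in ", path, " (fewer than 9 fields)")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) stop("no exon features in ", path)
  tx <- gr$transcript_id
  if (anyNA(tx) || any(tx == "")) {
    drop <- is.na(tx) | tx == ""
    warning(sum(drop), " exon record(s) without transcript_id dropped")
    gr <- gr[!drop]
    tx <- gr$transcript_id
  }
  df <- data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = gr$gene_id,
    transcript_id = tx)
  models <- lapply(split(df, by = "transcript_id", sorted = TRUE), function(d) {
    transcript_model(d$gene_id[1], d$transcript_id[1], d$chrom[1], d$strand[1],
                     d$start, d$end)
  })
  models
}

#' Write transcript models as a GTF file
#'
#' Emits exon features only, 1-based closed coordinates, Ensembl-style
#' `gene_id`/`transcript_id` attributes. Deterministic line order (transcript
#' order as given, exons 5' to 3').
#'
#' @param models List of `TranscriptModel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  lines <- unlist(lapply(models, function(m) {
    sprintf('%s\tejcmap\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
            m$chrom, m$exons$start + 1L, m$exons$end, m$strand,
            m$gene_id, m$transcript_id)
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Select the representative transcript of a gene
#'
#' One isoform per gene: the transcript with the most exons; ties broken by
#' the larger summed exonic length; remaining ties by lexicographically
#' smallest `transcript_id` (a declared convention, needed for determinism).
#'
#' @param transcripts Non-empty list of `TranscriptModel`, all one gene.
#' @return A single `TranscriptModel`.
#' @export
select_representative <- function(transcripts) {
  if (length(transcripts) == 0) stop("empty transcript list")
  gid <- vapply(transcripts, function(m) m$gene_id, "")
  if (length(unique(gid)) != 1)
    stop("select_representative() expects transcripts of a single gene")
  ne <- vapply(transcripts, n_exons, 0L)
  el <- vapply(transcripts, exonic_length, 0L)
  tid <- vapply(transcripts, function(m) m$transcript_id, "")
  ord <- order(-ne, -el, tid, method = "radix")
  transcripts[[ord[1]]]
}

#' Reduce a transcript list to one representative transcript per gene
#'
#' @param models List of `TranscriptModel` (any number of genes).
#' @return Named list of `TranscriptModel`, one per gene, ordered by gene id.
#' @export
representative_models <- function(models) {
  gid <- vapply(models, function(m) m$gene_id, "")
  out <- lapply(split(models, gid), select_representative)
  out[order(names(out), method = "radix")]
}

#' Classify the exons of a transcript
#'
#' Assigns each exon a positional class: `first`/`internal`/`last` for
#' multi-exon transcripts (in transcript orientation) and `single` for
#' one-exon transcripts, which lack splicing and are kept out of the
#' first/internal/last tallies.
#'
#' @param model A `TranscriptModel`.
#' @return `data.table` with columns `exon_id` (`gene_id:index`), `gene_id`,
#'   `transcript_id`, `index` (1-based, transcript order), `cls`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, `length`.
#' @export
classify_exons <- function(model) {
  n <- n_exons(model)
  cls <- if (n == 1) "single" else c("first", rep("internal", max(0L, n - 2L)), "last")
  data.table(
    exon_id = paste0(model$gene_id, ":", seq_len(n)),
    gene_id = model$gene_id,
    transcript_id = model$transcript_id,
    index = seq_len(n),
    cls = cls,
    chrom = model$chrom,
    start = model$exons$start,
    end = model$exons$end,
    strand = model$strand,
    length = model$exons$end - model$exons$start)
}

#' Exon table for a set of transcript models
#'
#' Row-binds [classify_exons()] over all models. This is the exon-relative
#' coordinate frame every downstream stage works in.
#'
#' @param models List of `TranscriptModel` (typically one per gene, see
#'   [representative_models()]).
#' @return `data.table`, one row per exon (see [classify_exons()]).
#' @export
exon_table <- function(models) {
  rbindlist(lapply(models, classify_exons))
}

#' Write the exon table as TSV
#' @param exons Exon table from [exon_table()].
#' @param path Output path.
#' @export
write_exon_table <- function(exons, path) {
  fwrite(exons, path, sep = "\t")
  invisible(path)
}

#' Junction-relative position of a genomic coordinate within an exon
#'
#' Positions are negative integers counted from the downstream (3', junction
#' side) exon boundary in transcript orientation: the junction-adjacent base is
#' -1 and the 5'-most base of the exon is -length. On `+` the offset is
#' `g - end`; on `-` it is `start - g - 1` (0-based coordinates).
#'
#' @param g Integer vector of 0-based genomic base positions inside the exon.
#' @param exon A single exon: one-row data.frame or list with `start`, `end`,
#'   `strand`.
#' @return Integer vector of negative offsets.
#' @export
relative_position <- function(g, exon) {
  g <- as.integer(g)
  if (any(g < exon$start | g >= exon$end))
    stop("genomic position outside exon [", exon$start, ",", exon$end, ")")
  rel_position_vec(g, exon$start, exon$end, exon$strand)
}

#' @rdname relative_position
#' @param start,end,strand Vectorized exon coordinates (0-based half-open).
#' @details `rel_position_vec()` is the vectorized core without the bounds
#'   check; `genomic_position_vec()` is its inverse, mapping a relative
#'   position back to the 0-based genomic base.
#' @export
rel_position_vec <- function(g, start, end, strand) {
  ifelse(strand == "+", g - end, start - g - 1L)
}

#' @rdname relative_position
#' @param rel Integer vector of negative junction-relative positions.
#' @export
genomic_position_vec <- function(rel, start, end, strand) {
  ifelse(strand == "+", end + rel, start - rel - 1L)
}

#' Sense-strand sequence of a junction-relative window
#'
#' Extracts the transcript-sense nucleotides of an inclusive relative window
#' `[a, b]` (a <= b <= -1) of each exon; minus-strand exons are
#' reverse-complemented. Exons shorter than `|a|` yield `NA` (window undefined).
#'
#' @param exons Exon table (or a single-row exon).
#' @param genome Named `DNAStringSet` (or named character vector) of chromosomes.
#' @param window Integer length-2 inclusive relative interval, e.g. `c(-30, -24)`.
#' @return Character vector of window sequences, 5' to 3' on the sense strand.
#' @export
window_sequences <- function(exons, genome, window) {
  window <- check_window(window)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  miss <- setdiff(unique(exons$chrom), names(genome))
  if (length(miss)) stop("chromosome(s) missing from genome: ",
                         paste(miss, collapse = ", "))
  a <- window[1]; b <- window[2]
  len <- exons$end - exons$start
  ok <- len >= abs(a)
  # 1-based substring bounds on the plus strand
  from <- ifelse(exons$strand == "+", exons$end + a + 1L, exons$start - b)
  to <- ifelse(exons$strand == "+", exons$end + b + 1L, exons$start - a)
  out <- rep(NA_character_, nrow(exons))
  if (any(ok)) {
    chrs <- as.character(genome)
    seqs <- substr(chrs[exons$chrom[ok]], from[ok], to[ok])
    neg <- exons$strand[ok] == "-"
    if (any(neg))
      seqs[neg] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[neg])))
    out[ok] <- seqs
  }
  out
}

#' Count uridines in a junction-relative window
#'
#' Counts `T` on the transcript sense strand within an inclusive relative
#' window (default `[-30, -24]`, seven nucleotides around the canonical -27
#' crosslink). Exons shorter than the window are flagged `NA`.
#'
#' @inheritParams window_sequences
#' @return Integer vector of U counts (`NA` where the window is undefined).
#' @export
count_uridines <- function(exons, genome, window = c(-30L, -24L)) {
  s <- window_sequences(exons, genome, window)
  n <- nchar(gsub("[^Tt]", "", s))
  n[is.na(s)] <- NA_integer_
  as.integer(n)
}

#' U content of the crosslink footprint
#'
#' Convenience wrapper of [count_uridines()] over the generator's crosslinkable
#' footprint (default `[-32, -23]`), used for U-bias stratification.
#'
#' @inheritParams window_sequences
#' @return `data.table` with `exon_id` and `u_count`.
#' @export
footprint_u_counts <- function(exons, genome, window = c(-32L, -23L)) {
  data.table(exon_id = exons$exon_id,
             u_count = count_uridines(exons, genome, window))
}

check_window <- function(window) {
  if (length(window) != 2 || any(!is.finite(window)))
    stop("window must be two finite integers")
  window <- as.integer(window)
  if (window[1] > window[2] || window[2] > -1L)
    stop("window must be an inclusive interval of negative positions, [a, b] with a <= b <= -1")
  window
}
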