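# shared fixtures: tiny constructed exons/reads and cached synthetic runs

toy_exon <- function(start = 100L, end = 200L, strand = "+", id = "gX:1",
                     cls = "internal", gene = "gX", chrom = "chr1") {
  data.table::data.table(exon_id = id, gene_id = gene, transcript_id = "t1",
                         index = 1L, cls = cls, chrom = chrom,
                         start = as.integer(start), end = as.integer(end),
                         strand = strand, length = as.integer(end - start))
}

mk_reads <- function(start, end, strand = "+", chrom = "chr1") {
  data.table::data.table(chrom = chrom, start = as.integer(start),
                         end = as.integer(end), strand = strand)
}

# reads specified by junction-relative 5'/3' positions within one exon
rel_reads <- function(exon, rel5, rel3) {
  if (exon$strand == "+") {
    g5 <- exon$end + rel5
    g3 <- exon$end + rel3
    mk_reads(g5, g3 + 1L, "+", exon$chrom)
  } else {
    g5 <- exon$start - rel5 - 1L
    g3 <- exon$start - rel3 - 1L
    mk_reads(g3, g5 + 1L, "-", exon$chrom)
  }
}

# synthetic experiments are expensive; cache them across test files
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(name, config) {
  if (!exists(name, envir = .sim_cache))
    assign(name, simulate_ejc_experiment(config), envir = .sim_cache)
  get(name, envir = .sim_cache)
}

# a mid-size run used by several unit tests (not the acceptance conditions)
small_config <- function(...) {
  sim_config(n_genes = 120L, eclip_depth = 60000L, sminput_depth = 60000L,
             ipart_depth = 45000L, rna_depth = 90000L, seed = 101L, ...)
}

small_sim <- function() cached_sim("small", small_config())

# a very small run for structural checks
tiny_config <- function(...) {
  sim_config(n_genes = 25L, eclip_depth = 8000L, sminput_depth = 8000L,
             ipart_depth = 6000L, rna_depth = 12000L, seed = 33L, ...)
}
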