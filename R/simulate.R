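#' Configuration of the synthetic EJC experiment
#'
#' Defines a toy genome with spliced gene models, EJC deposition on first and
#' internal exons only, and four read-generating assays: eCLIP replicates
#' (reverse-transcriptase truncations at crosslink sites, with readthrough),
#' size-matched input (SMInput) background, ipaRt-style protected fragments,
#' and mRNA-seq coverage. All libraries are seeded and deterministic.
#'
#' Default values are the study conditions used throughout the package's
#' analyses: 500 genes of 2-8 exons (60-600 nt, introns 60-200 nt), gene
#' expression log-uniform over 1-300 (arbitrary RPKM-like weights), universal
#' deposition on eligible exons, crosslinks drawn from the `[-32, -23]`
#' footprint with a geometric positional kernel centred on -27 and a 10-fold
#' preference for uridines, 15% readthrough, 35-nt reads, 10% background, and
#' a `[-36, -10]` protected fragment with up to 3 nt of end jitter.
#'
#' @param n_genes Number of genes.
#' @param exons_per_gene,exon_length,intron_length Integer sampling ranges
#'   `c(min, max)`.
#' @param expression_range Log-uniform sampling range of per-gene expression
#'   weights (shared by all exons of a gene).
#' @param deposition_prob Probability that an eligible (first/internal) exon
#'   carries an EJC.
#' @param crosslink_offset Canonical crosslink position (relative, default -27).
#' @param footprint Inclusive relative interval of crosslinkable positions.
#' @param u_weight Relative crosslink propensity of a uridine position.
#' @param zero_u_efficiency Capture multiplier for exons with no U in the
#'   footprint.
#' @param readthrough_prob Probability that reverse transcription passes the
#'   crosslink (5' end displaced upstream by a geometric overshoot, p = 0.5).
#' @param read_length Read length, nt (eCLIP / SMInput / mRNA-seq).
#' @param background_frac Fraction of IP reads (eCLIP and ipaRt) drawn from the
#'   corresponding background distribution.
#' @param ipart_fragment Inclusive relative interval of the ipaRt-protected
#'   fragment.
#' @param ipart_jitter Uniform +/- jitter (nt) applied independently to each
#'   fragment end.
#' @param n_eclip_reps,n_sminput,n_ipart_reps,n_rna Library counts.
#' @param eclip_depth,sminput_depth,ipart_depth,rna_depth Reads per library.
#' @param intergenic_gap Spacer between genes, nt.
#' @param chrom Chromosome name of the toy genome.
#' @param seed Integer master seed; per-library seeds are derived from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500L,
                       exons_per_gene = c(2L, 8L),
                       exon_length = c(60L, 600L),
                       intron_length = c(60L, 200L),
                       expression_range = c(1, 300),
                       deposition_prob = 1,
                       crosslink_offset = -27L,
                       footprint = c(-32L, -23L),
                       u_weight = 10,
                       zero_u_efficiency = 0.25,
                       readthrough_prob = 0.15,
                       read_length = 35L,
                       background_frac = 0.1,
                       ipart_fragment = c(-36L, -10L),
                       ipart_jitter = 3L,
                       n_eclip_reps = 3L, n_sminput = 2L,
                       n_ipart_reps = 3L, n_rna = 2L,
                       eclip_depth = 200000L, sminput_depth = 200000L,
                       ipart_depth = 150000L, rna_depth = 300000L,
                       intergenic_gap = 200L,
                       chrom = "chr_sim",
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              expression_range = as.numeric(expression_range),
              deposition_prob = deposition_prob,
              crosslink_offset = as.integer(crosslink_offset),
              footprint = check_window(footprint),
              u_weight = u_weight,
              zero_u_efficiency = zero_u_efficiency,
              readthrough_prob = readthrough_prob,
              read_length = as.integer(read_length),
              background_frac = background_frac,
              ipart_fragment = check_window(ipart_fragment),
              ipart_jitter = as.integer(ipart_jitter),
              n_eclip_reps = as.integer(n_eclip_reps),
              n_sminput = as.integer(n_sminput),
              n_ipart_reps = as.integer(n_ipart_reps),
              n_rna = as.integer(n_rna),
              eclip_depth = as.integer(eclip_depth),
              sminput_depth = as.integer(sminput_depth),
              ipart_depth = as.integer(ipart_depth),
              rna_depth = as.integer(rna_depth),
              intergenic_gap = as.integer(intergenic_gap),
              chrom = chrom,
              seed = as.integer(seed))
  probs <- c(cfg$deposition_prob, cfg$readthrough_prob, cfg$background_frac)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$n_genes < 1) stop("n_genes must be >= 1")
  if (cfg$exon_length[1] < abs(cfg$footprint[1]))
    stop("minimum exon length must cover the crosslink footprint")
  if (cfg$exon_length[1] < abs(cfg$ipart_fragment[1]) + cfg$ipart_jitter)
    stop("minimum exon length must cover the ipaRt fragment plus jitter")
  if (cfg$crosslink_offset < cfg$footprint[1] ||
      cfg$crosslink_offset > cfg$footprint[2])
    stop("crosslink_offset must lie within the footprint")
  if (cfg$expression_range[1] <= 0 ||
      cfg$expression_range[2] < cfg$expression_range[1])
    stop("expression_range must be positive and increasing")
  class(cfg) <- "sim_config"
  cfg
}

# deterministic per-library seed, kept below 2^31
lib_seed <- function(config, offset) {
  as.integer((as.double(config$seed) * 131L + offset * 9973) %% 2147483629)
}

sample_range <- function(range, n) {
  if (range[1] == range[2]) rep(range[1], n) else
    sample(seq.int(range[1], range[2]), n, replace = TRUE)
}

#' Build the toy genome, annotation, and deposition truth
#'
#' Generates a random-sequence chromosome with `n_genes` non-overlapping gene
#' models on both strands (Bernoulli(0.5)), assigns each gene a log-uniform
#' expression weight, and draws per-exon EJC deposition status: first and
#' internal exons are eligible with probability `deposition_prob`; last and
#' single exons are never loaded.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_genome` with `genome` (`DNAStringSet`), `models`
#'   (list of `TranscriptModel`), `exons` (exon table), `truth` (`data.table`:
#'   `exon_id`, `gene_id`, `cls`, `length`, `expression_weight`, `loaded`) and
#'   `config`.
#' @export
build_toy_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(lib_seed(config, 1L))
  n <- config$n_genes
  nex <- sample_range(config$exons_per_gene, n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  models <- vector("list", n)
  cursor <- config$intergenic_gap
  for (i in seq_len(n)) {
    k <- nex[i]
    elens <- sample_range(config$exon_length, k)
    ilens <- if (k > 1) sample_range(config$intron_length, k - 1L) else integer(0)
    starts <- cursor + cumsum(c(0L, elens[-k] + ilens))
    ends <- starts + elens
    gid <- sprintf("g%04d", i)
    models[[i]] <- transcript_model(gid, paste0(gid, ".t1"), config$chrom,
                                    strand[i], starts, ends)
    cursor <- ends[k] + config$intergenic_gap
  }
  seq <- paste(sample(c("A", "C", "G", "T"), cursor + config$intergenic_gap,
                      replace = TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(setNames(seq, config$chrom))
  exons <- exon_table(models)
  lw <- log(config$expression_range)
  expr <- exp(runif(n, lw[1], lw[2]))
  truth <- data.table(
    exon_id = exons$exon_id, gene_id = exons$gene_id, cls = exons$cls,
    length = exons$length,
    expression_weight = expr[match(exons$gene_id, sprintf("g%04d", seq_len(n)))])
  eligible <- truth$cls %in% c("first", "internal")
  truth[, loaded := eligible & runif(.N) < config$deposition_prob]
  structure(list(genome = genome, models = models, exons = exons,
                 truth = truth, config = config),
            class = "sim_genome")
}

# mean per-position U factor over the footprint; the capture efficiency of an
# exon grows linearly with its footprint U count (crosslinking prefers U),
# and zero-U footprints are further penalized.
capture_multiplier <- function(u_counts, config) {
  w <- config$footprint[2] - config$footprint[1] + 1L
  mult <- (w + (config$u_weight - 1) * u_counts) / w
  mult[u_counts == 0] <- mult[u_counts == 0] * config$zero_u_efficiency
  mult
}

# per-exon footprint position weights: geometric kernel centred on the
# canonical offset times the per-position U factor
footprint_weights <- function(fp_seqs, config) {
  fp <- seq.int(config$footprint[1], config$footprint[2])
  kernel <- 0.5^abs(fp - config$crosslink_offset)
  lapply(strsplit(fp_seqs, ""), function(b) {
    kernel * ifelse(b == "T", config$u_weight, 1)
  })
}

# uniform background fragments over exonic positions of expressed transcripts:
# exon chosen proportional to expression * length, 5' start uniform in the exon
sample_background_reads <- function(sim, n, read_length) {
  tr <- sim$truth
  ex <- sim$exons
  w <- tr$expression_weight * tr$length
  idx <- sample.int(nrow(ex), n, replace = TRUE, prob = w)
  len <- ex$length[idx]
  rel5 <- -(floor(runif(n) * len) + 1L)           # uniform in [-len, -1]
  rel3 <- pmin(rel5 + read_length - 1L, -1L)
  rel_reads_to_genomic(idx, rel5, rel3, ex)
}

# convert per-exon relative read spans to genomic BED-style intervals
rel_reads_to_genomic <- function(idx, rel5, rel3, ex) {
  strand <- ex$strand[idx]
  g5 <- genomic_position_vec(rel5, ex$start[idx], ex$end[idx], strand)
  g3 <- genomic_position_vec(rel3, ex$start[idx], ex$end[idx], strand)
  data.table(chrom = ex$chrom[idx],
             start = pmin(g5, g3),
             end = pmax(g5, g3) + 1L,
             strand = strand)
}

#' Simulate eCLIP replicates and SMInput controls
#'
#' For each loaded exon, crosslink positions are drawn within the footprint
#' (positional kernel times U preference); truncation reads start exactly at
#' the crosslink, and with probability `readthrough_prob` the 5' end overshoots
#' upstream by `1 + Geometric(0.5)` nt. Per-exon read counts are multinomial
#' with weight expression x capture efficiency; `background_frac` of each eCLIP
#' library is drawn from the SMInput distribution (uniform fragments over
#' expressed transcripts). SMInput libraries are pure background.
#'
#' @param config A [sim_config()].
#' @param sim Output of [build_toy_genome()].
#' @return List with `eclip` (list of read tables), `sminput` (list of read
#'   tables), and `crosslinks` (`data.table` of drawn crosslink positions:
#'   `exon_id`, `position`, `count`, pooled over replicates).
#' @export
simulate_eclip <- function(config, sim) {
  stopifnot(inherits(sim, "sim_genome"))
  tr <- sim$truth
  if (all(tr$expression_weight <= 0)) stop("no expressed genes")
  ex <- sim$exons
  loaded_idx <- which(tr$loaded)
  fp_seqs <- window_sequences(ex[loaded_idx], sim$genome, config$footprint)
  u_counts <- nchar(gsub("[^T]", "", fp_seqs))
  wpos <- footprint_weights(fp_seqs, config)
  wexon <- tr$expression_weight[loaded_idx] * capture_multiplier(u_counts, config)
  fp_lo <- config$footprint[1]
  nw <- config$footprint[2] - fp_lo + 1L

  xlink_acc <- vector("list", config$n_eclip_reps)
  eclip <- vector("list", config$n_eclip_reps)
  for (r in seq_len(config$n_eclip_reps)) {
    set.seed(lib_seed(config, 10L + r))
    n_sig <- if (length(loaded_idx) == 0) 0L else
      round(config$eclip_depth * (1 - config$background_frac))
    n_bg <- config$eclip_depth - n_sig
    if (n_sig == 0L) {
      xlink_acc[[r]] <- data.table(exon_id = character(0), position = integer(0))
      eclip[[r]] <- sample_background_reads(sim, n_bg, config$read_length)
      next
    }
    cnt <- as.vector(stats::rmultinom(1, n_sig, prob = wexon))
    keep <- which(cnt > 0)
    xl <- integer(n_sig); eidx <- integer(n_sig); at <- 1L
    for (k in keep) {
      ck <- cnt[k]
      pos <- fp_lo - 1L + sample.int(nw, ck, replace = TRUE, prob = wpos[[k]])
      xl[at:(at + ck - 1L)] <- pos
      eidx[at:(at + ck - 1L)] <- loaded_idx[k]
      at <- at + ck
    }
    xlink_acc[[r]] <- data.table(exon_id = ex$exon_id[eidx], position = xl)
    # readthrough: 5' end displaced upstream (more negative), clamped in exon
    rt <- runif(n_sig) < config$readthrough_prob
    p5 <- xl
    if (any(rt)) p5[rt] <- p5[rt] - (1L + rgeom(sum(rt), 0.5))
    p5 <- pmax(p5, -ex$length[eidx])
    p3 <- pmin(p5 + config$read_length - 1L, -1L)
    sig <- rel_reads_to_genomic(eidx, p5, p3, ex)
    bg <- sample_background_reads(sim, n_bg, config$read_length)
    eclip[[r]] <- rbind(sig, bg)
  }
  sminput <- vector("list", config$n_sminput)
  for (r in seq_len(config$n_sminput)) {
    set.seed(lib_seed(config, 20L + r))
    sminput[[r]] <- sample_background_reads(sim, config$sminput_depth,
                                            config$read_length)
  }
  xl <- rbindlist(xlink_acc)[, .(count = .N), by = .(exon_id, position)]
  list(eclip = eclip, sminput = sminput,
       crosslinks = xl[order(exon_id, position)])
}

#' Simulate ipaRt replicates and mRNA-seq controls
#'
#' ipaRt reads span the protected fragment around each loaded exon's junction
#' with independent uniform end jitter, counts proportional to expression;
#' `background_frac` of each replicate follows the mRNA-seq distribution.
#' mRNA-seq reads are uniform over exonic positions of expressed transcripts,
#' counts proportional to expression x length.
#'
#' @inheritParams simulate_eclip
#' @return List with `ipart` and `rna`, each a list of read tables.
#' @export
simulate_ipart <- function(config, sim) {
  stopifnot(inherits(sim, "sim_genome"))
  tr <- sim$truth
  if (all(tr$expression_weight <= 0)) stop("no expressed genes")
  ex <- sim$exons
  loaded_idx <- which(tr$loaded)
  wexon <- tr$expression_weight[loaded_idx]
  frag <- config$ipart_fragment
  j <- config$ipart_jitter
  ipart <- vector("list", config$n_ipart_reps)
  for (r in seq_len(config$n_ipart_reps)) {
    set.seed(lib_seed(config, 30L + r))
    n_sig <- if (length(loaded_idx) == 0) 0L else
      round(config$ipart_depth * (1 - config$background_frac))
    n_bg <- config$ipart_depth - n_sig
    if (n_sig == 0L) {
      ipart[[r]] <- sample_background_reads(sim, n_bg, config$read_length)
      next
    }
    cnt <- as.vector(stats::rmultinom(1, n_sig, prob = wexon))
    eidx <- rep(loaded_idx, cnt)
    nn <- length(eidx)
    j1 <- if (j > 0) sample.int(2L * j + 1L, nn, replace = TRUE) - j - 1L else 0L
    j2 <- if (j > 0) sample.int(2L * j + 1L, nn, replace = TRUE) - j - 1L else 0L
    p5 <- pmax(frag[1] + j1, -ex$length[eidx])
    p3 <- pmin(frag[2] + j2, -1L)
    p3 <- pmax(p3, p5)
    sig <- rel_reads_to_genomic(eidx, p5, p3, ex)
    bg <- sample_background_reads(sim, n_bg, config$read_length)
    ipart[[r]] <- rbind(sig, bg)
  }
  rna <- vector("list", config$n_rna)
  for (r in seq_len(config$n_rna)) {
    set.seed(lib_seed(config, 40L + r))
    rna[[r]] <- sample_background_reads(sim, config$rna_depth,
                                        config$read_length)
  }
  list(ipart = ipart, rna = rna)
}

#' Run the complete synthetic experiment
#'
#' [build_toy_genome()] + [simulate_eclip()] + [simulate_ipart()], returning
#' everything downstream stages need. Deterministic for a given `config`.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_experiment`: `genome`, `models`, `exons`,
#'   `truth` (with drawn crosslink positions attached as attribute
#'   `crosslinks`), and `reads` (lists `eclip`, `sminput`, `ipart`, `rna`).
#' @export
simulate_ejc_experiment <- function(config = sim_config()) {
  sim <- build_toy_genome(config)
  ecl <- simulate_eclip(config, sim)
  ipa <- simulate_ipart(config, sim)
  truth <- sim$truth
  data.table::setattr(truth, "crosslinks", ecl$crosslinks)
  structure(list(genome = sim$genome, models = sim$models, exons = sim$exons,
                 truth = truth,
                 reads = list(eclip = ecl$eclip, sminput = ecl$sminput,
                              ipart = ipa$ipart, rna = ipa$rna),
                 config = config),
            class = "sim_experiment")
}

#' Write a simulated experiment to disk
#'
#' FASTA genome, representative GTF, one BED6 per library, and TSV ground
#' truth. File contents are byte-identical across runs with the same config.
#'
#' @param sim A `sim_experiment` from [simulate_ejc_experiment()].
#' @param outdir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(outdir, "genome.fa"),
             annotation = file.path(outdir, "annotation.gtf"),
             truth = file.path(outdir, "truth.tsv"))
  write_genome_fasta(sim$genome, paths["genome"])
  write_gtf(sim$models, paths["annotation"])
  fwrite(sim$truth, paths["truth"], sep = "\t")
  for (grp in names(sim$reads)) {
    for (r in seq_along(sim$reads[[grp]])) {
      p <- file.path(outdir, sprintf("%s_rep%d.bed", grp, r))
      write_bed6(sim$reads[[grp]][[r]], p)
      paths[sprintf("%s_rep%d", grp, r)] <- p
    }
  }
  invisible(paths)
}
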