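# independent brute-force oracles, deliberately naive implementations

# loop over (read, position) pairs; counts arrests and read-through per position
brute_tabulate <- function(reads, exon) {
  g5 <- ifelse(reads$strand == "+", reads$start, reads$end - 1L)
  inside <- reads$strand == exon$strand & reads$chrom == exon$chrom &
    g5 >= exon$start & g5 < exon$end
  reads <- reads[inside, , drop = FALSE]
  g5 <- g5[inside]
  rel5 <- integer(0); rel3 <- integer(0)
  for (i in seq_len(nrow(reads))) {
    r5 <- if (exon$strand == "+") g5[i] - exon$end else exon$start - g5[i] - 1L
    width <- reads$end[i] - reads$start[i]
    rel5 <- c(rel5, r5)
    rel3 <- c(rel3, min(r5 + width - 1L, -1L))
  }
  out <- NULL
  if (length(rel5) == 0)
    return(data.frame(position = integer(0), n_arrest = integer(0),
                      n_through = integer(0)))
  for (p in seq(min(rel5), -1L)) {
    na <- 0L; nt <- 0L
    for (i in seq_along(rel5)) {
      if (rel5[i] == p) na <- na + 1L
      else if (rel5[i] < p && p <= rel3[i]) nt <- nt + 1L
    }
    if (na + nt > 0) out <- rbind(out, data.frame(position = p, n_arrest = na,
                                                  n_through = nt))
  }
  out
}

# reference chi-square p via stats::chisq.test (independent code path)
oracle_chisq_p <- function(a_s, t_s, a_c, t_c) {
  m <- matrix(c(a_s, t_s, a_c, t_c), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
}

# percentile by the explicit order-statistic interpolation h = (n-1)p + 1
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# window median coverage by explicit per-position depth counting
oracle_window_median <- function(rel_lo, rel_hi, window) {
  depths <- vapply(seq(window[1], window[2]), function(p) {
    sum(rel_lo <= p & p <= rel_hi)
  }, 0L)
  d <- depths[depths > 0]
  if (length(d) == 0) return(NA_real_)
  s <- sort(d)
  n <- length(s)
  if (n %% 2 == 1) as.numeric(s[(n + 1) / 2]) else (s[n / 2] + s[n / 2 + 1]) / 2
}
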