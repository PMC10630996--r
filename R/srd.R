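#' Tabulate reverse-transcription arrests per position of one exon
#'
#' For a read set assigned to an exon (5' end within the exon), counts at each
#' junction-relative position: `n_arrest` (reads whose 5' end is exactly
#' there, i.e. RT stopped at that nucleotide) and `n_through` (reads covering
#' the position whose 5' end lies 5'-ward of it, i.e. RT read through).
#' Coverage for stop-rate purposes is `n_arrest + n_through`; reads ending
#' 3' of a position do not contribute to it.
#'
#' @param reads Alignment table.
#' @param exon A single exon (one-row exon table).
#' @return `data.table` with `exon_id`, `position`, `n_arrest`, `n_through`,
#'   `stop_rate` for every position with nonzero coverage.
#' @export
tabulate_arrests <- function(reads, exon) {
  ex <- as.data.table(exon)
  stopifnot(nrow(ex) == 1)
  arrest_counts(reads, ex)
}

#' Tabulate arrests over all exons
#'
#' Vectorized form of [tabulate_arrests()]: reads are assigned to the exon
#' containing their 5' end (strand-matched) and per-position arrest/through
#' counts are produced for every covered position of every exon.
#'
#' @param reads Alignment table.
#' @param exons Exon table.
#' @return `data.table` with `exon_id`, `position`, `n_arrest`, `n_through`,
#'   `stop_rate`.
#' @export
arrest_counts <- function(reads, exons) {
  asn <- assign_reads(reads, exons, "fiveprime")
  if (nrow(asn) == 0)
    return(data.table(exon_id = character(0), position = integer(0),
                      n_arrest = integer(0), n_through = integer(0),
                      stop_rate = numeric(0)))
  out <- asn[, {
    lo <- min(rel5); hi <- max(rel3)
    npos <- hi - lo + 1L
    tab5 <- tabulate(rel5 - lo + 1L, nbins = npos)
    tab3 <- tabulate(rel3 - lo + 1L, nbins = npos)
    # coverage(p) = #{rel5 <= p} - #{rel3 <= p - 1}
    covv <- cumsum(tab5) - c(0L, cumsum(tab3)[-npos])
    keep <- covv > 0L
    .(position = (lo:hi)[keep], n_arrest = tab5[keep],
      n_through = covv[keep] - tab5[keep])
  }, by = exon_id]
  out[, stop_rate := n_arrest / (n_arrest + n_through)]
  setorder(out, exon_id, position)
  out[]
}

#' Chi-square test of arrest rate, sample versus control
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2 table
#' `[[n_arrest_s, n_through_s], [n_arrest_c, n_through_c]]`. Degenerate tables
#' (any zero marginal) return p = 1. Vectorized over all four arguments.
#' Significance downstream additionally requires the sample stop rate to
#' exceed the control's (a one-sided direction gate applied by
#' [srd_position_table()]).
#'
#' @param a_s,t_s Sample arrest / through counts.
#' @param a_c,t_c Control arrest / through counts.
#' @return Numeric vector of p-values.
#' @export
stop_rate_test <- function(a_s, t_s, a_c, t_c) {
  n <- a_s + t_s + a_c + t_c
  r1 <- a_s + t_s; r2 <- a_c + t_c
  c1 <- a_s + a_c; c2 <- t_s + t_c
  p <- rep(1, length(n))
  ok <- r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0
  stat <- (as.double(a_s) * t_c - as.double(t_s) * a_c)^2 * n /
    (as.double(r1) * r2 * c1 * c2)
  p[ok] <- pchisq(stat[ok], df = 1, lower.tail = FALSE)
  p
}

#' Arrest test on matched position records
#'
#' Spec-level wrapper of [stop_rate_test()] for two position records (rows of
#' [tabulate_arrests()] output) at the same exon and position.
#'
#' @param sample,control One-row position records with `exon_id`, `position`,
#'   `n_arrest`, `n_through`.
#' @return Scalar p-value.
#' @export
arrest_test <- function(sample, control) {
  if (sample$exon_id != control$exon_id || sample$position != control$position)
    stop("sample and control records are at different positions")
  stop_rate_test(sample$n_arrest, sample$n_through,
                 control$n_arrest, control$n_through)
}

#' Per-position stop rate difference across replicates
#'
#' Joins per-replicate arrest tables with the merged-control table on
#' (exon, position). Each replicate with data at a position is tested against
#' the control ([stop_rate_test()]); a replicate counts as significant iff
#' p < `alpha` AND its stop rate exceeds the control's. A position is
#' `significant` when at least `min_reps` replicates count. The SRD is the
#' mean of the available replicate stop rates minus the control stop rate.
#' Positions with no control data are computed against a control rate of 0 and
#' flagged (`control_missing`).
#'
#' @param rep_stats List of per-replicate tables from [arrest_counts()].
#' @param control_stats Merged-control table from [arrest_counts()] (pool the
#'   SMInput read sets before tabulating).
#' @param alpha Per-position significance level (default 0.05; no
#'   multiple-testing correction, mirroring the windowed exon score's role as
#'   the specificity mechanism).
#' @param min_reps Replicates required for a significant position (default 2).
#' @return `data.table` with `exon_id`, `position`, per-replicate `rate_i` and
#'   `p_i`, `control_rate`, `n_significant_replicates`, `srd`, `significant`,
#'   `control_missing`.
#' @export
srd_position_table <- function(rep_stats, control_stats, alpha = 0.05,
                               min_reps = 2L) {
  stopifnot(length(rep_stats) >= 1, alpha > 0, alpha < 1)
  nr <- length(rep_stats)
  tabs <- lapply(seq_len(nr), function(i) {
    d <- rep_stats[[i]][, .(exon_id, position, n_arrest, n_through)]
    setnames(d, c("n_arrest", "n_through"),
             c(sprintf("a_%d", i), sprintf("t_%d", i)))
    d
  })
  merged <- Reduce(function(x, y) merge(x, y, by = c("exon_id", "position"),
                                        all = TRUE), tabs)
  ctrl <- control_stats[, .(exon_id, position, a_c = n_arrest, t_c = n_through)]
  merged <- merge(merged, ctrl, by = c("exon_id", "position"), all.x = TRUE)
  merged[, control_missing := is.na(a_c)]
  merged[is.na(a_c), c("a_c", "t_c") := list(0L, 0L)]
  merged[, control_rate := ifelse(a_c + t_c > 0, a_c / (a_c + t_c), 0)]
  rate_mat <- matrix(NA_real_, nrow(merged), nr)
  sig_mat <- matrix(FALSE, nrow(merged), nr)
  for (i in seq_len(nr)) {
    a <- merged[[sprintf("a_%d", i)]]
    t <- merged[[sprintf("t_%d", i)]]
    have <- !is.na(a)
    rate <- ifelse(have & (a + t) > 0, a / (a + t), NA_real_)
    p <- rep(NA_real_, nrow(merged))
    p[have] <- stop_rate_test(a[have], t[have],
                              merged$a_c[have], merged$t_c[have])
    rate_mat[, i] <- rate
    sig_mat[, i] <- have & !is.na(p) & p < alpha &
      !is.na(rate) & rate > merged$control_rate
    merged[, (sprintf("rate_%d", i)) := rate]
    merged[, (sprintf("p_%d", i)) := p]
  }
  merged[, n_significant_replicates := rowSums(sig_mat)]
  merged[, srd := rowMeans(rate_mat, na.rm = TRUE) - control_rate]
  merged[, significant := n_significant_replicates >= min_reps]
  drop <- c(sprintf("a_%d", seq_len(nr)), sprintf("t_%d", seq_len(nr)),
            "a_c", "t_c")
  merged[, (drop) := NULL]
  setorder(merged, exon_id, position)
  merged[]
}

#' Windowed exon-level SRD score
#'
#' Averages the SRD over the significant positions inside the detection window
#' (default `[-32, -23]`, the canonical EJC region) of each exon. An exon is
#' `detected` when it has at least one significant window position and a
#' positive score.
#'
#' @param positions Output of [srd_position_table()] (any number of exons).
#' @param window Inclusive relative interval (default `c(-32, -23)`).
#' @return `data.table` with `exon_id`, `n_significant_positions`, `srd_score`
#'   (`NA` when no significant window position), `detected`.
#' @export
exon_srd <- function(positions, window = c(-32L, -23L)) {
  window <- check_window(window)
  win <- positions[position >= window[1] & position <= window[2]]
  sc <- win[significant == TRUE,
            .(n_significant_positions = .N, srd_score = mean(srd)),
            by = exon_id]
  all_ids <- unique(positions$exon_id)
  out <- merge(data.table(exon_id = all_ids), sc, by = "exon_id", all.x = TRUE)
  out[is.na(n_significant_positions), n_significant_positions := 0L]
  out[, detected := n_significant_positions >= 1L & !is.na(srd_score) &
        srd_score > 0]
  setorder(out, exon_id)
  out[]
}

#' SRD detection over a full experiment
#'
#' End-to-end driver: tabulates arrests per replicate, pools the SMInput
#' controls into a single merged control, computes the per-position SRD table
#' and the windowed per-exon scores, and joins exon annotation. Exons shorter
#' than the window's far bound are evaluated on the truncated window and
#' flagged `window_truncated`.
#'
#' @param eclip_reps List of eCLIP replicate read tables.
#' @param sminputs List of SMInput read tables (pooled into the control).
#' @param exons Exon table.
#' @param window Detection window (default `c(-32, -23)`).
#' @param alpha,min_reps See [srd_position_table()].
#' @return List with `positions` (per-position SRD table) and `exons`
#'   (per-exon: `exon_id`, `cls`, `length`, `n_significant_positions`,
#'   `srd_score`, `detected`, `window_truncated`).
#' @export
srd_detect <- function(eclip_reps, sminputs, exons, window = c(-32L, -23L),
                       alpha = 0.05, min_reps = 2L) {
  window <- check_window(window)
  rep_stats <- lapply(eclip_reps, arrest_counts, exons = exons)
  control <- arrest_counts(rbindlist(sminputs), exons)
  positions <- srd_position_table(rep_stats, control, alpha = alpha,
                                  min_reps = min_reps)
  scores <- exon_srd(positions, window)
  ann <- data.table(exon_id = exons$exon_id, cls = exons$cls,
                    length = exons$end - exons$start)
  out <- merge(ann, scores, by = "exon_id", all.x = TRUE)
  out[is.na(n_significant_positions), n_significant_positions := 0L]
  out[is.na(detected), detected := FALSE]
  out[, window_truncated := length < abs(window[1])]
  setorder(out, exon_id)
  list(positions = positions, exons = out[],
       params = list(window = window, alpha = alpha, min_reps = min_reps))
}

#' Overlap of secondary-window detections with the canonical window
#'
#' Fraction of exons detected in the secondary window (default `[-22, -13]`,
#' ten positions around -18, requiring significance in all replicates) that
#' are also detected in the canonical `[-32, -23]` window under the same
#' all-replicate rule.
#'
#' @param detected_secondary,detected_primary Character vectors of detected
#'   exon ids (or per-exon tables with `exon_id` and `detected`).
#' @return Fraction in `[0, 1]`, or `NA` when the secondary set is empty.
#' @export
secondary_window_overlap <- function(detected_secondary, detected_primary) {
  as_set <- function(x) {
    if (is.data.frame(x)) x$exon_id[x$detected] else as.character(x)
  }
  a <- unique(as_set(detected_secondary))
  b <- unique(as_set(detected_primary))
  if (length(a) == 0) {
    message("secondary-window detection set is empty; overlap undefined")
    return(NA_real_)
  }
  length(intersect(a, b)) / length(a)
}
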