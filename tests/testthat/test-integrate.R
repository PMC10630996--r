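test_that("RPKM follows its definition exactly", {
  # 100 reads on a 2 kb exon in a 10 M read library: 100 / 2 / 10 = 5
  expect_equal(rpkm(100, 2000, 1e7), 5)
  expect_equal(rpkm(0, 500, 1e6), 0)
  expect_equal(rpkm(c(10, 20), c(1000, 1000), 1e6), c(10, 20))
  expect_error(rpkm(10, 0, 1e6))
})

test_that("expression deciles are equal-count with stable tie breaking", {
  ids <- sprintf("g%02d:1", 1:100)
  vals <- c(5, 95, runif(98, 10, 90))
  bins <- expression_bins(data.frame(exon_id = ids, rpkm = vals), k = 10L)
  expect_equal(as.vector(table(bins$decile)), rep(10L, 10))
  expect_equal(bins[bins$exon_id == ids[1], ]$decile, 1L)   # rpkm 5: lowest
  expect_equal(bins[bins$exon_id == ids[2], ]$decile, 10L)  # rpkm 95: highest

  # monotone: a higher rpkm can never land in a lower decile
  o <- bins[order(bins$rpkm), ]
  expect_true(all(diff(o$decile) >= 0))

  # ties are broken by exon_id, deterministically
  tied <- expression_bins(data.frame(exon_id = c("b", "a", "d", "c"),
                                     rpkm = rep(1, 4)), k = 2L)
  expect_equal(tied[tied$exon_id %in% c("a", "b"), sort(decile)], c(1L, 1L))
  expect_equal(tied[tied$exon_id %in% c("c", "d"), sort(decile)], c(2L, 2L))

  # bin sizes differ by at most one when n is not a multiple of k
  b2 <- expression_bins(data.frame(exon_id = sprintf("e%02d", 1:23),
                                   rpkm = runif(23)), k = 10L)
  sizes <- as.vector(table(b2$decile))
  expect_lte(diff(range(sizes)), 1L)
  expect_error(expression_bins(data.frame(exon_id = "e1", rpkm = 1), k = 10L),
               "only 1 exons")
})

test_that("detection rates by stratum count what they claim", {
  calls <- data.frame(exon_id = sprintf("e%d", 1:6),
                      detected = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
                      cls = c("internal", "internal", "internal",
                              "last", "last", "first"))
  strata <- setNames(c(1, 1, 2, 2, 1, 2), calls$exon_id)
  r <- detection_rate_by_stratum(calls, strata)
  expect_equal(r[r$stratum == 1, ]$rate, 2 / 3)
  expect_equal(r[r$stratum == 2, ]$rate, 1 / 3)
  r2 <- detection_rate_by_stratum(calls, strata, exclude_cls = c("last"))
  expect_equal(r2[r2$stratum == 1, ]$n, 2L)
  expect_equal(r2[r2$stratum == 2, ]$rate, 0)  # e3, e6 both undetected
  # exons missing from the strata map are dropped, not miscounted
  r3 <- detection_rate_by_stratum(calls, strata[1:4])
  expect_equal(sum(r3$n), 4L)
})

test_that("combined calls partition the exon universe and conserve counts", {
  e <- setNames(c(TRUE, TRUE, FALSE, FALSE, TRUE), sprintf("e%d", 1:5))
  p <- setNames(c(TRUE, FALSE, TRUE, FALSE, TRUE), sprintf("e%d", 1:5))
  cc <- combine_calls(e, p, expressed_both = sprintf("e%d", 1:4))
  lab <- setNames(as.character(cc$combined), cc$exon_id)
  expect_equal(lab[["e1"]], "both")
  expect_equal(lab[["e2"]], "one")
  expect_equal(lab[["e3"]], "one")
  expect_equal(lab[["e4"]], "neither")
  expect_equal(lab[["e5"]], "excluded")
  expect_equal(sum(table(cc$combined)), 5L)
  # the union is at least as large as either single method, never larger
  # than their sum
  n_union <- sum(cc$union_detected)
  expect_gte(n_union, max(sum(e), sum(p)))
  expect_lte(n_union, sum(e) + sum(p))
})

test_that("combine_calls accepts score tables with detected/loaded columns", {
  ec <- data.frame(exon_id = c("e1", "e2"), detected = c(TRUE, FALSE))
  ip <- data.frame(exon_id = c("e1", "e2"), loaded = c(FALSE, FALSE))
  cc <- combine_calls(ec, ip, expressed_both = c("e1", "e2"))
  expect_equal(as.character(cc$combined), c("one", "neither"))
})

mk_peaks <- function(start, end, strand = "+", chrom = "chr1") {
  data.frame(chrom = rep_len(chrom, length(start)),
             start = as.integer(start), end = as.integer(end),
             strand = rep_len(strand, length(start)))
}

test_that("peak-set Jaccard matches its worked example", {
  # A has 3 peaks, B has 4; with 5 nt slop exactly 2 of A's peaks touch B
  a <- mk_peaks(c(100, 500, 900), c(110, 510, 910))
  b <- mk_peaks(c(112, 490, 2000, 3000), c(120, 498, 2010, 3010))
  j <- jaccard_peaks(a, b, slop = 5L)
  expect_equal(j$intersection, 2L)
  expect_equal(j$union, 5L)
  expect_equal(j$jaccard, 2 / 5)
})

test_that("Jaccard identities and edge cases hold", {
  a <- mk_peaks(c(10, 200), c(20, 210), strand = c("+", "-"))
  self <- jaccard_peaks(a, a)
  expect_equal(self$jaccard, 1)
  # disjoint far-apart sets
  b <- mk_peaks(5000, 5010)
  expect_equal(jaccard_peaks(a, b)$jaccard, 0)
  # strand-aware: same interval on the opposite strand does not overlap
  aplus <- mk_peaks(100, 110, "+")
  aminus <- mk_peaks(100, 110, "-")
  expect_equal(jaccard_peaks(aplus, aminus)$jaccard, 0)
  # slop bridges a gap of up to 2 * slop
  c1 <- mk_peaks(100, 110)
  c2 <- mk_peaks(119, 130)
  expect_equal(jaccard_peaks(c1, c2, slop = 5L)$jaccard, 1)
  expect_equal(jaccard_peaks(c1, c2, slop = 4L)$jaccard, 0)
  # empty input conventions
  expect_equal(jaccard_peaks(mk_peaks(integer(0), integer(0)), c1)$jaccard, 0)
  expect_true(suppressMessages(is.na(
    jaccard_peaks(mk_peaks(integer(0), integer(0)),
                  mk_peaks(integer(0), integer(0)))$jaccard)))
})

test_that("expressed-in-both genes require reads in both control assays", {
  exons <- rbind(toy_exon(0, 100, "+", id = "gA:1", gene = "gA"),
                 toy_exon(300, 400, "+", id = "gB:1", gene = "gB"),
                 toy_exon(600, 700, "+", id = "gC:1", gene = "gC"))
  rna <- rbind(rel_reads(exons[1], -50L, -30L),
               rel_reads(exons[2], -50L, -30L))
  smi <- rbind(rel_reads(exons[1], -40L, -20L),
               rel_reads(exons[3], -40L, -20L))
  expect_equal(expressed_genes(exons, rna, smi), "gA")
})
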