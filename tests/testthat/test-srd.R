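test_that("arrest tabulation counts stops and read-through per position", {
  ex <- toy_exon(0, 40, "+", id = "g1:1")
  reads <- mk_reads(c(10, 10, 12), c(30, 30, 32))
  tab <- tabulate_arrests(reads, ex)
  at <- function(p) tab[tab$position == p, ]
  expect_equal(at(-30)$n_arrest, 2L)       # rel(10) = 10 - 40
  expect_equal(at(-30)$n_through, 0L)
  expect_equal(at(-30)$stop_rate, 1)
  expect_equal(at(-28)$n_arrest, 1L)       # rel(12)
  expect_equal(at(-28)$n_through, 2L)
  expect_equal(at(-28)$stop_rate, 1 / 3)
})

test_that("a single read arrests at its 5' end and reads through downstream", {
  ex <- toy_exon(0, 60, "-", id = "g1:1")
  tab <- tabulate_arrests(rel_reads(ex, -20L, -6L), ex)
  expect_equal(tab[tab$position == -20, ]$stop_rate, 1)
  dn <- tab[tab$position > -20, ]
  expect_equal(nrow(dn), 14)
  expect_true(all(dn$stop_rate == 0))
  expect_true(all(dn$n_through == 1L))
})

test_that("tabulation matches the brute-force (read, position) loop", {
  set.seed(77)
  for (rep in 1:25) {
    strand <- sample(c("+", "-"), 1)
    len <- sample(40:120, 1)
    ex <- toy_exon(1000, 1000 + len, strand, id = "gR:1")
    n <- sample(5:30, 1)
    r5 <- -sample.int(len, n, replace = TRUE)
    r3 <- pmin(r5 + sample(5:40, n, replace = TRUE), -1L)
    reads <- do.call(rbind, lapply(seq_len(n), function(i)
      rel_reads(ex, r5[i], r3[i])))
    got <- as.data.frame(tabulate_arrests(reads, ex))
    want <- brute_tabulate(reads, ex)
    expect_equal(got$position, want$position)
    expect_equal(got$n_arrest, want$n_arrest)
    expect_equal(got$n_through, want$n_through)
  }
})

test_that("the arrest chi-square matches its worked example and degenerate rules", {
  # sample 10/90 vs control 2/98: chi-square 5.674, p ~ 0.0172
  p <- stop_rate_test(10, 90, 2, 98)
  expect_equal(p, 0.01722, tolerance = 1e-3)
  expect_equal(p, oracle_chisq_p(10, 90, 2, 98), tolerance = 1e-12)
  expect_equal(stop_rate_test(5, 95, 5, 95), 1)    # identical rates
  expect_equal(stop_rate_test(0, 0, 2, 98), 1)     # zero sample marginal
  expect_equal(stop_rate_test(3, 97, 0, 0), 1)
  expect_equal(stop_rate_test(0, 100, 0, 50), 1)   # zero arrest column
})

test_that("arrest_test guards against mismatched positions", {
  s <- data.frame(exon_id = "e1", position = -27L, n_arrest = 4L, n_through = 6L)
  ctl <- data.frame(exon_id = "e1", position = -26L, n_arrest = 1L, n_through = 9L)
  expect_error(arrest_test(s, ctl), "different positions")
  ctl$position <- -27L
  expect_equal(arrest_test(s, ctl), oracle_chisq_p(4, 6, 1, 9), tolerance = 1e-12)
})

test_that("more sample arrests never weaken significance while the rate gate holds", {
  t_s <- 80L; a_c <- 5L; t_c <- 95L
  prev <- 1
  for (a_s in 6:60) {
    p <- stop_rate_test(a_s, t_s, a_c, t_c)
    if (a_s / (a_s + t_s) > a_c / (a_c + t_c)) {
      expect_lte(p, prev + 1e-12)
      prev <- p
    }
  }
})

mk_pos_stats <- function(exon, position, a, t) {
  data.table::data.table(exon_id = exon, position = position,
                         n_arrest = as.integer(a), n_through = as.integer(t),
                         stop_rate = a / (a + t))
}

test_that("per-position SRD integrates replicates with the one-sided gate", {
  reps <- list(mk_pos_stats("e1", -27L, 30, 70),
               mk_pos_stats("e1", -27L, 40, 60),
               mk_pos_stats("e1", -27L, 50, 50))
  ctl <- mk_pos_stats("e1", -27L, 100, 900)
  pt <- srd_position_table(reps, ctl)
  expect_equal(pt$srd, 0.4 - 0.1)
  expect_equal(pt$n_significant_replicates, 3)
  expect_true(pt$significant)

  # control rate above the replicates: never significant, whatever the p
  ctl2 <- mk_pos_stats("e1", -27L, 500, 500)
  pt2 <- srd_position_table(reps, ctl2)
  expect_equal(pt2$srd, -0.1)
  expect_false(pt2$significant)
  expect_equal(pt2$n_significant_replicates, 0)

  # missing control data: computed against rate 0 and flagged
  pt3 <- srd_position_table(reps, mk_pos_stats("e1", -5L, 1, 9))
  expect_true(pt3[pt3$position == -27, ]$control_missing)
  expect_equal(pt3[pt3$position == -27, ]$srd, 0.4)
})

test_that("SRD averages over the replicates that have data", {
  reps <- list(mk_pos_stats("e1", -27L, 30, 70),
               mk_pos_stats("e1", -26L, 10, 90),
               mk_pos_stats("e1", -27L, 50, 50))
  ctl <- mk_pos_stats("e1", -27L, 100, 900)
  pt <- srd_position_table(reps, ctl)
  expect_equal(pt[pt$position == -27, ]$srd, 0.4 - 0.1)
})

mk_srd_pos <- function(exon, position, srd, significant) {
  data.table::data.table(exon_id = exon, position = as.integer(position),
                         srd = srd, significant = significant)
}

test_that("exon score averages significant window positions only", {
  pos <- rbind(mk_srd_pos("e1", c(-27, -25), c(0.4, 0.2), TRUE),
               mk_srd_pos("e1", -40, 0.9, FALSE))
  sc <- exon_srd(pos)
  expect_equal(sc$srd_score, 0.3)
  expect_true(sc$detected)
  expect_equal(sc$n_significant_positions, 2L)

  # significant position outside the window: no score, not detected
  sc2 <- exon_srd(mk_srd_pos("e2", -22, 0.5, TRUE))
  expect_true(is.na(sc2$srd_score))
  expect_false(sc2$detected)

  # the mean includes negative members
  sc3 <- exon_srd(rbind(mk_srd_pos("e3", -27, 0.4, TRUE),
                        mk_srd_pos("e3", -24, -0.1, TRUE)))
  expect_equal(sc3$srd_score, 0.15)
  expect_true(sc3$detected)
})

test_that("significant synthetic positions are strongly enriched in the canonical window", {
  # readthrough pushes some genuine arrests just upstream of the footprint
  # and sparse positions contribute a thin noise tail, so containment is not
  # the property; a strong per-position density excess in the window is
  sim <- small_sim()
  res <- srd_detect(sim$reads$eclip, sim$reads$sminput, sim$exons)
  pos <- as.data.frame(res$positions)
  sig <- pos[pos$significant, ]
  tab <- table(sig$position)
  mode_pos <- as.integer(names(tab)[which.max(tab)])
  expect_gte(mode_pos, -32L)
  expect_lte(mode_pos, -23L)
  in_win <- sig$position >= -32 & sig$position <= -23
  dens_in <- sum(in_win) / 10                    # window spans 10 positions
  dens_out <- sum(!in_win & sig$position >= -100) / 90
  expect_gte(dens_in / dens_out, 10)
})

test_that("secondary-window detections are a subset question with sane edge cases", {
  expect_equal(secondary_window_overlap(c("e1", "e2"), c("e1", "e2", "e3")), 1)
  expect_equal(secondary_window_overlap(c("e1", "e2"), c("e3", "e4")), 0)
  expect_true(suppressMessages(is.na(
    secondary_window_overlap(character(0), c("e1")))))
})

test_that("the synthetic data produce no secondary -18 window signal", {
  sim <- small_sim()
  det18 <- srd_detect(sim$reads$eclip, sim$reads$sminput, sim$exons,
                      window = c(-22L, -13L), min_reps = 3L)
  expect_lte(mean(det18$exons$detected), 0.01)
})
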