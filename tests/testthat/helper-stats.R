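# statistical checks for qualitative (stochastic) monotone / flat properties:
# a qualitative trend in detection rates is asserted as a significant
# Cochran-Armitage trend in the stated direction with no significant
# adjacent-stratum reversal; flatness as the absence of a significant trend.

trend_p <- function(n_det, n_tot) {
  suppressWarnings(stats::prop.trend.test(n_det, n_tot)$p.value)
}

trend_sign <- function(n_det, n_tot) {
  r <- n_det / n_tot
  sign(stats::cor(seq_along(r), r, method = "spearman"))
}

has_significant_adjacent_decrease <- function(n_det, n_tot, alpha = 0.01) {
  for (i in seq_len(length(n_det) - 1)) {
    r1 <- n_det[i] / n_tot[i]
    r2 <- n_det[i + 1] / n_tot[i + 1]
    if (r2 < r1) {
      m <- matrix(c(n_det[i], n_tot[i] - n_det[i],
                    n_det[i + 1], n_tot[i + 1] - n_det[i + 1]),
                  nrow = 2, byrow = TRUE)
      if (stats::fisher.test(m, alternative = "greater")$p.value < alpha)
        return(TRUE)
    }
  }
  FALSE
}

expect_increasing_rates <- function(n_det, n_tot, alpha = 0.01) {
  expect_lt(trend_p(n_det, n_tot), alpha)
  expect_gt(trend_sign(n_det, n_tot), 0)
  expect_false(has_significant_adjacent_decrease(n_det, n_tot, alpha))
}

expect_flat_rates <- function(n_det, n_tot, alpha = 0.01) {
  expect_gt(trend_p(n_det, n_tot), alpha)
}
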