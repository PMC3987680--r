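mk_class <- function(genes, counts, classes) {
  structure(data.frame(gene_symbol = genes, mirna_count = as.integer(counts),
                       class = factor(classes, levels = c("IC", "PC", "NC")),
                       stringsAsFactors = FALSE),
            class = c("TargetClassification", "data.frame"))
}

test_that("miRNA-count bins assign every gene exactly once", {
  tc <- mk_class(c("A", "B", "C", "D"), c(1, 7, 16, 31),
                 c("PC", "IC", "PC", "NC"))
  s <- bin_by_mirna_count(tc, repressor_only_group = c("R1", "R2"),
                          repressor_only_classes = c("PC", "IC"))
  expect_identical(s$label, c("repressor-only", "1-5", "6-10", "11-15", "16-31"))
  expect_equal(s$n_genes, c(2L, 1L, 1L, 0L, 2L))
  expect_equal(s$n_PC, c(1L, 1L, 0L, 0L, 1L))   # count 16 and 31 in last bin
  expect_equal(sum(s$n_genes), nrow(tc) + 2L)
  expect_error(bin_by_mirna_count(mk_class("X", 40, "PC")), "impossible")
})

test_that("per-bin totals equal a brute-force histogram on the bundle", {
  r <- default_run()
  tc <- r$objects$classification
  s <- r$objects$strat_global
  for (i in seq_len(nrow(s))) {
    rng <- as.integer(strsplit(s$label[i], "-")[[1]])
    if (length(rng) == 1L) rng <- c(rng, rng)
    inbin <- tc$mirna_count >= rng[1] & tc$mirna_count <= rng[2]
    expect_equal(s$n_genes[i], sum(inbin))
    expect_equal(s$n_PC[i], sum(inbin & tc$class == "PC"))
  }
  expect_equal(sum(s$n_genes), nrow(tc))
  expect_true(all(s$percent_PC >= 0 & s$percent_PC <= 100, na.rm = TRUE))
})

test_that("trend statistic matches the N*r^2 identity and known degenerate cases", {
  # identical proportions across bins -> no trend
  s0 <- chi_square_trend(c(10, 10, 10), c(100, 100, 100))
  expect_identical(s0$X2, 0)

  # closed form vs score-regression identity, to 1e-10
  n_PC <- c(20, 10, 5); n <- c(40, 40, 40); sc <- c(0, 1, 2)
  res <- chi_square_trend(n_PC, n, sc)
  y <- rep(rep(c(1, 0), 3), c(rbind(n_PC, n - n_PC)))
  x <- rep(sc, n)
  expect_equal(res$X2, sum(n) * stats::cor(x, y)^2, tolerance = 1e-10)
  # and against the stock trend test
  pt <- stats::prop.trend.test(n_PC, n, sc)
  expect_equal(res$X2, unname(pt$statistic), tolerance = 1e-10)
  expect_equal(res$p, pt$p.value, tolerance = 1e-10)

  # affine score transformation leaves the statistic unchanged
  res2 <- chi_square_trend(n_PC, n, 100 + 7 * sc)
  expect_equal(res2$X2, res$X2, tolerance = 1e-10)

  # two bins: equals the 2x2 chi-square without continuity correction
  res3 <- chi_square_trend(c(30, 10), c(50, 50))
  cs <- stats::chisq.test(rbind(c(30, 20), c(10, 40)), correct = FALSE)
  expect_equal(res3$X2, unname(cs$statistic), tolerance = 1e-10)

  # degenerate inputs
  expect_error(chi_square_trend(5, 10), ">= 2 non-empty bins")
  expect_identical(chi_square_trend(c(0, 0), c(10, 10))$X2, 0)
  # one-sided in the direction of decreasing proportions
  resd <- chi_square_trend(n_PC, n, sc, one_sided = "decreasing")
  expect_equal(resd$p, res$p / 2, tolerance = 1e-12)
})

test_that("the planted override gradient produces a strong decreasing trend", {
  r <- default_run()
  s <- r$objects$strat_global
  pop <- s$n_genes > 0
  tr <- chi_square_trend(s$n_PC[pop], s$n_genes[pop], s$score[pop])
  expect_lt(tr$p, 0.001)
  expect_lt(tr$slope_sign, 0)  # percent PC falls as miRNA count rises
})

test_that("log-space hypergeometric tails match exact summation", {
  # entire support -> probability exactly 1
  e1 <- hypergeom_upper_tail(20, 8, 10, max(0, 10 + 8 - 20))
  expect_identical(e1$p, 1)
  # all draws in the category: 1 / C(10,5)
  e2 <- hypergeom_upper_tail(10, 5, 5, 5)
  expect_equal(e2$p, 1 / 252, tolerance = 1e-12)
  expect_error(hypergeom_upper_tail(10, 5, 5, 6), "support")
  expect_error(hypergeom_upper_tail(10, 12, 5, 3), "N")

  # spot sweep against the Pascal-triangle oracle
  rows <- pascal_rows(30)
  for (N in c(7, 18, 30)) {
    for (K in c(2, N %/% 2, N - 1)) {
      for (n in c(1, N %/% 3, N)) {
        lo <- max(0, n + K - N)
        for (k in unique(c(lo, min(n, K), (lo + min(n, K)) %/% 2))) {
          expect_equal(hypergeom_upper_tail(N, K, n, k)$p,
                       oracle_hyper_upper(N, K, n, k, rows),
                       tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("alternative binning schemes change scores, not memberships", {
  tc <- mk_class(sprintf("G%d", 1:8), c(1, 2, 3, 6, 8, 12, 17, 30),
                 rep(c("PC", "IC"), 4))
  s_idx <- bin_by_mirna_count(tc)
  s_mid <- bin_by_mirna_count(tc, score_type = "midpoint")
  expect_identical(s_mid$n_genes, s_idx$n_genes)
  expect_identical(s_mid$n_PC, s_idx$n_PC)
  expect_equal(s_mid$score, c(3, 8, 13, 23.5))  # (1+5)/2, (6+10)/2, ...
  # trend is affine-invariant, so equal-width index vs midpoint scores give
  # different statistics only through non-linear spacing
  expect_true(all(diff(s_mid$score) > 0))

  counts <- c(rep(1, 10), rep(2, 10), rep(7, 10), rep(20, 10))
  edges <- equal_size_bin_edges(counts, 4)
  expect_identical(edges[1], 1L)
  expect_true(all(diff(edges) > 0))
  tc2 <- mk_class(sprintf("H%d", seq_along(counts)), counts,
                  rep("IC", length(counts)))
  s_eq <- bin_by_mirna_count(tc2, bin_edges = edges)
  expect_true(max(s_eq$n_genes) - min(s_eq$n_genes) <= 10)
})

test_that("repressor multiplicity split separates single from multi strata", {
  tc <- mk_class(sprintf("G%d", 1:6), c(2, 3, 7, 2, 3, 7),
                 c("PC", "PC", "IC", "IC", "PC", "NC"))
  rc <- stats::setNames(c(1L, 1L, 1L, 3L, 3L, 3L), tc$gene_symbol)
  sp <- repressor_multiplicity_split(tc, rc, split_edges = c(1L, 2L),
                                     split_max = 5L)
  expect_setequal(names(sp$strata), c("1", "2-5"))
  expect_equal(sum(sp$strata[["1"]]$n_genes), 3L)
  expect_equal(sum(sp$strata[["2-5"]]$n_genes), 3L)

  # all genes single-repressor: multi stratum omitted with a warning
  rc1 <- stats::setNames(rep(1L, 6), tc$gene_symbol)
  expect_warning(sp1 <- repressor_multiplicity_split(tc, rc1,
                                                     split_edges = c(1L, 2L),
                                                     split_max = 5L),
                 "empty")
  expect_identical(names(sp1$strata), "1")

  expect_error(repressor_multiplicity_split(tc, rc[1:3]), "repressor count")
})

test_that("multi-repressor genes override miRNA repression more than single", {
  r <- default_run()
  sp <- r$objects$split
  expect_true(!is.null(sp))
  cmp <- sp$comparison
  both <- !is.na(cmp[["1"]]) & !is.na(cmp[["2-5"]]) &
    sp$strata[["1"]]$n_genes > 10 & sp$strata[["2-5"]]$n_genes > 10
  expect_true(any(both))
  expect_true(all(cmp[["2-5"]][both] >= cmp[["1"]][both]))
})
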