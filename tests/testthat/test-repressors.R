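test_that("repressor selection intersects annotation, direction and targeting", {
  de <- structure(data.frame(
    feature_id = c("ZNF24", "YY1", "SPEN", "UPREG", "NSGENE"),
    mean_normal = 0, mean_cancer = 0, fc = 1, t = 0, p = 0.01,
    q = c(0.01, 0.01, 0.01, 0.01, 0.9),
    direction = factor(c("down", "down", "down", "up", "ns"),
                       levels = c("up", "down", "ns")),
    stringsAsFactors = FALSE), class = c("DETable", "data.frame"))
  sel <- select_repressors(c("ZNF24", "YY1", "SPEN", "UPREG", "NSGENE", "ABSENT"),
                           de, mirna_targets = c("ZNF24", "YY1", "UPREG"))
  expect_setequal(sel$genes, c("ZNF24", "YY1"))   # SPEN down but untargeted
  expect_equal(sel$candidate_count, 6L)
  expect_equal(sel$downregulated_count, 3L)
  expect_equal(sel$mirna_targeted_count, 2L)
  expect_true(sel$candidate_count >= sel$downregulated_count)
  expect_true(sel$downregulated_count >= sel$mirna_targeted_count)
})

test_that("the planted repressor set is recovered from the synthetic bundle", {
  b <- default_bundle()
  r <- default_run()
  sel <- r$objects$repressors
  expect_setequal(sel$genes, b$repressors)
  # decoys fall at the intended stages: 40 candidates, 20 down, 10 targeted
  expect_equal(sel$candidate_count, length(b$go_list))
  expect_true(sel$downregulated_count < sel$candidate_count)
  expect_true(sel$mirna_targeted_count < sel$downregulated_count)
})

test_that("TRANSFAC pairs require regulon membership, DE and miRNA targeting", {
  regulons <- structure(list(ZNF24 = c("VEGFA", "NODEG", "NOTARGET")),
                        class = "RegulonTable")
  de <- structure(data.frame(
    feature_id = c("VEGFA", "NOTARGET", "ZNF24"),
    mean_normal = 0, mean_cancer = 0, fc = 1, t = 0, p = 0.01, q = 0.01,
    direction = factor(c("up", "down", "down"), levels = c("up", "down", "ns")),
    stringsAsFactors = FALSE), class = c("DETable", "data.frame"))
  tp <- transfac_pairs(regulons, "ZNF24", de, mirna_targets = c("VEGFA", "ZNF24"))
  expect_identical(tp$edges$target, "VEGFA")       # NODEG and NOTARGET dropped
  expect_identical(tp$mutual_targets, "VEGFA")
  expect_identical(tp$active_repressors, "ZNF24")
  expect_warning(transfac_pairs(regulons, "ABSENT", de, "VEGFA"), "no selected repressor")
})

test_that("TRANSFAC pairs equal a brute-force triple intersection on the bundle", {
  b <- default_bundle()
  r <- default_run()
  tp <- r$objects$transfac
  de <- r$objects$de_mrna
  sel_pred <- r$objects$predictions[
    r$objects$predictions$mirna_id %in% r$objects$selected_mirnas, ]
  degs <- de$feature_id[de$direction != "ns"]
  targets <- unique(sel_pred$gene_symbol)
  want <- list()
  for (rep in b$repressors) {
    for (g in b$regulons[[rep]]) {
      if (g %in% degs && g %in% targets && g != rep) {
        want[[length(want) + 1L]] <- paste(rep, g)
      }
    }
  }
  expect_setequal(paste(tp$edges$repressor, tp$edges$target), unlist(want))
  # output is contained in the candidate universe
  expect_true(all(tp$mutual_targets %in% intersect(degs, targets)))
})

test_that("directional correlation p-value matches theory and a permutation oracle", {
  expect_equal(pearson_directional_p(0, 10), 0.5)
  expect_equal(pearson_directional_p(-0.8, 10), 0.0027, tolerance = 0.05)
  p0 <- pearson_directional_p(-1, 10)
  expect_identical(as.numeric(p0), 0)
  expect_equal(attr(p0, "boundary"), 1L)
  expect_error(pearson_directional_p(-0.5, 2), "n must be")

  # strictly decreasing in |r| for fixed n, and in n for fixed r < 0
  rs <- seq(-0.1, -0.95, by = -0.05)
  expect_true(all(diff(pearson_directional_p(rs, 10)) < 0))
  ns <- 4:30
  expect_true(all(diff(vapply(ns, function(n) pearson_directional_p(-0.5, n),
                              numeric(1))) < 0))

  # permutation oracle, n = 10: the t transform approximates the exact
  # (sample-dependent, discrete) permutation null well in the body of the
  # distribution and to order of magnitude in the far tail
  set.seed(2024)
  x <- stats::rnorm(10)
  z <- stats::residuals(stats::lm(stats::rnorm(10) ~ x)); z <- z / stats::sd(z)
  B <- 200000L
  perm_p <- function(r_target) {
    y <- r_target * scale(x)[, 1] + sqrt(1 - r_target^2) * z
    r_obs <- stats::cor(x, y)
    perm_r <- vapply(seq_len(B), function(i) stats::cor(x, y[sample.int(10)]),
                     numeric(1))
    c(perm = (1 + sum(perm_r <= r_obs)) / (B + 1),
      t = pearson_directional_p(r_obs, 10))
  }
  mid <- perm_p(-0.5)
  expect_lt(abs(mid["perm"] - mid["t"]) / mid["t"], 0.15)
  far <- perm_p(-0.9)
  expect_lt(abs(log10(far["perm"] / far["t"])), 1.2)
})

test_that("correlation regulon edges use a strict threshold and are scale invariant", {
  set.seed(77)
  n <- 12
  vals <- rbind(R1 = stats::rnorm(n))
  a <- vals["R1", ]
  vals <- rbind(vals,
                T1 = -a + stats::rnorm(n, 0, 0.1),    # strongly anti-correlated
                T2 = stats::rnorm(n))                  # unrelated
  colnames(vals) <- sprintf("S%02d", seq_len(n))
  m <- expr_fixture(vals, 10, 2)
  res <- infer_correlation_regulon(m, "R1", c("T1", "T2"), r_threshold = -0.8)
  expect_identical(res$edges$target, "T1")
  expect_identical(res$non_targets, "T2")
  expect_equal(res$edges$n, 10)

  # strictness: a threshold equal to the achieved r excludes the pair
  r1 <- res$edges$r[1]
  res_eq <- infer_correlation_regulon(m, "R1", c("T1", "T2"), r_threshold = r1)
  expect_false("T1" %in% res_eq$edges$target)
  res_above <- infer_correlation_regulon(m, "R1", c("T1", "T2"),
                                         r_threshold = r1 + 1e-9)
  expect_true("T1" %in% res_above$edges$target)

  # invariance under monotone-linear rescaling of either gene
  m2 <- m
  m2$values["T1", ] <- 3 * m$values["T1", ] + 10
  m2$values["R1", ] <- 0.5 * m$values["R1", ] - 2
  res2 <- infer_correlation_regulon(m2, "R1", c("T1", "T2"), r_threshold = -0.8)
  expect_equal(res2$edges$r, res$edges$r, tolerance = 1e-12)

  # every retained edge beats the threshold p by monotonicity
  expect_true(all(res$edges$p_directional <
                    pearson_directional_p(-0.8, 10)))

  # restricting to prior pairs drops edges outside the allowed set
  res_r <- infer_correlation_regulon(m, "R1", c("T1", "T2"),
                                     allowed_pairs = data.frame(
                                       repressor = "R1", target = "T2"))
  expect_equal(nrow(res_r$edges), 0L)
  expect_setequal(res_r$non_targets, c("T1", "T2"))

  # zero-variance vectors are skipped, not propagated
  m3 <- m
  m3$values["T2", ] <- 4
  expect_message(res3 <- infer_correlation_regulon(m3, "R1", c("T1", "T2")),
                 "zero-variance")
  expect_false("T2" %in% res3$edges$target)
})

test_that("planted anti-correlated regulons are recovered with high precision/recall", {
  b <- default_bundle()
  r <- default_run()
  corr <- r$objects$correlation
  de <- r$objects$de_mrna
  sel_pred <- r$objects$predictions[
    r$objects$predictions$mirna_id %in% r$objects$selected_mirnas, ]
  candidates <- intersect(de$feature_id[de$direction != "ns"],
                          unique(sel_pred$gene_symbol))
  truth <- b$corr_pairs[b$corr_pairs$target %in% candidates, ]
  truth_keys <- paste(truth$repressor, truth$target)
  got_keys <- paste(corr$edges$repressor, corr$edges$target)
  tp <- sum(got_keys %in% truth_keys)
  expect_gte(tp / length(got_keys), 0.9)   # precision
  expect_gte(tp / length(truth_keys), 0.9) # recall
})
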