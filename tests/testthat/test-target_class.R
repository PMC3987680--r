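make_de <- function(genes, direction) {
  structure(data.frame(
    feature_id = genes, mean_normal = 0, mean_cancer = 0, fc = 1, t = 0,
    p = 0.5, q = ifelse(direction == "ns", 0.9, 0.01),
    direction = factor(direction, levels = c("up", "down", "ns")),
    stringsAsFactors = FALSE), class = c("DETable", "data.frame"))
}

test_that("targets are classified IC/PC/NC by their expression response", {
  pred <- data.frame(
    mirna_id = c(sprintf("hsa-miR-%02d", 1:11), "hsa-miR-01", "hsa-miR-02",
                 "hsa-miR-03", "hsa-miR-99"),
    gene_symbol = c(rep("VEGFA", 11), "DOWNG", "NSG", "UNMEASURED", "VEGFA"),
    score = -0.5, stringsAsFactors = FALSE)
  de <- make_de(c("VEGFA", "DOWNG", "NSG", "OTHER"), c("up", "down", "ns", "up"))
  sel <- sprintf("hsa-miR-%02d", 1:11)   # miR-99 not selected -> ignored
  tc <- classify_targets(pred, de, sel)
  expect_identical(as.character(tc$class[tc$gene_symbol == "VEGFA"]), "PC")
  expect_equal(tc$mirna_count[tc$gene_symbol == "VEGFA"], 11L)
  expect_identical(as.character(tc$class[tc$gene_symbol == "DOWNG"]), "IC")
  expect_identical(as.character(tc$class[tc$gene_symbol == "NSG"]), "NC")
  expect_false("UNMEASURED" %in% tc$gene_symbol)
  expect_equal(attr(tc, "n_unmeasured"), 1L)
  # partition: every classified gene has exactly one class
  expect_equal(sum(table(tc$class)), nrow(tc))
})

test_that("classification counts match an independent join-and-count oracle", {
  b <- default_bundle()
  r <- default_run()
  tc <- r$objects$classification
  de <- r$objects$de_mrna
  pred <- r$objects$predictions
  sel <- r$objects$selected_mirnas
  # oracle: explicit loop over genes, no shared code with classify_targets
  pred_sel <- pred[pred$mirna_id %in% sel, ]
  genes <- intersect(unique(pred_sel$gene_symbol), de$feature_id)
  counts <- c(IC = 0L, PC = 0L, NC = 0L)
  for (g in genes) {
    d <- as.character(de$direction[de$feature_id == g])
    cl <- if (d == "down") "IC" else if (d == "up") "PC" else "NC"
    counts[cl] <- counts[cl] + 1L
  }
  expect_equal(sum(tc$class == "IC"), unname(counts["IC"]))
  expect_equal(sum(tc$class == "PC"), unname(counts["PC"]))
  expect_equal(sum(tc$class == "NC"), unname(counts["NC"]))
  # per-gene miRNA counts equal the number of distinct selected miRNAs
  set.seed(1)
  g1 <- sample(genes, 25)
  for (g in g1) {
    expect_equal(tc$mirna_count[tc$gene_symbol == g],
                 length(unique(pred_sel$mirna_id[pred_sel$gene_symbol == g])))
  }
})

test_that("summary rows reproduce count/percentage tables", {
  s <- summarize_classification(c(IC = 3110L, PC = 1719L, NC = 8015L))
  expect_equal(unlist(s[c("pct_IC", "pct_PC", "pct_NC", "total")]),
               c(pct_IC = 24L, pct_PC = 13L, pct_NC = 62L, total = 12844L))
  s2 <- summarize_classification(c(IC = 1L, PC = 0L, NC = 0L))
  expect_equal(unlist(s2[c("pct_IC", "pct_PC", "pct_NC")]),
               c(pct_IC = 100L, pct_PC = 0L, pct_NC = 0L))
  s3 <- summarize_classification(c(IC = 1519L, PC = 779L, NC = 2681L))
  expect_equal(unlist(s3[c("pct_IC", "pct_PC", "pct_NC", "total")]),
               c(pct_IC = 31L, pct_PC = 16L, pct_NC = 54L, total = 4979L))
  expect_error(summarize_classification(c(IC = 0L, PC = 0L, NC = 0L)), "empty")
})

test_that("label swap exchanges IC and PC exactly, NC unchanged", {
  b <- default_bundle()
  mrna_f <- present_filter(b$mrna, 0.60)
  de <- differential_expression(mrna_f, n_permutations = 300, seed = 42L)
  m_swap <- mrna_f
  m_swap$group_of <- ifelse(mrna_f$group_of == "normal", "cancer", "normal")
  de_swap <- differential_expression(m_swap, n_permutations = 300, seed = 42L)
  pred <- read_target_predictions(b$paths$predictions, score_cutoff = -0.2)
  tc <- classify_targets(pred, de, b$mirna_up)
  tc_swap <- classify_targets(pred, de_swap, b$mirna_up)
  expect_equal(sum(tc_swap$class == "IC"), sum(tc$class == "PC"))
  expect_equal(sum(tc_swap$class == "PC"), sum(tc$class == "IC"))
  expect_equal(sum(tc_swap$class == "NC"), sum(tc$class == "NC"))
})

test_that("relaxing the FDR threshold only moves genes out of NC", {
  b <- default_bundle()
  mrna_f <- present_filter(b$mrna, 0.60)
  de_tight <- differential_expression(mrna_f, n_permutations = 300, seed = 42L,
                                      fdr_threshold = 0.02)
  de_loose <- differential_expression(mrna_f, n_permutations = 300, seed = 42L,
                                      fdr_threshold = 0.2)
  pred <- read_target_predictions(b$paths$predictions, score_cutoff = -0.2)
  tc_tight <- classify_targets(pred, de_tight, b$mirna_up)
  tc_loose <- classify_targets(pred, de_loose, b$mirna_up)
  m <- match(tc_tight$gene_symbol, tc_loose$gene_symbol)
  moved <- as.character(tc_tight$class) != as.character(tc_loose$class[m])
  # every change starts from NC under the tight threshold
  expect_true(all(tc_tight$class[moved] == "NC"))
  # and no gene crosses between IC and PC
  expect_false(any(tc_tight$class %in% c("IC", "PC") &
                     as.character(tc_loose$class[m]) %in% c("IC", "PC") & moved))
})

test_that("repressive potential separates miRNA targets from background", {
  # hand fixture: one miRNA whose 4 DEG targets are all down
  pred <- data.frame(mirna_id = "hsa-miR-x",
                     gene_symbol = c("A", "B", "C", "D"),
                     score = -0.5, stringsAsFactors = FALSE)
  de <- make_de(c("A", "B", "C", "D", "E", "F"),
                c("down", "down", "down", "down", "up", "down"))
  rp <- repressive_potential(pred, de, "hsa-miR-x")
  expect_equal(rp$per_mirna$frac_down, 1.0)
  expect_equal(rp$background_frac_down, 0.5)   # E up, F down

  # a miRNA with no DEG target reports a missing fraction
  pred2 <- rbind(pred, data.frame(mirna_id = "hsa-miR-y", gene_symbol = "ZZZ",
                                  score = -0.5))
  expect_warning(rp2 <- repressive_potential(pred2, de, c("hsa-miR-x", "hsa-miR-y")),
                 "no DEG targets")
  expect_true(is.na(rp2$per_mirna$frac_down[rp2$per_mirna$mirna_id == "hsa-miR-y"]))

  # planted strong repression, weak override: every per-miRNA fraction
  # exceeds the background fraction
  r <- default_run()
  rp3 <- r$objects$repressive
  expect_true(all(rp3$per_mirna$frac_down > rp3$background_frac_down,
                  na.rm = TRUE))
  expect_gt(rp3$mean_frac_down, 0.65)
})
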