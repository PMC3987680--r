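#!/usr/bin/env Rscript
# Stage 5: degree-stratified trends and enrichment.
#
# Mutual targets are binned by the number of selected miRNAs targeting them
# (1-5, 6-10, 11-15, 16-31, plus a repressor-only group); the percentage of
# upregulated (PC) targets per bin is tested for trend with the 1-df
# Cochran-Armitage statistic. The same analysis runs globally over all
# classified targets, and within single- vs multi-repressor strata. Two
# log-space hypergeometric enrichments close the argument: downregulated
# genes among miRNA targets, and upregulated genes among
# correlation-inferred repressor targets.

suppressPackageStartupMessages(library(tomnet))

out <- "results/analysis"
de_mrna <- read_de_table(file.path(out, "de_mrna.tsv"))
tc <- read.delim(file.path(out, "target_classification.tsv"))
tc$class <- factor(tc$class, levels = c("IC", "PC", "NC"))
class(tc) <- c("TargetClassification", "data.frame")
mutual <- readLines(file.path(out, "mutual_targets.txt"))
tp_edges <- read.delim(file.path(out, "transfac_edges.tsv"))
corr_edges <- read.delim(file.path(out, "correlation_edges.tsv"))

rep_only <- readLines(file.path(out, "repressor_only.txt"))
rep_only <- rep_only[rep_only %in% de_mrna$feature_id]
ro_dir <- as.character(de_mrna$direction[match(rep_only, de_mrna$feature_id)])
ro_cls <- ifelse(ro_dir == "up", "PC", ifelse(ro_dir == "down", "IC", "NC"))

tc_mutual <- tc[tc$gene_symbol %in% mutual, ]
strat <- bin_by_mirna_count(tc_mutual, repressor_only_group = rep_only,
                            repressor_only_classes = ro_cls)
tr <- chi_square_trend(strat$n_PC, strat$n_genes, strat$score)
cat("motif-level stratification (mutual targets):\n")
print(as.data.frame(strat), row.names = FALSE)
cat(sprintf("trend: X2 = %.2f (1 df), p = %.3g, direction %s\n\n", tr$X2, tr$p,
            if (tr$slope_sign < 0) "decreasing" else "increasing"))

strat_g <- bin_by_mirna_count(tc)
tr_g <- chi_square_trend(strat_g$n_PC, strat_g$n_genes, strat_g$score)
cat("global stratification (all classified targets):\n")
print(as.data.frame(strat_g), row.names = FALSE)
cat(sprintf("trend: X2 = %.2f (1 df), p = %.3g\n\n", tr_g$X2, tr_g$p))

rep_counts <- table(tp_edges$target)
split <- repressor_multiplicity_split(
  tc_mutual, setNames(as.integer(rep_counts), names(rep_counts)))
cat("percent PC by miRNA bin, single vs multiple repressors:\n")
print(split$comparison, row.names = FALSE)

deg <- de_mrna[de_mrna$direction != "ns", ]
is_target <- deg$feature_id %in% tc$gene_symbol
e1 <- hypergeom_upper_tail(N = nrow(deg), K = sum(deg$direction == "down"),
                           n = sum(is_target),
                           k = sum(is_target & deg$direction == "down"))
cand <- deg[is_target, ]
is_rt <- cand$feature_id %in% unique(corr_edges$target)
e2 <- hypergeom_upper_tail(N = nrow(cand), K = sum(cand$direction == "up"),
                           n = sum(is_rt),
                           k = sum(is_rt & cand$direction == "up"))
cat("\nenrichment, downregulated genes among miRNA targets: ")
print(e1)
cat("enrichment, upregulated genes among repressor targets: ")
print(e2)

write.table(as.data.frame(strat), file.path(out, "stratified_motif.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(as.data.frame(strat_g), file.path(out, "stratified_global.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(split$comparison, file.path(out, "repressor_split.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
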