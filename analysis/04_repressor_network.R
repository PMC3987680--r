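#!/usr/bin/env Rscript
# Stage 4: repressor selection and the override feed-forward network.
#
# Repressors = GO-annotated candidates that are significantly downregulated
# AND predicted targets of >=1 selected miRNA. Two repressor->target edge
# layers are built: TRANSFAC-style regulons from the GMT file (restricted
# to DEGs), and a co-expression layer requiring Pearson r < -0.8 across the
# ten normal samples. The miRNA and TRANSFAC layers are joined into the
# override network; a worked per-gene query shows one full motif.

suppressPackageStartupMessages(library(tomnet))

ws <- "results/analysis/workspace"
out <- "results/analysis"
de_mrna <- read_de_table(file.path(out, "de_mrna.tsv"))
selected <- readLines(file.path(out, "selected_mirnas.txt"))
predictions <- read_target_predictions(file.path(ws, "predictions.tsv"),
                                       score_cutoff = -0.2)
tc <- read.delim(file.path(out, "target_classification.tsv"))
tc$class <- factor(tc$class, levels = c("IC", "PC", "NC"))
class(tc) <- c("TargetClassification", "data.frame")

go_list <- read_gene_list(file.path(ws, "repressor_candidates.txt"))
sel_pred <- predictions[predictions$mirna_id %in% selected, ]
mirna_targets <- unique(sel_pred$gene_symbol)
repsel <- select_repressors(go_list, de_mrna, mirna_targets)
print(repsel)

regulons <- read_gmt(file.path(ws, "regulons.gmt"))
tp <- transfac_pairs(regulons, repsel$genes, de_mrna, mirna_targets)
cat(sprintf("TRANSFAC layer: %d repressors with regulons, %d edges, %d mutual targets\n",
            length(tp$active_repressors), nrow(tp$edges),
            length(tp$mutual_targets)))

groups <- read.delim(file.path(ws, "sample_groups.tsv"))
gm <- setNames(groups$group, groups$sample_id)
mrna_f <- present_filter(
  read_expression_matrix(file.path(ws, "mrna_expression.tsv"), gm, "log2",
                         present = file.path(ws, "mrna_present.tsv")),
  0.60, strict = TRUE)
candidates <- intersect(de_mrna$feature_id[de_mrna$direction != "ns"],
                        mirna_targets)
corr <- infer_correlation_regulon(mrna_f, repsel$genes, candidates,
                                  r_threshold = -0.8)
cat(sprintf("correlation layer: %d targets inferred, %d non-targets (r < -0.8, n = 10)\n",
            length(unique(corr$edges$target)), length(corr$non_targets)))

# network over the DEG-restricted regulon layer
degs <- de_mrna$feature_id[de_mrna$direction != "ns"]
reg_edges <- do.call(rbind, lapply(intersect(repsel$genes, names(regulons)),
  function(r) {
    g <- setdiff(intersect(regulons[[r]], degs), r)
    if (!length(g)) NULL else data.frame(repressor = r, target = g)
  }))
net <- build_tom_network(sel_pred, reg_edges, tc)
print(net)

# one worked motif: the strongest overridden mutual target
pc_targets <- Filter(function(f) identical(f$class, "PC") &&
                       length(f$shared_mirnas) > 0, net$ffl)
ex <- pc_targets[[which.max(vapply(pc_targets, function(f)
  length(f$targeting_mirnas), numeric(1)))]]
q <- query_gene(net, ex$target)
cat("\nworked example:\n", q$narrative, "\n")

write.table(corr$edges, file.path(out, "correlation_edges.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(tp$edges, file.path(out, "transfac_edges.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_network_sif(net$edges, file.path(out, "tom_network.sif"))
writeLines(net$mutual_targets, file.path(out, "mutual_targets.txt"))
writeLines(net$repressor_only, file.path(out, "repressor_only.txt"))
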