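#!/usr/bin/env Rscript
# Stage 2: detection filtering, differential expression, miRNA selection.
#
# mRNA arrays (10 normal vs 10 cancer): features kept with >60% present
# calls in either group, then a moderated t with 1000 group-label
# permutations and BH FDR at 5.5%. miRNA arrays (3 vs 3): >=65% present
# calls, Student-t p-values (a 3+3 design cannot resolve p < 0.05 by
# permutation), then selection at fold change > 6 and p < 0.03 among
# human, mouse-conserved features.

suppressPackageStartupMessages(library(tomnet))

ws <- "results/analysis/workspace"
out <- "results/analysis"
groups <- read.delim(file.path(ws, "sample_groups.tsv"))
gm <- setNames(groups$group, groups$sample_id)

mrna <- read_expression_matrix(file.path(ws, "mrna_expression.tsv"),
                               gm, "log2",
                               present = file.path(ws, "mrna_present.tsv"))
mrna_f <- present_filter(mrna, 0.60, strict = TRUE)
de_mrna <- differential_expression(mrna_f, n_permutations = 1000,
                                   fdr_threshold = 0.055, seed = 42L)
report <- selection_report(length(mrna$feature_ids),
                           length(mrna_f$feature_ids), de_mrna)
print(report)

mirna <- read_expression_matrix(file.path(ws, "mirna_expression.tsv"),
                                gm, "log2",
                                present = file.path(ws, "mirna_present.tsv"))
mirna_f <- present_filter(mirna, 0.65, strict = FALSE)
de_mirna <- differential_expression(mirna_f, fdr_threshold = 0.055,
                                    seed = 42L, p_method = "student")
conserved <- readLines(file.path(ws, "conserved_mirnas.txt"))
selected <- select_mirnas(de_mirna, conserved, fc_min = 6, p_max = 0.03)
cat(sprintf("selected %d upregulated miRNAs (fc %.1f-%.1f)\n",
            length(selected),
            min(de_mirna$fc[de_mirna$feature_id %in% selected]),
            max(de_mirna$fc[de_mirna$feature_id %in% selected])))

write.table(de_mrna, file.path(out, "de_mrna.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(de_mirna, file.path(out, "de_mirna.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(selected, file.path(out, "selected_mirnas.txt"))
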