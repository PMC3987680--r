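#!/usr/bin/env Rscript
# Stage 3: classify predicted miRNA targets as IC / PC / NC.
#
# Predictions are filtered at mirSVR-style score < -0.2; each measured
# target of the selected upregulated miRNAs is classified by its own
# response: IC (down, the canonical expectation), PC (up, candidate
# override) or NC (no change at the FDR threshold). Per-miRNA repressive
# potential (fraction of DEG targets that are down) is contrasted with the
# background rate among untargeted DEGs.

suppressPackageStartupMessages(library(tomnet))

ws <- "results/analysis/workspace"
out <- "results/analysis"
de_mrna <- read_de_table(file.path(out, "de_mrna.tsv"))
selected <- readLines(file.path(out, "selected_mirnas.txt"))
predictions <- read_target_predictions(file.path(ws, "predictions.tsv"),
                                       score_cutoff = -0.2)

tc <- classify_targets(predictions, de_mrna, selected)
s <- summarize_classification(tc)
cat(sprintf("classified %d predicted targets: IC %d (%d%%), PC %d (%d%%), NC %d (%d%%)\n",
            s$total, s$n_IC, s$pct_IC, s$n_PC, s$pct_PC, s$n_NC, s$pct_NC))

rp <- repressive_potential(predictions, de_mrna, selected)
cat(sprintf("mean repression across %d miRNAs: %.0f%% of DEG targets down (background %.0f%%)\n",
            nrow(rp$per_mirna), 100 * rp$mean_frac_down,
            100 * rp$background_frac_down))

write.table(tc, file.path(out, "target_classification.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(s, file.path(out, "classification_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(rp$per_mirna, file.path(out, "repressive_potential.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
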