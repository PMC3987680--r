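#!/usr/bin/env Rscript
# Stage 1: build the synthetic two-condition study.
#
# Generates a ground-truthed input bundle with the structure the override
# analysis assumes: 31 upregulated miRNAs (fold changes 8-120) among a pool
# of decoys, ten repressor genes that are downregulated miRNA targets, and
# ~2000 genes whose cancer-vs-normal shift is an additive trade-off between
# miRNA repression and repressor-loss derepression. Everything downstream
# reads only the files written here.

suppressPackageStartupMessages(library(tomnet))

ws_dir <- "results/analysis/workspace"
cfg <- generator_config(seed = 42L)
bundle <- generate_bundle(cfg, ws_dir)

gt <- bundle$gene_truth
cat("workspace written to", ws_dir, "\n")
cat(sprintf("planted upregulated miRNAs: %d (fold change %.1f-%.1f)\n",
            length(bundle$mirna_up), min(bundle$mirna_planted_fc),
            max(bundle$mirna_planted_fc)))
cat(sprintf("planted repressors: %d, regulon sizes %d-%d\n",
            length(bundle$repressors),
            min(lengths(bundle$regulons)), max(lengths(bundle$regulons))))
cat(sprintf("genes: %d (%d low-expressed fillers); expected classes: %s\n",
            nrow(gt), sum(gt$base < 5),
            paste(names(table(gt$expected_class)),
                  table(gt$expected_class), collapse = " ", sep = "=")))
cat(sprintf("true anti-correlated repressor-target pairs: %d\n",
            nrow(bundle$corr_pairs)))
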