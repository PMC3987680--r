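# tomnet — transcriptional override analysis of miRNA–repressor–target networks

`tomnet` is an R implementation of the transcriptional override model
(TOM) analysis for paired two-condition mRNA/miRNA expression studies,
written for systems biologists asking why most predicted targets of
upregulated miRNAs fail to go down. The answer the model proposes is a
feed-forward motif: an upregulated miRNA also downregulates a
transcriptional repressor, and the resulting derepression of the
repressor's targets can mask (NC) or override (PC) the expected
inverse response (IC) of genes the miRNA targets directly.

On log2 scale the expected shift of gene *g* is modeled additively,

```
Δg = Σ_{r ∈ R(g)} γ_r  −  β·|M(g)|  +  ε
```

with `M(g)` the upregulated miRNAs predicted to target *g* and `R(g)` the
downregulated repressors regulating it. The pipeline:

1. filters features on present/absent detection calls (>60% in either
   group for mRNA, ≥65% for miRNA);
2. calls differential expression with a moderated permutation t
   (BH FDR 5.5%) and selects upregulated miRNAs at fc > 6, p < 0.03;
3. classifies every measured predicted target (mirSVR-style score < −0.2)
   as IC / PC / NC;
4. selects repressors (GO candidates ∩ downregulated ∩ miRNA-targeted) and
   builds repressor→target edges from TRANSFAC-style GMT regulons and from
   co-expression (Pearson r < −0.8 across normal samples; one-sided
   p = 0.0027 at n = 10);
5. assembles the miRNA/repressor/mutual-target network with per-gene
   feed-forward-loop records; and
6. quantifies override with degree-stratified percent-PC trends
   (Cochran-Armitage 1-df chi-square) and log-space hypergeometric
   enrichment.

A first-class synthetic-data module (`generator_config()`,
`generate_bundle()`) plants the full TOM structure — 31 upregulated
miRNAs, ten anti-correlated repressors, masked and overridden targets —
with byte-reproducible ground truth, so every stage is verifiable offline.

## Worked example

```r
library(tomnet)

ws <- make_synthetic(list(dir = "workspace",
                          generator = list(seed = 42L)))
cfg <- ws$run_config
cfg$out_dir <- "out"
report <- run_pipeline(cfg)
```

The same analysis, stage by stage with narrative output, is in
`analysis/01_simulate.R` … `analysis/05_stratified_trends.R`. With the
default configuration (seed 42) the run prints:

```
features 2040 -> present 1849 -> significant 1516 (498 up [33%], 1018 down [67%])
selected 31 upregulated miRNAs (fc 10.1-125.4)
classified 1351 predicted targets: IC 985 (73%), PC 163 (12%), NC 203 (15%)
mean repression across 31 miRNAs: 93% of DEG targets down (background 9%)
repressor chain: 40 candidates -> 20 downregulated -> 10 miRNA-targeted
TomNetwork: 31 miRNAs, 10 repressors, 556 mutual targets (+ 221 repressor-only )
```

All 31 planted miRNAs and all 10 planted repressors are recovered, and the
motif-level stratification shows the override signature — percent PC
falling monotonically as the number of targeting miRNAs grows, from the
repressor-only group down to the 16–31 bin:

```
          label score n_genes n_PC percent_PC
 repressor-only     0     221  220  99.547511
            1-5     1     172  110  63.953488
           6-10     2     120   31  25.833333
          11-15     3      78    9  11.538462
          16-31     4     186   13   6.989247
trend: X2 = 409.10 (1 df), p = 5.75e-91, direction decreasing
```

Genes regulated by 2–5 repressors stay PC at every miRNA load more often
than single-repressor genes (e.g. 15.3% vs 3.1% in the 16–31 bin), and the
closing enrichments — downregulated genes among miRNA targets, upregulated
genes among correlation-inferred repressor targets — are extreme
(log10 p ≈ −166 and −56 on this bundle).

The methods vignette (`vignettes/transcriptional-override.Rmd`) documents
the model, every threshold, the synthetic generator's assumptions, and
what passing tests do and do not establish.

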