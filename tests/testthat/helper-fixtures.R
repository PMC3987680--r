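# Shared fixtures and independent oracles. Everything is built in code at
# test time; the default bundle and pipeline run are generated once per
# session and cached.

.fixtures <- new.env(parent = emptyenv())

default_bundle <- function() {
  if (is.null(.fixtures$bundle)) {
    dir <- file.path(tempdir(), "tomnet-bundle-42")
    .fixtures$bundle <- generate_bundle(generator_config(seed = 42L), dir)
  }
  .fixtures$bundle
}

bundle_run_config <- function(bundle, out_dir) {
  list(paths = bundle$paths[c("mrna_expression", "mrna_present",
                              "mirna_expression", "mirna_present",
                              "predictions", "regulons_gmt",
                              "repressor_candidates", "conserved_mirnas",
                              "sample_groups")],
       seed = bundle$config$seed,
       out_dir = out_dir)
}

default_run <- function() {
  if (is.null(.fixtures$run)) {
    b <- default_bundle()
    cfg <- bundle_run_config(b, file.path(tempdir(), "tomnet-run-42"))
    .fixtures$run <- suppressMessages(suppressWarnings(run_pipeline(cfg)))
  }
  .fixtures$run
}

# Build an ExpressionMatrix directly in memory (log2 scale, all present
# unless stated otherwise).
expr_fixture <- function(values, n_normal, n_cancer, present = NULL) {
  features <- rownames(values)
  samples <- colnames(values)
  if (is.null(samples)) {
    samples <- c(sprintf("N%02d", seq_len(n_normal)),
                 sprintf("C%02d", seq_len(n_cancer)))
    colnames(values) <- samples
  }
  if (is.null(features)) {
    features <- sprintf("F%03d", seq_len(nrow(values)))
    rownames(values) <- features
  }
  if (is.null(present)) present <- matrix(TRUE, nrow(values), ncol(values),
                                          dimnames = dimnames(values))
  structure(list(values = values, feature_ids = features,
                 sample_ids = samples, scale = "log2",
                 group_of = stats::setNames(rep(c("normal", "cancer"),
                                                c(n_normal, n_cancer)), samples),
                 present = present),
            class = "ExpressionMatrix")
}

# Independent hypergeometric upper-tail oracle: direct summation over
# binomial coefficients built from Pascal's triangle (integer-valued,
# no phyper/dhyper/choose involved).
pascal_rows <- function(nmax) {
  rows <- vector("list", nmax + 1L)
  rows[[1L]] <- 1
  for (i in seq_len(nmax)) {
    prev <- rows[[i]]
    rows[[i + 1L]] <- c(1, prev[-1L] + prev[-length(prev)], 1)
  }
  rows  # rows[[n+1]][k+1] == C(n, k)
}

oracle_hyper_upper <- function(N, K, n, k, rows = pascal_rows(N)) {
  lo <- max(0L, n + K - N); hi <- min(n, K)
  i <- max(k, lo):hi
  sum(rows[[K + 1L]][i + 1L] * rows[[N - K + 1L]][n - i + 1L]) /
    rows[[N + 1L]][n + 1L]
}

# Brute-force feed-forward triangle oracle: enumerate all (miRNA, repressor,
# target) triples by explicit loops over the two edge lists.
oracle_triangles <- function(mirna_edges, repressor_edges) {
  out <- list()
  for (i in seq_len(nrow(repressor_edges))) {
    r <- repressor_edges$repressor[i]; g <- repressor_edges$target[i]
    if (r == g) next
    mirs_r <- mirna_edges$mirna_id[mirna_edges$gene_symbol == r]
    mirs_g <- mirna_edges$mirna_id[mirna_edges$gene_symbol == g]
    if (!length(mirs_g)) next   # target must carry a miRNA edge to be mutual
    for (m in intersect(mirs_r, mirs_g)) {
      out[[length(out) + 1L]] <- c(m, r, g)
    }
  }
  if (!length(out)) {
    return(data.frame(mirna = character(0), repressor = character(0),
                      target = character(0)))
  }
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(df) <- c("mirna", "repressor", "target")
  unique(df[order(df$mirna, df$repressor, df$target), ])
}
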