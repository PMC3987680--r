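#' Select repressor genes: annotated, downregulated, miRNA-targeted
#'
#' Implements the three-stage repressor chain: candidate transcriptional
#' repressors (a flat list drawn from negative-regulation-of-transcription
#' GO terms), intersected with significantly downregulated genes, then with
#' predicted targets of at least one selected upregulated miRNA.
#'
#' @param go_list Character vector of candidate repressor symbols.
#' @param de Gene-level `DETable`.
#' @param mirna_targets Character vector: genes predicted to be targeted by
#'   >= 1 selected miRNA.
#' @return A `RepressorSelection` list: `candidate_count`,
#'   `downregulated_count`, `mirna_targeted_count`, and the final `genes`.
#' @export
select_repressors <- function(go_list, de, mirna_targets) {
  go_list <- unique(toupper(go_list))
  gene_col <- if ("gene_symbol" %in% colnames(de)) "gene_symbol" else "feature_id"
  down <- toupper(de[[gene_col]][de$direction == "down"])
  stage2 <- intersect(go_list, down)
  final <- intersect(stage2, toupper(mirna_targets))
  if (!length(final)) warning("no repressor passes all three filters")
  structure(list(candidate_count = length(go_list),
                 downregulated_count = length(stage2),
                 mirna_targeted_count = length(final),
                 genes = sort(final)),
            class = "RepressorSelection")
}

#' @export
print.RepressorSelection <- function(x, ...) {
  cat(sprintf("repressor chain: %d candidates -> %d downregulated -> %d miRNA-targeted\n",
              x$candidate_count, x$downregulated_count, x$mirna_targeted_count))
  invisible(x)
}

#' Repressor-target pairs from TRANSFAC-style regulons
#'
#' Extracts edges R -> G where R is a selected repressor with a regulon in
#' the gene-set table and G is a regulon member that is both a DEG and a
#' predicted target of >= 1 selected miRNA. Also returns the mutual-target
#' gene set and the repressor subset with at least one retained edge.
#'
#' @param regulons A `RegulonTable` (from [read_gmt()]).
#' @param repressors Character vector of selected repressor symbols.
#' @param de Gene-level `DETable`.
#' @param mirna_targets Genes targeted by >= 1 selected miRNA.
#' @return List with `edges` (data.frame `repressor`, `target`),
#'   `mutual_targets` (sorted unique targets) and `active_repressors`.
#' @export
transfac_pairs <- function(regulons, repressors, de, mirna_targets) {
  repressors <- toupper(repressors)
  covered <- intersect(repressors, names(regulons))
  if (!length(covered)) {
    warning("no selected repressor has a regulon")
    return(list(edges = data.frame(repressor = character(0), target = character(0),
                                   stringsAsFactors = FALSE),
                mutual_targets = character(0), active_repressors = character(0)))
  }
  gene_col <- if ("gene_symbol" %in% colnames(de)) "gene_symbol" else "feature_id"
  degs <- toupper(de[[gene_col]][de$direction != "ns"])
  eligible <- intersect(degs, toupper(mirna_targets))
  edges <- do.call(rbind, lapply(covered, function(r) {
    g <- intersect(regulons[[r]], eligible)
    g <- setdiff(g, r)   # drop self-regulation
    if (!length(g)) return(NULL)
    data.frame(repressor = r, target = sort(g), stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(repressor = character(0), target = character(0),
                        stringsAsFactors = FALSE)
  }
  list(edges = edges,
       mutual_targets = sort(unique(edges$target)),
       active_repressors = sort(unique(edges$repressor)))
}

#' One-sided p-value for negative Pearson correlation
#'
#' Directional significance of an observed correlation under the null of
#' zero correlation, via the t transform `t = r * sqrt(n-2) / sqrt(1-r^2)`
#' with n-2 degrees of freedom; the lower tail is reported because
#' repression predicts anti-correlation. With r = -0.8 and n = 10 this gives
#' p = 0.0027.
#'
#' @param r Pearson correlation(s), |r| <= 1.
#' @param n Number of paired samples (>= 3).
#' @return One-sided p-value(s); exactly 0 (r = -1) or 1 (r = +1) at the
#'   degenerate boundaries, flagged with attribute `boundary`.
#' @export
pearson_directional_p <- function(r, n) {
  if (any(n < 3)) stop("n must be >= 3")
  if (any(abs(r) > 1)) stop("|r| must be <= 1")
  at_bound <- abs(r) == 1
  p <- numeric(length(r))
  rr <- r[!at_bound]
  p[!at_bound] <- stats::pt(rr * sqrt(n - 2) / sqrt(1 - rr^2), df = n - 2)
  p[at_bound] <- ifelse(r[at_bound] < 0, 0, 1)
  if (any(at_bound)) attr(p, "boundary") <- which(at_bound)
  p
}

#' Infer a repressor regulon from anti-correlation across normal samples
#'
#' For every (repressor, candidate) pair, the Pearson correlation of log2
#' expression across the normal samples only; a pair becomes an edge iff
#' r is strictly below `r_threshold`. Candidates with no qualifying
#' repressor form the non-target class. Pairs where either gene has zero
#' variance across normal samples are skipped and counted.
#'
#' @param mat Log2 `ExpressionMatrix` containing both repressors and
#'   candidates.
#' @param repressors Character vector of repressor feature ids/symbols.
#' @param candidates Character vector of candidate target genes (typically
#'   DEGs that are miRNA targets).
#' @param r_threshold Strict upper bound on r (default -0.8).
#' @param allowed_pairs Optional data.frame with columns `repressor`,
#'   `target`: restrict evaluation to these pairs (e.g. pairs with a prior
#'   TRANSFAC edge) instead of all repressor x candidate combinations.
#' @return List with `edges` (data.frame `repressor`, `target`, `r`, `n`,
#'   `p_directional`), `regulons` (a correlation-provenance `RegulonTable`),
#'   `non_targets` (candidates with no edge) and `n_skipped` zero-variance
#'   pairs.
#' @export
infer_correlation_regulon <- function(mat, repressors, candidates,
                                      r_threshold = -0.8,
                                      allowed_pairs = NULL) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  normal_cols <- mat$group_of == "normal"
  n <- sum(normal_cols)
  if (n < 3L) stop("need >= 3 normal samples for correlation")
  repressors <- intersect(toupper(repressors), mat$feature_ids)
  candidates0 <- unique(toupper(candidates))
  candidates <- intersect(candidates0, mat$feature_ids)
  candidates <- setdiff(candidates, repressors)
  xr <- t(mat$values[repressors, normal_cols, drop = FALSE])
  xc <- t(mat$values[candidates, normal_cols, drop = FALSE])
  sd_r <- apply(xr, 2L, stats::sd); sd_c <- apply(xc, 2L, stats::sd)
  ok_r <- sd_r > 0; ok_c <- sd_c > 0
  n_skipped <- sum(!ok_r) * length(candidates) + sum(ok_r) * sum(!ok_c)
  if (n_skipped) message("skipping ", n_skipped, " zero-variance pair(s)")
  cc <- stats::cor(xr[, ok_r, drop = FALSE], xc[, ok_c, drop = FALSE])
  hit <- which(cc < r_threshold, arr.ind = TRUE)
  edges <- data.frame(repressor = rownames(cc)[hit[, 1L]],
                      target = colnames(cc)[hit[, 2L]],
                      r = cc[hit], n = rep(n, nrow(hit)),
                      p_directional = if (nrow(hit)) pearson_directional_p(cc[hit], n)
                                      else numeric(0),
                      stringsAsFactors = FALSE)
  if (!is.null(allowed_pairs)) {
    keep <- paste(edges$repressor, edges$target) %in%
      paste(toupper(allowed_pairs$repressor), toupper(allowed_pairs$target))
    edges <- edges[keep, , drop = FALSE]
  }
  edges <- edges[order(edges$repressor, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  regs <- split(edges$target, edges$repressor)
  regulons <- structure(lapply(regs, sort), class = "RegulonTable",
                        provenance = "correlation")
  list(edges = edges, regulons = regulons,
       non_targets = sort(setdiff(candidates, edges$target)),
       n_skipped = n_skipped)
}
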