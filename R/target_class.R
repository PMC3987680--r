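#' Classify predicted miRNA targets as IC, PC or NC
#'
#' For every gene predicted (at the score cutoff) to be targeted by at least
#' one of the selected upregulated miRNAs and measured on the filtered
#' array, the expression response relative to its regulating miRNAs is
#' classified: IC (inversely correlated, gene down while miRNAs up), PC
#' (positively correlated, gene up), or NC (no change detected at the FDR
#' threshold). Genes never measured are excluded from the denominator and
#' counted separately. Predictions for miRNAs outside the selected set are
#' ignored.
#'
#' @param predictions A `TargetPredictionTable` (already score-filtered).
#' @param de Gene-level `DETable` restricted to measured, present-filtered
#'   genes; the gene identifier column is `gene_symbol` if present, else
#'   `feature_id`.
#' @param selected_mirnas Character vector of selected upregulated miRNA ids.
#' @return A `TargetClassification` data.frame with columns `gene_symbol`,
#'   `mirna_count` (distinct selected miRNAs predicted to target the gene)
#'   and `class` (factor IC/PC/NC); attribute `n_unmeasured` counts predicted
#'   targets absent from `de`.
#' @export
classify_targets <- function(predictions, de, selected_mirnas) {
  pred <- predictions[predictions$mirna_id %in% selected_mirnas, , drop = FALSE]
  gene_col <- if ("gene_symbol" %in% colnames(de)) "gene_symbol" else "feature_id"
  de_genes <- toupper(de[[gene_col]])
  counts <- tapply(pred$mirna_id, pred$gene_symbol,
                   function(m) length(unique(m)))
  target_genes <- names(counts)
  measured <- target_genes %in% de_genes
  n_unmeasured <- sum(!measured)
  target_genes <- target_genes[measured]
  idx <- match(target_genes, de_genes)
  dir <- as.character(de$direction[idx])
  cls <- ifelse(dir == "down", "IC", ifelse(dir == "up", "PC", "NC"))
  out <- data.frame(gene_symbol = target_genes,
                    mirna_count = as.integer(counts[target_genes]),
                    class = factor(cls, levels = c("IC", "PC", "NC")),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("TargetClassification", "data.frame")
  attr(out, "n_unmeasured") <- n_unmeasured
  out
}

#' Summarize an IC/PC/NC classification into a table row
#'
#' Produces counts and integer-rounded percentages per class, with the total
#' as denominator — the layout of a per-algorithm summary row.
#'
#' @param tc A `TargetClassification`, or a named integer vector/list with
#'   entries `IC`, `PC`, `NC`.
#' @return A one-row data.frame: `n_IC`, `pct_IC`, `n_PC`, `pct_PC`, `n_NC`,
#'   `pct_NC`, `total`.
#' @export
summarize_classification <- function(tc) {
  if (inherits(tc, "TargetClassification")) {
    counts <- table(tc$class)
    counts <- c(IC = unname(counts["IC"]), PC = unname(counts["PC"]),
                NC = unname(counts["NC"]))
  } else {
    counts <- c(IC = tc[["IC"]], PC = tc[["PC"]], NC = tc[["NC"]])
  }
  counts[is.na(counts)] <- 0L
  total <- sum(counts)
  if (total == 0L) stop("empty classification")
  pct <- as.integer(round(100 * counts / total))
  data.frame(n_IC = counts[["IC"]], pct_IC = pct[[1L]],
             n_PC = counts[["PC"]], pct_PC = pct[[2L]],
             n_NC = counts[["NC"]], pct_NC = pct[[3L]],
             total = total, row.names = NULL)
}

#' Per-miRNA repressive potential
#'
#' For each selected upregulated miRNA, the fraction of its predicted DEG
#' targets that are actually downregulated; plus the background fraction of
#' downregulated genes among DEGs predicted to be targeted by none of the
#' selected miRNAs, and the mean fraction over miRNAs. A miRNA with zero DEG
#' targets gets a missing fraction.
#'
#' @inheritParams classify_targets
#' @return List with `per_mirna` (data.frame: `mirna_id`, `n_deg_targets`,
#'   `frac_down`), `background_frac_down`, `n_background` and
#'   `mean_frac_down`.
#' @export
repressive_potential <- function(predictions, de, selected_mirnas) {
  gene_col <- if ("gene_symbol" %in% colnames(de)) "gene_symbol" else "feature_id"
  de_genes <- toupper(de[[gene_col]])
  is_deg <- de$direction != "ns"
  deg_genes <- de_genes[is_deg]
  deg_down <- de_genes[de$direction == "down"]
  pred <- predictions[predictions$mirna_id %in% selected_mirnas, , drop = FALSE]

  per <- lapply(selected_mirnas, function(m) {
    targ <- unique(pred$gene_symbol[pred$mirna_id == m])
    degs <- intersect(targ, deg_genes)
    if (!length(degs)) {
      warning("miRNA ", m, " has no DEG targets; fraction undefined")
      return(data.frame(mirna_id = m, n_deg_targets = 0L,
                        frac_down = NA_real_, stringsAsFactors = FALSE))
    }
    data.frame(mirna_id = m, n_deg_targets = length(degs),
               frac_down = mean(degs %in% deg_down), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  any_target <- unique(pred$gene_symbol)
  background <- setdiff(deg_genes, any_target)
  list(per_mirna = per,
       background_frac_down = if (length(background)) mean(background %in% deg_down) else NA_real_,
       n_background = length(background),
       mean_frac_down = mean(per$frac_down, na.rm = TRUE))
}
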