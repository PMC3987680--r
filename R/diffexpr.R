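#' Filter features on present/absent detection calls
#'
#' Keeps features detected in a sufficient fraction of samples in at least
#' one of the two groups. The comparison is strict (`>`) by default, matching
#' the ">60% present calls in either group" rule used for mRNA arrays; miRNA
#' arrays conventionally use a non-strict "at least 65%" rule
#' (`strict = FALSE`).
#'
#' @param mat An `ExpressionMatrix`.
#' @param min_fraction Present-call fraction threshold, in (0, 1].
#' @param strict If `TRUE` require fraction `> min_fraction`, else `>=`.
#' @return The filtered `ExpressionMatrix`, with attribute `n_dropped`.
#' @export
present_filter <- function(mat, min_fraction = 0.60, strict = TRUE) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must be in (0, 1]")
  }
  keep_frac <- function(grp) rowMeans(mat$present[, mat$group_of == grp, drop = FALSE])
  fn <- keep_frac("normal"); fc <- keep_frac("cancer")
  keep <- if (strict) fn > min_fraction | fc > min_fraction else
    fn >= min_fraction | fc >= min_fraction
  out <- mat
  out$values <- mat$values[keep, , drop = FALSE]
  out$present <- mat$present[keep, , drop = FALSE]
  out$feature_ids <- mat$feature_ids[keep]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Signed linear fold change from log2 group means
#'
#' Maps a log2 difference `d = mean_cancer - mean_normal` to the signed
#' linear convention used in array studies: `2^d` for upregulation,
#' `-2^(-d)` for downregulation, so the magnitude is always >= 1 and the
#' sign gives the direction (positive = up in cancer).
#'
#' @param mean_normal_log2,mean_cancer_log2 Group means on log2 scale.
#' @return Signed linear fold change(s).
#' @export
signed_fold_change <- function(mean_normal_log2, mean_cancer_log2) {
  d <- mean_cancer_log2 - mean_normal_log2
  ifelse(d >= 0, 2^d, -(2^(-d)))
}

#' Two-group differential expression with permutation or Student-t p-values
#'
#' A moderated two-sample t statistic (per-feature standard error plus an
#' additive fudge constant s0, the 5th percentile of per-feature SEs, so
#' zero-variance features never produce infinite statistics) is computed for
#' cancer minus normal. P-values come either from random group-label
#' permutations of that statistic (`p_method = "permutation"`; the default,
#' appropriate for the 10+10 mRNA design) or from the Student t reference
#' distribution (`"student"`; needed when the number of distinct label
#' assignments is too small for permutation p-values to resolve small
#' thresholds, as in a 3+3 miRNA design where the permutation floor is 0.05).
#' FDR is Benjamini-Hochberg; a feature is called up/down when q is at or
#' below `fdr_threshold`.
#'
#' @param mat Log2-scale `ExpressionMatrix`, both groups >= 2 samples.
#' @param n_permutations Number of label permutations (>= 100).
#' @param fdr_threshold BH FDR for direction calls (default 0.055).
#' @param seed Integer seed for the permutation draws (required).
#' @param p_method `"permutation"` or `"student"`.
#' @return A `DETable` data.frame with columns `feature_id`, `mean_normal`,
#'   `mean_cancer`, `fc` (signed linear), `t`, `p`, `q`, `direction`
#'   (factor up/down/ns); attribute `n_zero_variance` counts floored
#'   features.
#' @export
differential_expression <- function(mat, n_permutations = 1000,
                                    fdr_threshold = 0.055, seed,
                                    p_method = c("permutation", "student")) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  p_method <- match.arg(p_method)
  if (mat$scale != "log2") stop("differential_expression requires a log2-scale matrix")
  if (missing(seed)) stop("seed is required")
  is_n <- mat$group_of == "normal"
  is_c <- mat$group_of == "cancer"
  n1 <- sum(is_n); n2 <- sum(is_c)
  if (n1 < 2L || n2 < 2L) stop("both groups need >= 2 samples")
  if (p_method == "permutation" && n_permutations < 100L) {
    stop("n_permutations must be >= 100")
  }
  x <- mat$values

  tstat_for <- function(cancer_cols) {
    xn <- x[, !cancer_cols, drop = FALSE]
    xc <- x[, cancer_cols, drop = FALSE]
    mn <- rowMeans(xn); mc <- rowMeans(xc)
    ssn <- rowSums(xn * xn) - n1 * mn^2   # corrected sums of squares
    ssc <- rowSums(xc * xc) - n2 * mc^2
    sp2 <- pmax(ssn + ssc, 0) / (n1 + n2 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    list(diff = mc - mn, se = se, mn = mn, mc = mc)
  }

  obs <- tstat_for(is_c)
  s0 <- stats::quantile(obs$se, 0.05, names = FALSE)
  n_zero <- sum(obs$se == 0)
  t_obs <- obs$diff / (obs$se + s0)

  if (p_method == "student") {
    p <- 2 * stats::pt(-abs(t_obs), df = n1 + n2 - 2L)
  } else {
    set.seed(seed)
    exceed <- integer(nrow(x))
    abs_obs <- abs(t_obs)
    for (b in seq_len(n_permutations)) {
      perm_c <- logical(ncol(x))
      perm_c[sample.int(ncol(x), n2)] <- TRUE
      pb <- tstat_for(perm_c)
      t_b <- pb$diff / (pb$se + s0)
      exceed <- exceed + (abs(t_b) >= abs_obs)
    }
    p <- (1L + exceed) / (n_permutations + 1L)
  }

  q <- stats::p.adjust(p, method = "BH")
  direction <- ifelse(q > fdr_threshold, "ns",
                      ifelse(obs$diff > 0, "up", "down"))
  out <- data.frame(feature_id = mat$feature_ids,
                    mean_normal = obs$mn, mean_cancer = obs$mc,
                    fc = signed_fold_change(obs$mn, obs$mc),
                    t = t_obs, p = p, q = q,
                    direction = factor(direction, levels = c("up", "down", "ns")),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("DETable", "data.frame")
  attr(out, "n_zero_variance") <- n_zero
  attr(out, "fdr_threshold") <- fdr_threshold
  out
}

#' Read a DETable previously written as TSV
#'
#' Restores the direction factor and class so downstream stages can consume
#' a differential-expression table from disk.
#'
#' @param path TSV path (as written by the pipeline's de_mrna.tsv /
#'   de_mirna.tsv exports).
#' @return A `DETable` data.frame.
#' @export
read_de_table <- function(path) {
  de <- utils::read.delim(path, stringsAsFactors = FALSE)
  de$direction <- factor(de$direction, levels = c("up", "down", "ns"))
  class(de) <- c("DETable", "data.frame")
  de
}

#' Collapse a probe-set level DETable to gene level
#'
#' Many-to-one probe-set to gene maps are resolved by keeping, per gene, the
#' probe set with the smallest p-value (default) or the largest absolute
#' fold change.
#'
#' @param de A `DETable`.
#' @param gene_of Named character vector: feature_id -> gene symbol.
#' @param method `"min_p"` or `"max_fc"`.
#' @return Gene-level `DETable` with `feature_id` replaced by `gene_symbol`.
#' @export
collapse_to_genes <- function(de, gene_of, method = c("min_p", "max_fc")) {
  method <- match.arg(method)
  gene <- toupper(gene_of[de$feature_id])
  keep <- !is.na(gene) & nzchar(gene)
  de <- de[keep, , drop = FALSE]
  gene <- gene[keep]
  o <- if (method == "min_p") order(gene, de$p) else order(gene, -abs(de$fc))
  de <- de[o, , drop = FALSE]
  gene <- gene[o]
  first <- !duplicated(gene)
  out <- de[first, , drop = FALSE]
  out$gene_symbol <- gene[first]
  rownames(out) <- NULL
  class(out) <- c("DETable", "data.frame")
  out
}

#' Select upregulated miRNAs by fold change and significance
#'
#' Applies the selection rule for differentially expressed miRNAs: restrict
#' to human (`hsa-` prefixed) features flagged as conserved to mouse, then
#' keep those with fold change strictly above `fc_min` and p-value strictly
#' below `p_max`.
#'
#' @param de miRNA-level `DETable` (computed on the present-filtered miRNA
#'   matrix).
#' @param conserved Character vector of conserved miRNA identifiers, or
#'   `NULL` to skip the conservation filter.
#' @param fc_min Fold-change threshold (strict `>`), default 6.
#' @param p_max P-value threshold (strict `<`), default 0.03.
#' @param require_hsa Keep only `hsa-` prefixed identifiers (case
#'   insensitive). Identifiers without any species prefix are kept.
#' @return Character vector of selected miRNA ids, with a `report` attribute
#'   giving counts per filter stage.
#' @export
select_mirnas <- function(de, conserved = NULL, fc_min = 6, p_max = 0.03,
                          require_hsa = TRUE) {
  ids <- de$feature_id
  keep <- rep(TRUE, length(ids))
  if (require_hsa) {
    has_prefix <- grepl("^[a-z]{3}-", ids, ignore.case = TRUE)
    keep <- keep & (!has_prefix | grepl("^hsa-", ids, ignore.case = TRUE))
  }
  n_hsa <- sum(keep)
  if (!is.null(conserved)) keep <- keep & ids %in% conserved
  n_conserved <- sum(keep)
  pass <- keep & de$fc > fc_min & de$p < p_max
  selected <- ids[pass]
  if (!length(selected)) warning("no miRNAs pass fc > ", fc_min, " and p < ", p_max)
  structure(selected,
            report = c(input = length(ids), human = n_hsa,
                       conserved = n_conserved, selected = length(selected)))
}

#' Stage-count report for a DEG selection
#'
#' @param n_input Features before filtering.
#' @param n_present Features passing the present filter.
#' @param de A `DETable` after DE analysis (gene level if collapsed).
#' @return A `SelectionReport` list: counts at each stage plus the up/down
#'   split with integer percentages of the significant total.
#' @export
selection_report <- function(n_input, n_present, de) {
  up <- sum(de$direction == "up")
  down <- sum(de$direction == "down")
  sig <- up + down
  structure(list(input = n_input, present = n_present, significant = sig,
                 up = up, down = down,
                 pct_up = if (sig) as.integer(round(100 * up / sig)) else NA_integer_,
                 pct_down = if (sig) as.integer(round(100 * down / sig)) else NA_integer_),
            class = "SelectionReport")
}

#' @export
print.SelectionReport <- function(x, ...) {
  cat(sprintf("features %d -> present %d -> significant %d (%d up [%d%%], %d down [%d%%])\n",
              x$input, x$present, x$significant, x$up, x$pct_up, x$down, x$pct_down))
  invisible(x)
}
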