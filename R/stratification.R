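#' Bin genes by the number of upregulated miRNAs targeting them
#'
#' Partitions genes into ordered count bins (default edges give the groups
#' 1-5, 6-10, 11-15, 16-31) plus, optionally, a leading group of genes that
#' carry a repressor edge but are predicted targets of none of the selected
#' miRNAs. Each gene is assigned exactly once; per-bin PC tallies are
#' computed from the classification.
#'
#' @param classification A `TargetClassification` (or data.frame with
#'   `gene_symbol`, `mirna_count`, `class`) covering the genes to stratify.
#' @param bin_edges Integer vector of lower bin edges for the miRNA-count
#'   bins, strictly increasing, first edge >= 1. Default `c(1, 6, 11, 16)`.
#' @param max_count Cap for the last bin label and a sanity bound: a count
#'   above it is an impossible count (cannot exceed the selected miRNA set).
#' @param repressor_only_group Optional character vector of genes to place
#'   in a leading zero-miRNA group (targets of the repressors but of no
#'   selected miRNA); such genes need not appear in `classification` rows
#'   with positive counts.
#' @param repressor_only_classes Optional factor/character of classes for
#'   `repressor_only_group` genes (needed because zero-count genes carry no
#'   miRNA-target classification row); same length as the group.
#' @param score_type `"index"` scores bins 1, 2, ... (default);
#'   `"midpoint"` scores each bin by its count midpoint, weighting the
#'   trend test by actual miRNA load.
#' @return A `StratifiedSummary` data.frame: `label`, `score`, `n_genes`,
#'   `n_PC`, `percent_PC`, ordered by score.
#' @export
bin_by_mirna_count <- function(classification, bin_edges = c(1L, 6L, 11L, 16L),
                               max_count = 31L,
                               repressor_only_group = NULL,
                               repressor_only_classes = NULL,
                               score_type = c("index", "midpoint")) {
  score_type <- match.arg(score_type)
  stopifnot(all(diff(bin_edges) > 0), bin_edges[1L] >= 1L)
  counts <- classification$mirna_count
  if (any(counts > max_count)) {
    stop("impossible miRNA count > ", max_count, " (exceeds selected miRNA set)")
  }
  if (any(counts < 1L)) stop("classification rows must have mirna_count >= 1")
  breaks <- c(bin_edges, max_count + 1L)
  labels <- vapply(seq_along(bin_edges), function(i) {
    lo <- bin_edges[i]; hi <- breaks[i + 1L] - 1L
    if (lo == hi) as.character(lo) else paste0(lo, "-", hi)
  }, character(1L))
  bin <- cut(counts, breaks = breaks, labels = labels, right = FALSE)
  is_pc <- classification$class == "PC"
  tab_n <- tapply(rep(1L, length(bin)), bin, sum, default = 0L)
  tab_pc <- tapply(is_pc, bin, sum, default = 0L)
  scores <- if (score_type == "index") seq_along(labels) else
    (bin_edges + (breaks[-1L] - 1L)) / 2
  out <- data.frame(label = labels,
                    score = scores,
                    n_genes = as.integer(tab_n[labels]),
                    n_PC = as.integer(tab_pc[labels]),
                    stringsAsFactors = FALSE)
  if (!is.null(repressor_only_group)) {
    n0 <- length(unique(repressor_only_group))
    pc0 <- if (!is.null(repressor_only_classes)) {
      sum(repressor_only_classes[!duplicated(repressor_only_group)] == "PC")
    } else 0L
    out <- rbind(data.frame(label = "repressor-only", score = 0L,
                            n_genes = n0, n_PC = as.integer(pc0),
                            stringsAsFactors = FALSE), out)
  }
  out$percent_PC <- ifelse(out$n_genes > 0, 100 * out$n_PC / out$n_genes, NA_real_)
  class(out) <- c("StratifiedSummary", "data.frame")
  out
}

#' Equal-occupancy bin edges for miRNA counts
#'
#' Alternative binning scheme: lower edges chosen from quantiles of the
#' observed positive counts so bins hold roughly equal numbers of genes,
#' instead of equal count width.
#'
#' @param counts Integer miRNA counts (>= 1) for the genes to stratify.
#' @param n_bins Number of bins requested; fewer are returned when ties
#'   collapse quantiles.
#' @return Strictly increasing integer vector of lower edges starting at 1,
#'   usable as `bin_edges` in [bin_by_mirna_count()].
#' @export
equal_size_bin_edges <- function(counts, n_bins = 4L) {
  counts <- counts[counts >= 1L]
  if (!length(counts)) stop("no positive counts")
  qs <- stats::quantile(counts, probs = seq(0, 1, length.out = n_bins + 1L),
                        type = 1L)
  edges <- sort(unique(as.integer(ceiling(qs[-length(qs)]))))
  edges[1L] <- 1L
  edges
}

#' Cochran-Armitage chi-square test for trend in proportions
#'
#' One-degree-of-freedom trend statistic for proportions across ordered
#' bins with numeric scores (default: bin index). Algebraically equal to
#' `N * r^2`, where r is the point-biserial correlation between score and
#' the binary outcome; the statistic is invariant to affine transformations
#' of the scores, and for two bins it reduces to the 2x2 chi-square without
#' continuity correction.
#'
#' @param n_PC Successes per bin (e.g. PC genes).
#' @param n_genes Totals per bin.
#' @param scores Numeric scores, strictly monotone; default bin index.
#' @param one_sided If `"decreasing"` or `"increasing"`, return the
#'   one-sided p in that direction of the success proportion; default the
#'   standard two-sided chi-square upper tail.
#' @return List with `X2`, `p`, `df` = 1 and `slope_sign`.
#' @export
chi_square_trend <- function(n_PC, n_genes, scores = seq_along(n_genes),
                             one_sided = c("none", "decreasing", "increasing")) {
  one_sided <- match.arg(one_sided)
  keep <- n_genes > 0
  n_PC <- n_PC[keep]; n_genes <- n_genes[keep]; scores <- scores[keep]
  if (length(n_genes) < 2L) stop("need >= 2 non-empty bins for a trend test")
  if (any(n_PC > n_genes) || any(n_PC < 0)) stop("need 0 <= n_PC <= n_genes")
  if (any(diff(scores) == 0)) stop("scores must be strictly monotone")
  N <- sum(n_genes); R <- sum(n_PC)
  if (R == 0L || R == N) {
    return(list(X2 = 0, p = 1, df = 1L, slope_sign = 0))
  }
  pbar <- R / N
  sbar <- sum(scores * n_genes) / N
  num <- sum(scores * n_PC) - R * sbar
  den <- pbar * (1 - pbar) * (sum(scores^2 * n_genes) - N * sbar^2)
  X2 <- num^2 / den
  p2 <- stats::pchisq(X2, df = 1L, lower.tail = FALSE)
  slope <- sign(num)
  p <- switch(one_sided,
              none = p2,
              decreasing = if (slope < 0) p2 / 2 else 1 - p2 / 2,
              increasing = if (slope > 0) p2 / 2 else 1 - p2 / 2)
  list(X2 = X2, p = p, df = 1L, slope_sign = slope)
}

#' Upper-tail hypergeometric probability in log space
#'
#' P(X >= k) for X ~ Hypergeometric(population N, category size K, draws n),
#' computed in log space so enrichment probabilities far below the smallest
#' positive double remain representable as log10 p.
#'
#' @param N Population size.
#' @param K Category-1 size (e.g. downregulated genes).
#' @param n Category-2 size / number of draws (e.g. predicted targets).
#' @param k Observed overlap.
#' @return An `EnrichmentResult` list: the parameters, `log10_p` and `p`
#'   (0 when underflowed).
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N) {
    stop("need 0 <= K, n <= N and k >= 0")
  }
  if (k < max(0, n + K - N) || k > min(n, K)) {
    stop("k = ", k, " outside the hypergeometric support [",
         max(0, n + K - N), ", ", min(n, K), "]")
  }
  log10_p <- stats::phyper(k - 1, m = K, n = N - K, k = n,
                           lower.tail = FALSE, log.p = TRUE) / log(10)
  structure(list(N = N, K = K, n = n, k = k,
                 log10_p = log10_p, p = 10^log10_p),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("hypergeometric upper tail: N=%d K=%d n=%d k=%d -> log10 p = %.4f\n",
              x$N, x$K, x$n, x$k, x$log10_p))
  invisible(x)
}

#' Stratify the miRNA-count trend by repressor multiplicity
#'
#' Splits genes into repressor-count strata (default 1 vs 2-5 vs 6-45) and
#' computes a miRNA-count stratified summary plus trend test within each
#' stratum, exposing whether multiple downregulated repressors override
#' miRNA repression more strongly than a single one.
#'
#' @param classification A `TargetClassification` covering the genes.
#' @param repressor_counts Named integer vector: gene -> number of
#'   downregulated repressors regulating it (>= 1 for every gene in scope).
#' @param split_edges Lower edges of the repressor-count strata
#'   (default `c(1, 2, 6)` giving 1, 2-5, 6-45).
#' @param split_max Upper cap for the last stratum label (default 45).
#' @param bin_edges,max_count Passed to [bin_by_mirna_count()].
#' @return A `RepressorMultiplicitySplit` list: `strata` (named list of
#'   `StratifiedSummary`), `trends` (named list from [chi_square_trend()],
#'   `NULL` where a stratum has < 2 populated bins) and `comparison`
#'   (data.frame of percent_PC per miRNA bin across strata).
#' @export
repressor_multiplicity_split <- function(classification, repressor_counts,
                                         split_edges = c(1L, 2L, 6L),
                                         split_max = 45L,
                                         bin_edges = c(1L, 6L, 11L, 16L),
                                         max_count = 31L) {
  genes <- classification$gene_symbol
  rc <- repressor_counts[genes]
  if (anyNA(rc) || any(rc < 1L)) {
    stop("every gene in scope needs a repressor count >= 1")
  }
  breaks <- c(split_edges, split_max + 1L)
  labels <- vapply(seq_along(split_edges), function(i) {
    lo <- split_edges[i]; hi <- breaks[i + 1L] - 1L
    if (lo == hi) as.character(lo) else paste0(lo, "-", hi)
  }, character(1L))
  stratum <- cut(rc, breaks = breaks, labels = labels, right = FALSE)
  strata <- list(); trends <- list()
  for (lab in labels) {
    sub <- classification[which(stratum == lab), , drop = FALSE]
    if (!nrow(sub)) {
      warning("repressor-count stratum '", lab, "' is empty; omitted")
      next
    }
    s <- bin_by_mirna_count(sub, bin_edges = bin_edges, max_count = max_count)
    strata[[lab]] <- s
    pop <- s$n_genes > 0
    trends[[lab]] <- if (sum(pop) >= 2L) {
      chi_square_trend(s$n_PC[pop], s$n_genes[pop], s$score[pop])
    } else NULL
  }
  if (!length(strata)) stop("all repressor-count strata are empty")
  bins <- strata[[1L]]$label
  comparison <- data.frame(mirna_bin = bins, stringsAsFactors = FALSE)
  for (lab in names(strata)) comparison[[lab]] <- strata[[lab]]$percent_PC
  structure(list(strata = strata, trends = trends, comparison = comparison),
            class = "RepressorMultiplicitySplit")
}
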