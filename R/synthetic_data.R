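#' Configuration for the synthetic TOM bundle generator
#'
#' Assembles and validates the generator settings. The defaults mirror the
#' study design the pipeline targets: 10+10 mRNA samples, 3+3 miRNA
#' samples, 31 planted upregulated miRNAs among a larger pool, ten planted
#' repressors, and an additive log2 effect model in which per-gene shifts
#' trade off miRNA repression against repressor-loss derepression.
#'
#' @param n_normal,n_cancer mRNA sample counts per group.
#' @param n_normal_mirna,n_cancer_mirna miRNA sample counts per group.
#' @param n_genes Number of regular genes (a `frac_low` share of them
#'   low-expressed fillers that the present filter removes).
#' @param n_mirnas Planted upregulated miRNAs.
#' @param n_mirna_decoys,n_mirna_nonconserved,n_mirna_mouse,n_mirna_low
#'   Decoy miRNA features: unchanged human conserved decoys, human
#'   non-conserved, mouse-prefixed, and low-expressed ones.
#' @param mirna_fc_range Linear fold-change range for planted miRNA
#'   up-shifts, sampled log-uniformly. The lower end sits above the fc > 6
#'   selection threshold by a measurement-noise margin so the planted set is
#'   recoverable by the printed selection rule.
#' @param beta_mir Log2 repression per targeting upregulated miRNA.
#' @param gamma_rep Mean log2 derepression per regulating downregulated
#'   repressor for ordinary genes (gamma ~ Gamma(shape 2)).
#' @param override_frac Fraction of repressor-regulated genes whose
#'   derepression is drawn from the strong (override) component.
#' @param override_range Range of the strong per-repressor derepression
#'   (uniform); its upper end sets how far into the high-miRNA-count bins
#'   full override persists.
#' @param n_repressors Planted repressors.
#' @param regulon_frac Per-repressor probability that a regular gene is in
#'   its TRANSFAC-style regulon.
#' @param target_beta Beta(a, b) parameters for the per-gene probability
#'   that each upregulated miRNA targets it (spreads miRNA counts 0..31).
#' @param decoy_target_prob Targeting probability for decoy miRNAs.
#' @param noise_sd Per-sample measurement noise and the jitter on the
#'   expected shift, log2 scale.
#' @param mirna_noise_sd Per-sample miRNA measurement noise, log2 scale.
#' @param latent_activity_sd SD of the per-repressor latent activity shared
#'   (with opposite loadings) by true repressor-target pairs across samples;
#'   drives the anti-correlation over normal samples.
#' @param up_background_frac Fraction of genes targeted by no selected miRNA
#'   planted as tumor-activated (extra log2 shift +1.5 to +4); balances the
#'   up/down DEG split toward the ~38/62 two-condition profile the analysis
#'   expects.
#' @param frac_low Fraction of regular genes planted as low-expressed.
#' @param n_go_decoys GO-candidate decoys (split evenly between upregulated,
#'   downregulated-but-untargeted, and unchanged).
#' @param class_margin Log2 margin for the expected IC/PC/NC truth label.
#' @param seed Integer seed (mandatory).
#' @return A validated `GeneratorConfig` list.
#' @export
generator_config <- function(n_normal = 10L, n_cancer = 10L,
                             n_normal_mirna = 3L, n_cancer_mirna = 3L,
                             n_genes = 2000L,
                             n_mirnas = 31L, n_mirna_decoys = 20L,
                             n_mirna_nonconserved = 5L, n_mirna_mouse = 4L,
                             n_mirna_low = 3L,
                             mirna_fc_range = c(8, 120),
                             beta_mir = 0.5, gamma_rep = 1.0,
                             override_frac = 0.2, override_range = c(2, 14),
                             n_repressors = 10L, regulon_frac = 0.075,
                             target_beta = c(0.4, 1.2),
                             decoy_target_prob = 0.05,
                             noise_sd = 0.25, mirna_noise_sd = 0.15,
                             latent_activity_sd = 1.0,
                             up_background_frac = 0.5,
                             frac_low = 0.1, n_go_decoys = 30L,
                             class_margin = 1.0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  counts <- c(cfg$n_normal, cfg$n_cancer, cfg$n_normal_mirna, cfg$n_cancer_mirna,
              cfg$n_genes, cfg$n_mirnas, cfg$n_repressors)
  if (any(counts < 1L)) stop("all sample/feature counts must be >= 1")
  if (cfg$n_repressors > cfg$n_genes) stop("more repressors than genes is infeasible")
  if (any(c(cfg$beta_mir, cfg$gamma_rep, cfg$override_frac,
            cfg$noise_sd, cfg$mirna_noise_sd, cfg$latent_activity_sd) < 0)) {
    stop("strengths and noise SDs must be >= 0")
  }
  if (cfg$mirna_fc_range[1L] <= 1 || diff(cfg$mirna_fc_range) < 0) {
    stop("mirna_fc_range must be an increasing range above 1")
  }
  structure(cfg, class = "GeneratorConfig")
}

#' Expected IC/PC/NC class from a planted expression shift
#'
#' Truth labelling for recovery tests: PC if the expected log2 shift exceeds
#' the margin, IC if below its negative, NC otherwise.
#'
#' @param delta_expected Planted expected log2 shift(s), cancer vs normal.
#' @param significance_margin Non-negative log2 margin.
#' @return Factor with levels IC, PC, NC.
#' @export
expected_class <- function(delta_expected, significance_margin = 1.0) {
  if (significance_margin < 0) stop("margin must be >= 0")
  cls <- ifelse(delta_expected > significance_margin, "PC",
                ifelse(delta_expected < -significance_margin, "IC", "NC"))
  factor(cls, levels = c("IC", "PC", "NC"))
}

# deterministic TSV writer (fixed column order, full numeric precision)
write_tsv_plain <- function(df, path) {
  is_num <- vapply(df, is.double, logical(1L))
  for (j in which(is_num)) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Generate a complete synthetic input bundle with ground truth
#'
#' Writes every file the pipeline reads — mRNA and miRNA expression matrices
#' with present-call companions, a score-filtered-able prediction table, a
#' TRANSFAC-style GMT of planted regulons, a GO-style repressor candidate
#' list with decoys, a conserved-miRNA list and a sample-group table — and
#' returns the planted truth.
#'
#' The effect model is additive on log2 scale: a gene's expected cancer
#' shift is `gamma_g * R_g - beta_mir * M_g + eps`, where `M_g` counts the
#' planted upregulated miRNAs targeting it, `R_g` the planted repressors
#' whose regulon contains it, and `gamma_g` is ordinary (Gamma-distributed,
#' mean `gamma_rep`) or, with probability `override_frac`, strong
#' (`override_range`), producing the masked/overridden (NC/PC) responses the
#' override model predicts. Each repressor-regulated gene shares a latent
#' activity with its primary repressor, with opposite loadings, so true
#' pairs are strongly anti-correlated across normal samples.
#'
#' @param cfg A `GeneratorConfig`.
#' @param dir Output directory (created if needed).
#' @return A `TruthBundle` list: `config`, `paths`, truth tables
#'   (`mirna_up`, `mirna_planted_fc`, `mirna_edges`, `regulons`,
#'   `repressors`, `go_list`, `corr_pairs`, `gene_truth`, `group_map`).
#' @export
generate_bundle <- function(cfg, dir) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  ## --- identifiers -------------------------------------------------------
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  n_low <- floor(cfg$frac_low * cfg$n_genes)
  low_genes <- if (n_low) genes[(cfg$n_genes - n_low + 1L):cfg$n_genes] else character(0)
  reps <- sprintf("REP%02d", seq_len(cfg$n_repressors))
  n_dec3 <- cfg$n_go_decoys %/% 3L
  dec_up <- sprintf("GODECU%02d", seq_len(n_dec3))
  dec_down <- sprintf("GODECD%02d", seq_len(n_dec3))
  dec_ns <- sprintf("GODECN%02d", seq_len(cfg$n_go_decoys - 2L * n_dec3))
  features <- c(genes, dec_up, dec_down, dec_ns, reps)

  mir_up <- sprintf("hsa-miR-U%02d", seq_len(cfg$n_mirnas))
  mir_dec <- sprintf("hsa-miR-D%02d", seq_len(cfg$n_mirna_decoys))
  mir_ncv <- sprintf("hsa-miR-N%02d", seq_len(cfg$n_mirna_nonconserved))
  mir_mmu <- sprintf("mmu-miR-M%02d", seq_len(cfg$n_mirna_mouse))
  mir_low <- sprintf("hsa-miR-L%02d", seq_len(cfg$n_mirna_low))
  mirnas <- c(mir_up, mir_dec, mir_ncv, mir_mmu, mir_low)
  conserved <- c(mir_up, mir_dec, mir_low, mir_mmu)

  samples_m <- c(sprintf("OSE%02d", seq_len(cfg$n_normal)),
                 sprintf("CEPI%02d", seq_len(cfg$n_cancer)))
  groups_m <- stats::setNames(rep(c("normal", "cancer"),
                                  c(cfg$n_normal, cfg$n_cancer)), samples_m)
  samples_u <- c(sprintf("OSEmir%02d", seq_len(cfg$n_normal_mirna)),
                 sprintf("CEPImir%02d", seq_len(cfg$n_cancer_mirna)))
  groups_u <- stats::setNames(rep(c("normal", "cancer"),
                                  c(cfg$n_normal_mirna, cfg$n_cancer_mirna)), samples_u)

  ## --- planted miRNA edges ----------------------------------------------
  lfr <- log(cfg$mirna_fc_range)
  planted_fc <- exp(stats::runif(cfg$n_mirnas, lfr[1L], lfr[2L]))
  names(planted_fc) <- mir_up

  p_g <- stats::rbeta(cfg$n_genes, cfg$target_beta[1L], cfg$target_beta[2L])
  hit <- matrix(stats::runif(cfg$n_genes * cfg$n_mirnas), cfg$n_genes) <= p_g
  dimnames(hit) <- list(genes, mir_up)
  M_g <- rowSums(hit)

  edge_list <- lapply(mir_up, function(m) {
    tg <- genes[hit[, m]]
    if (!length(tg)) return(NULL)
    data.frame(mirna_id = m, gene_symbol = tg, stringsAsFactors = FALSE)
  })
  # repressors are themselves miRNA targets
  M_r <- stats::setNames(sample(3:12, cfg$n_repressors, replace = TRUE), reps)
  rep_edges <- do.call(rbind, lapply(reps, function(r) {
    data.frame(mirna_id = sample(mir_up, M_r[[r]]), gene_symbol = r,
               stringsAsFactors = FALSE)
  }))
  # decoy miRNAs target genes too (ignored downstream by selection)
  dec_edges <- do.call(rbind, lapply(c(mir_dec, mir_ncv, mir_mmu, mir_low), function(m) {
    tg <- genes[stats::runif(cfg$n_genes) <= cfg$decoy_target_prob]
    if (!length(tg)) return(NULL)
    data.frame(mirna_id = m, gene_symbol = tg, stringsAsFactors = FALSE)
  }))
  true_edges <- rbind(do.call(rbind, edge_list), rep_edges, dec_edges)
  true_edges$score <- -stats::runif(nrow(true_edges), 0.25, 1.0)

  ## --- planted regulons --------------------------------------------------
  member <- matrix(stats::runif(cfg$n_repressors * cfg$n_genes) <= cfg$regulon_frac,
                   cfg$n_repressors, dimnames = list(reps, genes))
  R_g <- colSums(member)
  regulons <- apply(member, 1L, function(row) genes[row], simplify = FALSE)
  primary <- apply(member, 2L, function(col) if (any(col)) reps[which(col)[1L]] else NA_character_)

  ## --- expected shifts and classes ---------------------------------------
  is_override <- stats::runif(cfg$n_genes) < cfg$override_frac & R_g >= 1L
  gamma_g <- stats::rgamma(cfg$n_genes, shape = 2, scale = cfg$gamma_rep / 2)
  gamma_g[is_override] <- stats::runif(sum(is_override),
                                       cfg$override_range[1L], cfg$override_range[2L])
  eps <- stats::rnorm(cfg$n_genes, 0, cfg$noise_sd)
  delta_g <- gamma_g * R_g - cfg$beta_mir * M_g + eps
  # tumor-activated background outside the selected-miRNA circuitry
  free <- M_g == 0L
  is_up_bg <- free & stats::runif(cfg$n_genes) < cfg$up_background_frac
  delta_g[is_up_bg] <- delta_g[is_up_bg] + stats::runif(sum(is_up_bg), 1.5, 4)

  delta_dec <- c(stats::runif(length(dec_up), 2, 4),
                 -stats::runif(length(dec_down), 2, 4),
                 rep(0, length(dec_ns)))
  delta_rep <- -(cfg$beta_mir * M_r + stats::runif(cfg$n_repressors, 0.5, 1.5))
  delta_all <- stats::setNames(c(delta_g, delta_dec, delta_rep), features)

  cls <- expected_class(delta_all, cfg$class_margin)

  ## --- mRNA expression ----------------------------------------------------
  base <- stats::setNames(stats::rnorm(length(features), 8, 1), features)
  base[low_genes] <- stats::rnorm(n_low, 2.5, 0.5)
  n_samp <- length(samples_m)
  latent <- matrix(stats::rnorm(cfg$n_repressors * n_samp),
                   cfg$n_repressors, n_samp, dimnames = list(reps, samples_m))
  # standardize each activity over the normal samples so the planted
  # anti-correlation strength is a condition, not a per-seed accident
  nrm <- groups_m == "normal"
  if (cfg$latent_activity_sd > 0 && sum(nrm) >= 2L) {
    mu <- rowMeans(latent[, nrm, drop = FALSE])
    sdv <- apply(latent[, nrm, drop = FALSE], 1L, stats::sd)
    latent <- (latent - mu) / sdv * cfg$latent_activity_sd
  } else {
    latent <- latent * cfg$latent_activity_sd
  }
  load <- matrix(0, length(features), n_samp, dimnames = list(features, samples_m))
  for (r in reps) load[r, ] <- latent[r, ]
  with_prim <- genes[!is.na(primary)]
  if (length(with_prim)) load[with_prim, ] <- -latent[primary[with_prim], , drop = FALSE]
  shift <- outer(delta_all, as.numeric(groups_m == "cancer"))
  expr <- base + shift + load +
    matrix(stats::rnorm(length(features) * n_samp, 0, cfg$noise_sd),
           length(features), n_samp)
  dimnames(expr) <- list(features, samples_m)
  pres <- matrix(stats::runif(length(expr)), nrow(expr)) <
    stats::plogis((expr - 5) * 1.5)
  dimnames(pres) <- dimnames(expr)

  mrna <- structure(list(values = expr, feature_ids = features,
                         sample_ids = samples_m, scale = "log2",
                         group_of = groups_m, present = pres),
                    class = "ExpressionMatrix")

  ## --- miRNA expression ---------------------------------------------------
  mbase <- stats::setNames(stats::rnorm(length(mirnas), 7, 1), mirnas)
  mbase[mir_low] <- stats::rnorm(length(mir_low), 1.5, 0.5)
  mshift <- stats::setNames(rep(0, length(mirnas)), mirnas)
  mshift[mir_up] <- log2(planted_fc)
  mexpr <- mbase + outer(mshift, as.numeric(groups_u == "cancer")) +
    matrix(stats::rnorm(length(mirnas) * length(samples_u), 0, cfg$mirna_noise_sd),
           length(mirnas))
  dimnames(mexpr) <- list(mirnas, samples_u)
  mpres <- matrix(stats::runif(length(mexpr)), nrow(mexpr)) <
    stats::plogis((mexpr - 4) * 2)
  dimnames(mpres) <- dimnames(mexpr)
  mirna_mat <- structure(list(values = mexpr, feature_ids = mirnas,
                              sample_ids = samples_u, scale = "log2",
                              group_of = groups_u, present = mpres),
                         class = "ExpressionMatrix")

  ## --- prediction table (true edges + above-cutoff noise rows) ------------
  n_noise <- 500L
  noise_rows <- data.frame(
    mirna_id = sample(mirnas, n_noise, replace = TRUE),
    gene_symbol = sample(genes, n_noise, replace = TRUE),
    score = -stats::runif(n_noise, 0.01, 0.19), stringsAsFactors = FALSE)
  boundary_rows <- data.frame(
    mirna_id = sample(mir_up, 10L, replace = TRUE),
    gene_symbol = sample(genes, 10L), score = -0.2, stringsAsFactors = FALSE)
  predictions <- rbind(true_edges, noise_rows, boundary_rows)

  ## --- files --------------------------------------------------------------
  paths <- list(
    mrna_expression = file.path(dir, "mrna_expression.tsv"),
    mrna_present = file.path(dir, "mrna_present.tsv"),
    mirna_expression = file.path(dir, "mirna_expression.tsv"),
    mirna_present = file.path(dir, "mirna_present.tsv"),
    predictions = file.path(dir, "predictions.tsv"),
    regulons_gmt = file.path(dir, "regulons.gmt"),
    repressor_candidates = file.path(dir, "repressor_candidates.txt"),
    conserved_mirnas = file.path(dir, "conserved_mirnas.txt"),
    sample_groups = file.path(dir, "sample_groups.tsv"),
    truth_gene_effects = file.path(dir, "truth_gene_effects.tsv"),
    truth_mirna_edges = file.path(dir, "truth_mirna_edges.tsv"),
    truth_regulons = file.path(dir, "truth_regulons.tsv"),
    truth_mirnas = file.path(dir, "truth_mirnas.tsv"),
    truth_corr_pairs = file.path(dir, "truth_corr_pairs.tsv"),
    truth_repressors = file.path(dir, "truth_repressors.txt"))

  write_expression_matrix(mrna, paths$mrna_expression, paths$mrna_present)
  write_expression_matrix(mirna_mat, paths$mirna_expression, paths$mirna_present)
  write_tsv_plain(predictions, paths$predictions)

  gmt_lines <- vapply(seq_along(reps), function(i) {
    paste(c(sprintf("V$%s_01", reps[i]), "synthetic regulon", regulons[[i]]),
          collapse = "\t")
  }, character(1L))
  writeLines(gmt_lines, paths$regulons_gmt)

  go_terms <- c("GO:0045892", "GO:0000122", "GO:0010944", "GO:0032088", "GO:0008156")
  go_genes <- c(reps, dec_up, dec_down, dec_ns)
  writeLines(paste(go_genes,
                   go_terms[(seq_along(go_genes) - 1L) %% length(go_terms) + 1L],
                   sep = "\t"),
             paths$repressor_candidates)
  writeLines(conserved, paths$conserved_mirnas)
  write_tsv_plain(data.frame(sample_id = c(samples_m, samples_u),
                             assay = rep(c("mrna", "mirna"),
                                         c(length(samples_m), length(samples_u))),
                             group = c(unname(groups_m), unname(groups_u)),
                             stringsAsFactors = FALSE),
                  paths$sample_groups)

  corr_pairs <- data.frame(repressor = primary[with_prim], target = with_prim,
                           stringsAsFactors = FALSE)
  corr_pairs <- corr_pairs[order(corr_pairs$repressor, corr_pairs$target), ]
  rownames(corr_pairs) <- NULL

  gene_truth <- data.frame(
    gene_symbol = features,
    base = base,
    delta_expected = delta_all,
    mirna_count = c(M_g, rep(0L, length(delta_dec)), unname(M_r)),
    repressor_count = c(R_g, rep(0L, length(delta_dec)), rep(0L, cfg$n_repressors)),
    primary_repressor = c(primary, rep(NA_character_, length(delta_dec) + cfg$n_repressors)),
    expected_class = as.character(cls),
    stringsAsFactors = FALSE, row.names = NULL)

  write_tsv_plain(gene_truth, paths$truth_gene_effects)
  write_tsv_plain(true_edges[order(true_edges$mirna_id, true_edges$gene_symbol), ],
                  paths$truth_mirna_edges)
  write_tsv_plain(do.call(rbind, lapply(reps, function(r) {
    if (!length(regulons[[r]])) return(NULL)
    data.frame(repressor = r, target = regulons[[r]], stringsAsFactors = FALSE)
  })), paths$truth_regulons)
  write_tsv_plain(data.frame(mirna_id = mir_up, planted_fc = unname(planted_fc),
                             stringsAsFactors = FALSE), paths$truth_mirnas)
  write_tsv_plain(corr_pairs, paths$truth_corr_pairs)
  writeLines(reps, paths$truth_repressors)

  structure(list(config = cfg, paths = paths,
                 mirna_up = mir_up, mirna_planted_fc = planted_fc,
                 mirna_edges = true_edges, regulons = regulons,
                 repressors = reps, go_list = go_genes,
                 corr_pairs = corr_pairs, gene_truth = gene_truth,
                 group_map = c(groups_m, groups_u),
                 mrna = mrna, mirna = mirna_mat),
            class = "TruthBundle")
}
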