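#' Default pipeline configuration values
#'
#' @return Named list of every tunable the pipeline understands, at its
#'   default: thresholds, bin schemes, permutation count and seed slot.
#' @export
default_run_config <- function() {
  list(
    score_cutoff = -0.2,
    fdr_threshold = 0.055,
    mirna_fc_min = 6,
    mirna_p_max = 0.03,
    present_fraction_mrna = 0.60,   # strict >
    present_fraction_mirna = 0.65,  # non-strict >=
    r_threshold = -0.8,
    n_permutations = 1000L,
    bin_edges = c(1L, 6L, 11L, 16L),
    max_mirna_count = 31L,
    repressor_split_edges = c(1L, 2L, 6L),
    repressor_split_max = 45L,
    seed = NULL,
    out_dir = NULL)
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- default_run_config()
  params <- config[setdiff(names(config), "paths")]
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  merged <- utils::modifyList(defaults, params)
  if (is.null(merged$seed)) stop("config must set a seed")
  need_paths <- c("mrna_expression", "mirna_expression", "predictions",
                  "regulons_gmt", "repressor_candidates", "sample_groups")
  missing_p <- setdiff(need_paths, names(config$paths))
  if (length(missing_p)) stop("config$paths missing: ", paste(missing_p, collapse = ", "))
  for (p in names(config$paths)) {
    if (!file.exists(config$paths[[p]])) {
      stop("input file for '", p, "' not found: ", config$paths[[p]])
    }
  }
  merged$paths <- config$paths
  merged
}

read_group_map <- function(path, assay) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  g <- g[g$assay == assay, , drop = FALSE]
  stats::setNames(g$group, g$sample_id)
}

#' Run the full override-model pipeline from a config
#'
#' Executes every stage in dependency order — differential expression on
#' mRNA and miRNA arrays, miRNA selection, target classification, repressor
#' selection, TRANSFAC and correlation edge layers, network assembly, and
#' the stratified trend and enrichment statistics — writing all tables plus
#' a JSON run report into `out_dir`. Rerunning with an identical config and
#' seed reproduces identical outputs.
#'
#' @param config Path to a YAML config file, or an equivalent list. Needs a
#'   `paths` block (see [generate_bundle()] for the file roster) plus any
#'   overrides of [default_run_config()]; `seed` and `out_dir` are required.
#' @return A `RunReport` list (invisibly contains all intermediate objects
#'   under `$objects`).
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  if (is.null(cfg$out_dir)) stop("config must set out_dir")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  elapsed <- list()
  tick <- function(stage, start) {
    elapsed[[stage]] <<- round(as.numeric(Sys.time() - start, units = "secs"), 3)
    message("[", stage, "] done (", elapsed[[stage]], " s)")
  }

  ## stage: differential expression -----------------------------------------
  s <- Sys.time()
  gm_m <- read_group_map(cfg$paths$sample_groups, "mrna")
  gm_u <- read_group_map(cfg$paths$sample_groups, "mirna")
  mrna <- read_expression_matrix(cfg$paths$mrna_expression, gm_m, "log2",
                                 present = cfg$paths$mrna_present)
  mirna <- read_expression_matrix(cfg$paths$mirna_expression, gm_u, "log2",
                                  present = cfg$paths$mirna_present)
  mrna_f <- present_filter(mrna, cfg$present_fraction_mrna, strict = TRUE)
  mirna_f <- present_filter(mirna, cfg$present_fraction_mirna, strict = FALSE)
  de_mrna <- differential_expression(mrna_f, cfg$n_permutations,
                                     cfg$fdr_threshold, seed = cfg$seed,
                                     p_method = "permutation")
  # 3+3 miRNA design: permutation floor (0.05) exceeds p_max, use Student t
  de_mirna <- differential_expression(mirna_f, cfg$n_permutations,
                                      cfg$fdr_threshold, seed = cfg$seed,
                                      p_method = "student")
  sel_report <- selection_report(length(mrna$feature_ids),
                                 length(mrna_f$feature_ids), de_mrna)
  message(sprintf(
    "[diffexpr] mRNA features %d -> present %d -> DEGs %d (%d up, %d down)",
    sel_report$input, sel_report$present, sel_report$significant,
    sel_report$up, sel_report$down))
  tick("diffexpr", s)

  ## stage: miRNA selection and target classification -----------------------
  s <- Sys.time()
  conserved <- if (!is.null(cfg$paths$conserved_mirnas)) {
    readLines(cfg$paths$conserved_mirnas, warn = FALSE)
  } else NULL
  selected <- select_mirnas(de_mirna, conserved,
                            fc_min = cfg$mirna_fc_min, p_max = cfg$mirna_p_max)
  predictions <- read_target_predictions(cfg$paths$predictions,
                                         score_cutoff = cfg$score_cutoff)
  tc <- classify_targets(predictions, de_mrna, selected)
  tc_summary <- summarize_classification(tc)
  rp <- repressive_potential(predictions, de_mrna, selected)
  tick("target_class", s)

  ## stage: repressors -------------------------------------------------------
  s <- Sys.time()
  go_list <- read_gene_list(cfg$paths$repressor_candidates)
  sel_pred <- predictions[predictions$mirna_id %in% selected, , drop = FALSE]
  mirna_targets <- unique(sel_pred$gene_symbol)
  repsel <- select_repressors(go_list, de_mrna, mirna_targets)
  regulons <- read_gmt(cfg$paths$regulons_gmt)
  tp <- transfac_pairs(regulons, repsel$genes, de_mrna, mirna_targets)
  degs <- de_mrna$feature_id[de_mrna$direction != "ns"]
  candidates <- intersect(toupper(degs), mirna_targets)
  corr <- infer_correlation_regulon(mrna_f, repsel$genes, candidates,
                                    r_threshold = cfg$r_threshold)
  tick("repressors", s)

  ## stage: network -----------------------------------------------------------
  s <- Sys.time()
  # repressor layer filtered to DEGs only: the miRNA-target requirement is
  # enforced by intersection with the miRNA edge layer, and regulon DEGs
  # with no miRNA edge form the repressor-only group
  degs_all <- toupper(de_mrna$feature_id[de_mrna$direction != "ns"])
  deg_regulon_edges <- do.call(rbind, lapply(
    intersect(repsel$genes, names(regulons)), function(r) {
      g <- setdiff(intersect(regulons[[r]], degs_all), r)
      if (!length(g)) return(NULL)
      data.frame(repressor = r, target = g, stringsAsFactors = FALSE)
    }))
  if (is.null(deg_regulon_edges)) {
    deg_regulon_edges <- data.frame(repressor = character(0), target = character(0))
  }
  net <- build_tom_network(sel_pred, deg_regulon_edges, tc)
  tick("tom_network", s)

  ## stage: stratified statistics ---------------------------------------------
  s <- Sys.time()
  # motif-level analysis: mutual targets, plus repressor-only group
  tc_mutual <- tc[tc$gene_symbol %in% net$mutual_targets, , drop = FALSE]
  rep_only <- net$repressor_only[net$repressor_only %in% de_mrna$feature_id]
  rep_only_cls <- as.character(de_mrna$direction[match(rep_only, de_mrna$feature_id)])
  rep_only_cls <- ifelse(rep_only_cls == "up", "PC",
                         ifelse(rep_only_cls == "down", "IC", "NC"))
  strat_motif <- bin_by_mirna_count(tc_mutual, cfg$bin_edges, cfg$max_mirna_count,
                                    repressor_only_group = rep_only,
                                    repressor_only_classes = rep_only_cls)
  trend_motif <- chi_square_trend(strat_motif$n_PC, strat_motif$n_genes,
                                  strat_motif$score)
  # global analysis: every classified miRNA target
  strat_global <- bin_by_mirna_count(tc, cfg$bin_edges, cfg$max_mirna_count)
  trend_global <- chi_square_trend(strat_global$n_PC, strat_global$n_genes,
                                   strat_global$score)
  # repressor multiplicity within the mutual-target set
  rep_counts <- table(tp$edges$target)
  split_res <- if (nrow(tc_mutual)) {
    repressor_multiplicity_split(
      tc_mutual,
      stats::setNames(as.integer(rep_counts), names(rep_counts)),
      split_edges = cfg$repressor_split_edges,
      split_max = cfg$repressor_split_max,
      bin_edges = cfg$bin_edges, max_count = cfg$max_mirna_count)
  } else NULL

  # enrichment: miRNA targets vs downregulated genes over the DEG universe
  deg_tab <- de_mrna[de_mrna$direction != "ns", , drop = FALSE]
  is_target <- deg_tab$feature_id %in% mirna_targets
  enr_mirna <- hypergeom_upper_tail(
    N = nrow(deg_tab), K = sum(deg_tab$direction == "down"),
    n = sum(is_target),
    k = sum(is_target & deg_tab$direction == "down"))
  # enrichment: correlation-inferred repressor targets vs upregulated genes,
  # over the DEG-and-miRNA-target universe
  cand_tab <- deg_tab[is_target, , drop = FALSE]
  is_rt <- cand_tab$feature_id %in% unique(corr$edges$target)
  enr_rep <- hypergeom_upper_tail(
    N = nrow(cand_tab), K = sum(cand_tab$direction == "up"),
    n = sum(is_rt),
    k = sum(is_rt & cand_tab$direction == "up"))
  tick("stratification_stats", s)

  ## artifacts -----------------------------------------------------------------
  out <- function(f) file.path(cfg$out_dir, f)
  write_tsv_plain(de_mrna, out("de_mrna.tsv"))
  write_tsv_plain(de_mirna, out("de_mirna.tsv"))
  write_tsv_plain(tc, out("target_classification.tsv"))
  write_tsv_plain(tc_summary, out("classification_summary.tsv"))
  write_tsv_plain(rp$per_mirna, out("repressive_potential.tsv"))
  write_tsv_plain(corr$edges, out("correlation_edges.tsv"))
  write_network_sif(net$edges, out("tom_network.sif"))
  ffl_idx <- do.call(rbind, lapply(net$ffl, function(f) {
    data.frame(target = f$target, n_mirnas = length(f$targeting_mirnas),
               n_repressors = length(f$repressors),
               n_shared_mirnas = length(f$shared_mirnas),
               class = f$class, stringsAsFactors = FALSE)
  }))
  if (!is.null(ffl_idx)) write_tsv_plain(ffl_idx, out("ffl_index.tsv"))
  write_tsv_plain(as.data.frame(strat_motif), out("stratified_motif.tsv"))
  write_tsv_plain(as.data.frame(strat_global), out("stratified_global.tsv"))

  report <- list(
    counts = list(
      mrna_features = length(mrna$feature_ids),
      mrna_present = length(mrna_f$feature_ids),
      degs = sel_report$significant,
      up = sel_report$up, down = sel_report$down,
      pct_up = sel_report$pct_up, pct_down = sel_report$pct_down,
      mirna_features = length(mirna$feature_ids),
      mirna_present = length(mirna_f$feature_ids),
      selected_mirnas = length(selected),
      repressor_candidates = repsel$candidate_count,
      repressor_down = repsel$downregulated_count,
      repressor_final = repsel$mirna_targeted_count,
      transfac_repressors = length(tp$active_repressors),
      mutual_targets = length(net$mutual_targets),
      repressor_only = length(net$repressor_only),
      correlation_targets = length(unique(corr$edges$target)),
      correlation_non_targets = length(corr$non_targets),
      classified = nrow(tc),
      class_IC = sum(tc$class == "IC"),
      class_PC = sum(tc$class == "PC"),
      class_NC = sum(tc$class == "NC")),
    classification_summary = as.list(tc_summary),
    repression = list(mean_frac_down = rp$mean_frac_down,
                      background_frac_down = rp$background_frac_down),
    trends = list(motif = trend_motif[c("X2", "p")],
                  global = trend_global[c("X2", "p")]),
    enrichment = list(
      mirna_targets_down = enr_mirna[c("N", "K", "n", "k", "log10_p")],
      repressor_targets_up = enr_rep[c("N", "K", "n", "k", "log10_p")]),
    seed = cfg$seed)
  # the JSON report is fully determined by config + seed (timings kept out
  # so identical runs write byte-identical reports)
  jsonlite::write_json(report, out("run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$elapsed_s <- elapsed
  report$objects <- list(de_mrna = de_mrna, de_mirna = de_mirna,
                         selected_mirnas = selected, predictions = predictions,
                         classification = tc, repressors = repsel,
                         transfac = tp, correlation = corr, network = net,
                         strat_motif = strat_motif, strat_global = strat_global,
                         split = split_res, enrichment = list(enr_mirna, enr_rep),
                         repressive = rp)
  class(report) <- "RunReport"
  invisible(report)
}

#' Generate a ready-to-run synthetic workspace
#'
#' Builds a [generator_config()] from the `generator` section of a config
#' list/YAML, writes the full input bundle plus truth tables, and returns
#' the bundle together with a pipeline config pointing at it.
#'
#' @param config List or YAML path with a `generator` section (fields of
#'   [generator_config()]) and a `dir` entry.
#' @return List with `bundle` (the `TruthBundle`) and `run_config` (a list
#'   directly usable by [run_pipeline()] after setting `out_dir`).
#' @export
make_synthetic <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$dir))
  gen <- config$generator
  if (is.null(gen) || is.null(gen$seed)) stop("config needs generator$seed")
  cfg <- do.call(generator_config, gen)
  bundle <- generate_bundle(cfg, config$dir)
  run_config <- list(
    paths = bundle$paths[c("mrna_expression", "mrna_present", "mirna_expression",
                           "mirna_present", "predictions", "regulons_gmt",
                           "repressor_candidates", "conserved_mirnas",
                           "sample_groups")],
    seed = cfg$seed)
  list(bundle = bundle, run_config = run_config)
}
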