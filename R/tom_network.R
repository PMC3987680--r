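#' Assemble the TOM feed-forward network
#'
#' Joins the three edge layers — upregulated miRNA -> gene predictions,
#' repressor -> gene regulation, and the per-gene IC/PC/NC classification —
#' into the override network. A mutual target has at least one edge of each
#' type; regulon genes with no miRNA edge form the repressor-only group.
#' Each mutual target gets a feed-forward-loop record listing its targeting
#' miRNAs, its repressors, and the shared miRNAs that target both the gene
#' and at least one of its repressors (the motif's defining triangle).
#'
#' @param mirna_edges data.frame with columns `mirna_id`, `gene_symbol`
#'   (predictions restricted to the selected upregulated miRNAs).
#' @param repressor_edges data.frame with columns `repressor`, `target`
#'   (from the TRANSFAC or the correlation layer; pick one, never merged).
#' @param classification A `TargetClassification`.
#' @return A `TomNetwork` list: `mirnas`, `repressors`, `mutual_targets`,
#'   `repressor_only`, `edges` (typed source/relation/target), and `ffl`
#'   (named list of FFLRecord lists).
#' @export
build_tom_network <- function(mirna_edges, repressor_edges, classification) {
  mirna_edges$gene_symbol <- toupper(mirna_edges$gene_symbol)
  repressor_edges$target <- toupper(repressor_edges$target)
  repressor_edges$repressor <- toupper(repressor_edges$repressor)
  self <- repressor_edges$repressor == repressor_edges$target
  if (any(self)) {
    message("excluding ", sum(self), " self-regulation edge(s)")
    repressor_edges <- repressor_edges[!self, , drop = FALSE]
  }
  mir_genes <- unique(mirna_edges$gene_symbol)
  reg_genes <- unique(repressor_edges$target)
  rep_universe <- unique(c(reg_genes, repressor_edges$repressor))
  if (nrow(mirna_edges) && nrow(repressor_edges) &&
      !length(intersect(mir_genes, rep_universe))) {
    stop("miRNA and repressor edge layers share no genes; check symbol normalization")
  }
  mutual <- sort(intersect(mir_genes, reg_genes))
  repressor_only <- sort(setdiff(reg_genes, mir_genes))
  mirs_of <- split(mirna_edges$mirna_id, mirna_edges$gene_symbol)
  reps_of <- split(repressor_edges$repressor, repressor_edges$target)
  cls_of <- stats::setNames(as.character(classification$class),
                            classification$gene_symbol)
  ffl <- lapply(mutual, function(g) {
    tm <- sort(unique(mirs_of[[g]]))
    rp <- sort(unique(reps_of[[g]]))
    rep_mirs <- sort(unique(unlist(mirs_of[rp], use.names = FALSE)))
    list(target = g,
         targeting_mirnas = tm,
         repressors = rp,
         shared_mirnas = intersect(tm, rep_mirs),
         class = if (g %in% names(cls_of)) cls_of[[g]] else NA_character_)
  })
  names(ffl) <- mutual
  edges <- rbind(
    data.frame(source = mirna_edges$mirna_id,
               relation = rep("mirna_targets", nrow(mirna_edges)),
               target = mirna_edges$gene_symbol, stringsAsFactors = FALSE),
    data.frame(source = repressor_edges$repressor,
               relation = rep("represses", nrow(repressor_edges)),
               target = repressor_edges$target, stringsAsFactors = FALSE))
  edges <- unique(edges[order(edges$source, edges$relation, edges$target), , drop = FALSE])
  rownames(edges) <- NULL
  structure(list(mirnas = sort(unique(mirna_edges$mirna_id)),
                 repressors = sort(unique(repressor_edges$repressor)),
                 mutual_targets = mutual,
                 repressor_only = repressor_only,
                 edges = edges, ffl = ffl),
            class = "TomNetwork")
}

#' @export
print.TomNetwork <- function(x, ...) {
  cat("TomNetwork:", length(x$mirnas), "miRNAs,", length(x$repressors),
      "repressors,", length(x$mutual_targets), "mutual targets (+",
      length(x$repressor_only), "repressor-only )\n")
  invisible(x)
}

#' Query the motif context of one gene
#'
#' Returns the gene's feed-forward-loop record with a human-readable
#' narrative, and the per-gene subnetwork as a SIF-ready edge table.
#'
#' @param network A `TomNetwork`.
#' @param symbol Gene symbol.
#' @return List with `record` (the FFLRecord, or a non-mutual explanation),
#'   `narrative` (character) and `edges` (subgraph data.frame).
#' @export
query_gene <- function(network, symbol) {
  symbol <- toupper(symbol)
  known <- unique(c(network$mutual_targets, network$repressor_only,
                    network$edges$target, network$edges$source))
  if (!symbol %in% known) {
    d <- utils::adist(symbol, known)
    near <- known[order(d)][seq_len(min(3L, length(known)))]
    stop("unknown gene '", symbol, "'; nearest matches: ",
         paste(near, collapse = ", "))
  }
  sub <- network$edges[network$edges$target == symbol |
                         network$edges$source == symbol, , drop = FALSE]
  if (symbol %in% names(network$ffl)) {
    rec <- network$ffl[[symbol]]
    # pull in the miRNA->repressor legs closing the triangles
    legs <- network$edges[network$edges$relation == "mirna_targets" &
                            network$edges$target %in% rec$repressors, , drop = FALSE]
    sub <- unique(rbind(sub, legs))
    narrative <- sprintf(
      paste0("%s is a mutual target (class %s): targeted by %d upregulated miRNA(s) ",
             "[%s] and repressed by %d downregulated repressor(s) [%s]; ",
             "%d miRNA(s) [%s] target both %s and at least one of its repressors, ",
             "closing the override feed-forward loop."),
      rec$target, rec$class, length(rec$targeting_mirnas),
      paste(rec$targeting_mirnas, collapse = ", "),
      length(rec$repressors), paste(rec$repressors, collapse = ", "),
      length(rec$shared_mirnas), paste(rec$shared_mirnas, collapse = ", "),
      rec$target)
  } else {
    in_mir <- symbol %in% network$edges$target[network$edges$relation == "mirna_targets"]
    in_rep <- symbol %in% network$edges$target[network$edges$relation == "represses"]
    rec <- list(target = symbol, targeting_mirnas = character(0),
                repressors = character(0), shared_mirnas = character(0),
                class = NA_character_)
    narrative <- sprintf(
      "%s is not a mutual target: it has %s edges only, so no override motif applies.",
      symbol,
      if (in_mir && !in_rep) "miRNA" else if (in_rep && !in_mir) "repressor"
      else "no regulatory")
  }
  rownames(sub) <- NULL
  list(record = rec, narrative = narrative, edges = sub)
}
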