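#' Read a feature-by-sample expression matrix
#'
#' Parses a tab-delimited expression table (first column feature identifiers,
#' header row sample identifiers) and attaches group labels and present/absent
#' detection flags, producing the `ExpressionMatrix` object every downstream
#' stage consumes.
#'
#' @param path Path to a tab-delimited file; first column feature ids, header
#'   row sample ids.
#' @param group_map Named character vector mapping every sample id to
#'   `"normal"` or `"cancer"`.
#' @param scale_flag Either `"log2"` or `"linear"`; must be set before any
#'   fold-change computation downstream.
#' @param present Optional logical matrix of detection (present/absent) calls
#'   with the same dimensions and dimnames as the expression values, or a path
#'   to a companion TSV of 0/1 flags in the same layout. If `NULL`, flags are
#'   derived as `value > present_floor`.
#' @param present_floor Expression floor used to derive present flags when no
#'   companion data is given.
#' @return An object of class `ExpressionMatrix`: a list with `values`
#'   (numeric matrix), `feature_ids`, `sample_ids`, `scale`, `group_of`
#'   (named character vector) and `present` (logical matrix). Features with
#'   all values missing are dropped with a message.
#' @export
read_expression_matrix <- function(path, group_map, scale_flag = c("log2", "linear"),
                                   present = NULL, present_floor = 0) {
  scale_flag <- match.arg(scale_flag)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression file needs a feature column plus >=1 sample column: ", path)
  feature_ids <- as.character(raw[[1L]])
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample id(s) in ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  vals <- raw[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))) & !is.na(vals[[j]]))
      stop("non-numeric cell in column '", sample_ids[j], "'",
           if (length(bad)) paste0(", row '", feature_ids[bad[1L]], "'") else "")
    }
  }
  values <- as.matrix(vals)
  dimnames(values) <- list(feature_ids, sample_ids)

  unknown <- setdiff(sample_ids, names(group_map))
  if (length(unknown)) stop("sample(s) missing from group_map: ", paste(unknown, collapse = ", "))
  group_of <- group_map[sample_ids]
  if (!all(group_of %in% c("normal", "cancer"))) {
    stop("group_map values must be 'normal' or 'cancer'")
  }
  if (length(unique(group_of)) < 2L) stop("both groups must be non-empty")

  all_missing <- rowSums(!is.na(values)) == 0L
  if (any(all_missing)) {
    message("dropping ", sum(all_missing), " feature(s) with all values missing")
    values <- values[!all_missing, , drop = FALSE]
    feature_ids <- feature_ids[!all_missing]
  }

  if (is.character(present) && length(present) == 1L) {
    ptab <- utils::read.delim(present, header = TRUE, check.names = FALSE)
    pm <- as.matrix(ptab[, -1L, drop = FALSE]) > 0
    dimnames(pm) <- list(as.character(ptab[[1L]]), colnames(ptab)[-1L])
    present <- pm[feature_ids, sample_ids, drop = FALSE]
  } else if (is.null(present)) {
    present <- !is.na(values) & values > present_floor
  }
  stopifnot(identical(dim(present), dim(values)))
  dimnames(present) <- dimnames(values)

  structure(list(values = values, feature_ids = feature_ids,
                 sample_ids = sample_ids, scale = scale_flag,
                 group_of = group_of, present = present),
            class = "ExpressionMatrix")
}

#' Write an expression matrix (with companion present-call file)
#'
#' Inverse of [read_expression_matrix()]; numeric values are written with
#' full (round-trip) precision so write-then-read reproduces the matrix
#' exactly.
#'
#' @param mat An `ExpressionMatrix`.
#' @param path Output TSV path for expression values.
#' @param present_path Optional output TSV path for 0/1 present flags.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, present_path = NULL) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("feature_id", mat$sample_ids), collapse = "\t"), con)
  body <- apply(mat$values, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(mat$feature_ids, body, sep = "\t"), con)
  if (!is.null(present_path)) {
    pcon <- file(present_path, "w")
    writeLines(paste(c("feature_id", mat$sample_ids), collapse = "\t"), pcon)
    pbody <- apply(mat$present * 1L, 1L, paste, collapse = "\t")
    writeLines(paste(mat$feature_ids, pbody, sep = "\t"), pcon)
    close(pcon)
  }
  invisible(path)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "features x", ncol(x$values),
      "samples (", sum(x$group_of == "normal"), "normal /",
      sum(x$group_of == "cancer"), "cancer ), scale =", x$scale, "\n")
  invisible(x)
}

# Default TRANSFAC-style set-name parser: "V$YY1_02" -> "YY1".
# Returns NA for names that do not match the motif pattern.
transfac_name_parser <- function(set_names) {
  m <- regmatches(set_names, regexec("^V\\$([A-Za-z0-9-]+)_", set_names))
  vapply(m, function(g) if (length(g) == 2L) toupper(g[2L]) else NA_character_,
         character(1L))
}

#' Read a GMT gene-set file into a regulon table
#'
#' Each GMT line is `name TAB description TAB member TAB member ...`. Set
#' names are mapped to regulator gene symbols by `name_parser` (default:
#' extract the token between `V$` and the first underscore, the TRANSFAC
#' motif convention). Members are uppercased; a member equal to its own
#' regulator symbol (self-loop) is removed and counted.
#'
#' @param path GMT file path.
#' @param name_parser Function mapping a character vector of set names to
#'   gene symbols (`NA` where unparseable).
#' @return A `RegulonTable`: named list of character vectors (regulator
#'   symbol -> target set), with attributes `provenance` (`"transfac"`),
#'   `unparsed` (count of sets kept under their raw name) and `self_loops`
#'   (count removed).
#' @export
read_gmt <- function(path, name_parser = transfac_name_parser) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) warning(sum(short), " GMT line(s) with <3 fields skipped")
  fields <- fields[!short]
  raw_names <- vapply(fields, `[[`, character(1L), 1L)
  symbols <- name_parser(raw_names)
  unparsed <- sum(is.na(symbols))
  if (unparsed) warning(unparsed, " GMT set name(s) not parseable to a symbol; kept under raw name")
  keys <- ifelse(is.na(symbols), raw_names, symbols)
  self_loops <- 0L
  regulons <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    members <- toupper(trimws(fields[[i]][-(1:2)]))
    members <- unique(members[nzchar(members)])
    if (keys[i] %in% members) {
      self_loops <- self_loops + 1L
      members <- setdiff(members, keys[i])
    }
    regulons[[i]] <- members
  }
  names(regulons) <- keys
  # merge duplicate keys (several motifs for one TF)
  if (anyDuplicated(keys)) {
    regulons <- tapply(regulons, keys, function(l) unique(unlist(l)), simplify = FALSE)
    regulons <- regulons[unique(keys)]
  }
  structure(regulons, class = "RegulonTable", provenance = "transfac",
            unparsed = unparsed, self_loops = self_loops)
}

#' Read a miRNA target-prediction table and apply the score filter
#'
#' Reads a tab-delimited prediction table (mirSVR-style) and keeps only rows
#' with score strictly less than `score_cutoff` (more negative = stronger
#' predicted repression). Duplicate (miRNA, gene) rows are collapsed keeping
#' the minimum (strongest) score.
#'
#' @param path TSV path with a header row.
#' @param mirna_column,gene_column,score_column Column names.
#' @param score_cutoff Retain rows with `score < score_cutoff` (strict).
#' @return A `TargetPredictionTable`: data.frame with columns `mirna_id`,
#'   `gene_symbol` (uppercased), `score`.
#' @export
read_target_predictions <- function(path, mirna_column = "mirna_id",
                                    gene_column = "gene_symbol",
                                    score_column = "score",
                                    score_cutoff = -0.2) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c(mirna_column, gene_column, score_column)
  missing_cols <- setdiff(need, colnames(tab))
  if (length(missing_cols)) {
    stop("prediction table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(mirna_id = as.character(tab[[mirna_column]]),
                    gene_symbol = toupper(trimws(as.character(tab[[gene_column]]))),
                    score = as.numeric(tab[[score_column]]),
                    stringsAsFactors = FALSE)
  if (anyNA(out$score)) stop("non-finite score(s) in prediction table")
  out <- out[out$score < score_cutoff, , drop = FALSE]
  if (!nrow(out)) warning("no predictions survive score < ", score_cutoff)
  # collapse duplicates to the strongest (minimum) score
  key <- paste(out$mirna_id, out$gene_symbol, sep = "\r")
  if (anyDuplicated(key)) {
    o <- order(key, out$score)
    out <- out[o, , drop = FALSE]
    out <- out[!duplicated(key[o]), , drop = FALSE]
  }
  out <- out[order(out$mirna_id, out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("TargetPredictionTable", "data.frame")
  out
}

#' Read a flat gene list
#'
#' One symbol per line, optional TAB-separated annotation column. Symbols are
#' uppercased; duplicates after case normalisation are dropped.
#'
#' @param path File path.
#' @return Character vector of unique uppercase symbols; any annotation is
#'   attached as a named `annotation` attribute.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  syms <- toupper(trimws(vapply(parts, `[[`, character(1L), 1L)))
  ann <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else NA_character_,
                character(1L))
  keep <- !duplicated(syms)
  structure(syms[keep], annotation = stats::setNames(ann[keep], syms[keep]))
}

#' Export typed network edges as SIF
#'
#' Writes `source TAB relation TAB target` lines in deterministic
#' lexicographic order, the simple-interaction format Cytoscape reads.
#'
#' @param edges data.frame with columns `source`, `relation`, `target`;
#'   relations are typically `mirna_targets` or `represses`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_sif <- function(edges, path) {
  if (nrow(edges)) {
    stopifnot(all(c("source", "relation", "target") %in% colnames(edges)))
    lines <- paste(edges$source, edges$relation, edges$target, sep = "\t")
    lines <- sort(lines)
  } else {
    lines <- character(0L)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a SIF file back into an edge data.frame
#' @param path SIF path.
#' @return data.frame with `source`, `relation`, `target`.
#' @export
read_network_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(source = character(0), relation = character(0),
                      target = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(source = vapply(parts, `[[`, "", 1L),
             relation = vapply(parts, `[[`, "", 2L),
             target = vapply(parts, `[[`, "", 3L),
             stringsAsFactors = FALSE)
}
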