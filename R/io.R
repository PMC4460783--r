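# On-disk formats: tab-separated expression matrices, TargetScan context-score
# tables (or pre-aggregated weight tables), GMT gene-set files, sample
# annotation tables and the results table.

#' Read a tab-separated expression matrix
#'
#' Expects a header row of sample identifiers and a first column of feature
#' identifiers (genes or miRNAs), i.e. features in rows. Some public matrices
#' ship transposed (samples in rows); set `transpose = TRUE` for those —
#' orientation is never guessed.
#'
#' Missing cells and non-numeric cells are hard errors naming the offending
#' feature and sample: the downstream Spearman ranking assumes complete
#' expression vectors, so silent imputation or row dropping is never done.
#'
#' @param path Path to a UTF-8 TSV file.
#' @param transpose If `TRUE`, the file holds samples in rows and features in
#'   columns; the matrix is transposed after parsing.
#' @return A numeric matrix, features x samples, with unique dimnames.
#' @export
read_expression_tsv <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", na.strings = NULL)
  if (ncol(df) < 2L)
    stop("expression TSV needs a feature-id column plus at least one sample: ",
         path, call. = FALSE)
  feature_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  # locate missing/non-numeric cells before conversion so errors cite position
  blank <- !nzchar(trimws(cells)) | is.na(cells)
  if (any(blank)) {
    ij <- which(blank, arr.ind = TRUE)[1L, ]
    stop(sprintf("missing cell at feature '%s', sample '%s' in %s",
                 feature_ids[ij[1L]], sample_ids[ij[2L]], path), call. = FALSE)
  }
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  if (anyNA(vals)) {
    ij <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value '%s' at feature '%s', sample '%s' in %s",
                 cells[ij[1L], ij[2L]], feature_ids[ij[1L]], sample_ids[ij[2L]],
                 path), call. = FALSE)
  }
  dimnames(vals) <- list(feature_ids, sample_ids)
  if (transpose) vals <- t(vals)
  dup <- rownames(vals)[duplicated(rownames(vals))]
  if (length(dup))
    stop("duplicated feature id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  dup <- colnames(vals)[duplicated(colnames(vals))]
  if (length(dup))
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  .assert_expression_matrix(vals, "parsed matrix")
  vals
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_tsv()]; round-trips values to full double
#' precision.
#'
#' @param m Numeric feature x sample matrix with dimnames.
#' @param path Output path.
#' @param id_column Header label for the feature-id column.
#' @export
write_expression_tsv <- function(m, path, id_column = "feature_id") {
  .assert_expression_matrix(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Normalize a header name: lower-case, non-alphanumerics collapsed to "_".
.norm_colname <- function(x) gsub("^_+|_+$", "", gsub("[^a-z0-9]+", "_", tolower(x)))

.require_columns <- function(df, wanted, path) {
  norm <- .norm_colname(colnames(df))
  aliases <- list(
    mirna_id = c("mirna_id", "mirna", "mir", "mirna_family"),
    gene_id = c("gene_id", "gene", "gene_symbol", "entrez_id"),
    utr_id = c("utr_id", "transcript_id", "refseq_id", "isoform_id"),
    utr_length = c("utr_length", "utr_len", "x3p_utr_length", "length"),
    total_context_score = c("total_context_score", "context_score",
                            "total_context_score_"),
    weight = c("weight", "w", "confidence"))
  idx <- vapply(wanted, function(col) {
    hit <- which(norm %in% aliases[[col]])
    if (!length(hit))
      stop(sprintf("missing required column '%s' in %s", col, path),
           call. = FALSE)
    hit[1L]
  }, integer(1L))
  stats::setNames(idx, wanted)
}

#' Read sequence-based target predictions
#'
#' Two dialects are supported. `"targetscan_context"` follows the public
#' TargetScan context-score distribution in spirit: one row per
#' (miRNA, gene, 3'UTR isoform) with the total context score aggregated over
#' the isoform's binding sites; scores must lie in \[-1, 0\] (more negative =
#' more confident repression). `"preaggregated"` is a plain
#' (miRNA, gene, weight) table with weights in (0, 1\], letting users bypass
#' TargetScan files entirely.
#'
#' Column names are matched case-insensitively against common aliases
#' (`mirna_id`/`miRNA`, `gene_id`/`Gene ID`, `utr_id`/`Transcript ID`,
#' `utr_length`, `total_context_score`, `weight`).
#'
#' @param path Path to a TSV file with a header row.
#' @param dialect `"targetscan_context"` or `"preaggregated"`.
#' @return A data.frame of prediction records: columns `mirna_id`, `gene_id`,
#'   and either (`utr_id`, `utr_length`, `total_context_score`) or `weight`,
#'   with the dialect recorded in attribute `"dialect"`.
#' @export
read_target_predictions <- function(path,
                                    dialect = c("targetscan_context",
                                                "preaggregated")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, comment.char = "")
  if (dialect == "targetscan_context") {
    idx <- .require_columns(df, c("mirna_id", "gene_id", "utr_id",
                                  "utr_length", "total_context_score"), path)
    out <- data.frame(mirna_id = as.character(df[[idx["mirna_id"]]]),
                      gene_id = as.character(df[[idx["gene_id"]]]),
                      utr_id = as.character(df[[idx["utr_id"]]]),
                      utr_length = df[[idx["utr_length"]]],
                      total_context_score = df[[idx["total_context_score"]]],
                      stringsAsFactors = FALSE)
    if (!is.numeric(out$utr_length) || anyNA(out$utr_length) ||
        any(out$utr_length < 0))
      stop("malformed utr_length (non-numeric or negative) in ", path,
           call. = FALSE)
    s <- out$total_context_score
    if (!is.numeric(s) || anyNA(s))
      stop("malformed total_context_score in ", path, call. = FALSE)
    bad <- which(s < -1 | s > 0)
    if (length(bad))
      stop(sprintf(
        "total_context_score outside [-1, 0] at row %d (value %g) in %s",
        bad[1L], s[bad[1L]], path), call. = FALSE)
  } else {
    idx <- .require_columns(df, c("mirna_id", "gene_id", "weight"), path)
    out <- data.frame(mirna_id = as.character(df[[idx["mirna_id"]]]),
                      gene_id = as.character(df[[idx["gene_id"]]]),
                      weight = df[[idx["weight"]]],
                      stringsAsFactors = FALSE)
    w <- out$weight
    if (!is.numeric(w) || anyNA(w))
      stop("malformed weight in ", path, call. = FALSE)
    bad <- which(w <= 0 | w > 1)
    if (length(bad))
      stop(sprintf("weight outside (0, 1] at row %d (value %g) in %s",
                   bad[1L], w[bad[1L]], path), call. = FALSE)
  }
  attr(out, "dialect") <- dialect
  out
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line — name, description, then gene ids, all
#' tab-separated. Duplicate genes within a line are collapsed (first
#' occurrence kept).
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of gene ids, with the source path
#'   in attribute `"source"` and per-set descriptions in attribute
#'   `"descriptions"`. An empty file yields an empty collection.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descriptions <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L)
      stop(sprintf("GMT line %d has fewer than 3 fields in %s", i, path),
           call. = FALSE)
    name <- fields[1L]
    if (name %in% names(sets))
      stop(sprintf("duplicated gene-set name '%s' at GMT line %d in %s",
                   name, i, path), call. = FALSE)
    sets[[name]] <- unique(fields[-(1:2)])
    descriptions[name] <- fields[2L]
  }
  attr(sets, "source") <- path
  attr(sets, "descriptions") <- descriptions
  sets
}

#' Read a sample annotation table
#'
#' TSV with a mandatory `sample_id` column and optional `batch`,
#' `replicate_group` and `subtype` columns, used by the preprocessing steps
#' and the subtype-restricted analyses.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with unique `sample_id`s.
#' @export
read_sample_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ann <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, comment.char = "",
                           colClasses = "character")
  if (!"sample_id" %in% colnames(ann))
    stop("sample annotation must have a 'sample_id' column: ", path,
         call. = FALSE)
  dup <- ann$sample_id[duplicated(ann$sample_id)]
  if (length(dup))
    stop("duplicated sample_id(s) in annotation: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  ann
}

.results_columns <- c("mirna_id", "es", "p_value", "p_adjusted",
                      "n_targets_in_universe", "leading_edge_size",
                      "leading_edge_genes")

#' Write a per-miRNA results table
#'
#' Rows are sorted by enrichment score, descending (ties by miRNA id), and
#' leading-edge genes are semicolon-joined. Numeric values are written at full
#' double precision so a round-trip via [read_results_table()] reproduces them
#' well within 1e-6.
#'
#' @param results A results data.frame from [run_mirna_analysis()].
#' @param path Output path.
#' @export
write_results_table <- function(results, path) {
  stopifnot(is.data.frame(results))
  le <- if (nrow(results)) {
    vapply(results$leading_edge, paste, character(1L), collapse = ";")
  } else character(0)
  out <- data.frame(mirna_id = results$mirna_id,
                    es = results$es,
                    p_value = results$p_value,
                    p_adjusted = results$p_adjusted,
                    n_targets_in_universe = results$n_targets_in_universe,
                    leading_edge_size = results$leading_edge_size,
                    leading_edge_genes = le,
                    stringsAsFactors = FALSE)
  out <- out[.radix_order(-out$es, out$mirna_id), , drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(.results_columns, collapse = "\t"), con)
  if (nrow(out)) {
    fmt <- function(x) formatC(x, digits = 15, format = "g")
    body <- paste(out$mirna_id, fmt(out$es), fmt(out$p_value),
                  fmt(out$p_adjusted), out$n_targets_in_universe,
                  out$leading_edge_size, out$leading_edge_genes, sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#'
#' @param path Path to a results TSV.
#' @return A data.frame with the table's columns and `leading_edge` restored
#'   as a list of character vectors.
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, comment.char = "",
                          colClasses = "character")
  missing <- setdiff(.results_columns, colnames(df))
  if (length(missing))
    stop("results table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$es <- as.numeric(df$es)
  df$p_value <- as.numeric(df$p_value)
  df$p_adjusted <- as.numeric(df$p_adjusted)
  df$n_targets_in_universe <- as.integer(df$n_targets_in_universe)
  df$leading_edge_size <- as.integer(df$leading_edge_size)
  df$leading_edge <- lapply(df$leading_edge_genes, function(s) {
    if (!nzchar(s)) character(0) else strsplit(s, ";", fixed = TRUE)[[1L]]
  })
  df
}

#' Export aggregated target sets as a (miRNA, gene, weight) TSV
#'
#' Reproducibility audit trail for the per-miRNA weights actually used; the
#' file reads back with `read_target_predictions(dialect = "preaggregated")`.
#'
#' @param sets Named list of named numeric weight vectors.
#' @param path Output path.
#' @export
write_target_sets <- function(sets, path) {
  if (!length(sets)) {
    writeLines("mirna_id\tgene_id\tweight", path)
    return(invisible(path))
  }
  .assert_target_sets(sets)
  rows <- lapply(names(sets), function(m) {
    w <- sets[[m]]
    ord <- .radix_order(names(w))
    data.frame(mirna_id = m, gene_id = names(w)[ord], weight = unname(w)[ord],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
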