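# From per-(miRNA, gene, 3'UTR isoform) prediction records to per-miRNA
# weighted target sets restricted to the measured universe.

#' Aggregate prediction records into weighted target sets
#'
#' For every (miRNA, gene) pair with several 3'UTR isoforms, the record for
#' the longest isoform is used (ties broken by the most negative total context
#' score, then by UTR id, so the result is independent of input row order).
#' The target weight is the absolute value of the selected total context
#' score — TargetScan scores live in \[-1, 0\] with more negative meaning more
#' confident repression, while the running-sum statistic needs larger weights
#' for higher confidence. Genes whose selected score is exactly 0 carry no
#' information and are dropped.
#'
#' Pre-aggregated records (a `weight` column instead of context scores) pass
#' through directly; duplicate (miRNA, gene) pairs there are an error.
#'
#' @param records A prediction data.frame from [read_target_predictions()],
#'   or any data.frame with those columns.
#' @return A named list (one element per miRNA, sorted by id) of named numeric
#'   weight vectors with weights in (0, 1].
#' @export
build_target_sets <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  if ("weight" %in% colnames(records)) {
    key <- paste(records$mirna_id, records$gene_id, sep = "\r")
    if (anyDuplicated(key))
      stop("pre-aggregated records contain duplicated (miRNA, gene) pairs",
           call. = FALSE)
    sel <- records[, c("mirna_id", "gene_id", "weight")]
  } else {
    needed <- c("mirna_id", "gene_id", "utr_id", "utr_length",
                "total_context_score")
    missing <- setdiff(needed, colnames(records))
    if (length(missing))
      stop("records missing column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    ord <- .radix_order(records$mirna_id, records$gene_id,
                        -records$utr_length, records$total_context_score,
                        records$utr_id)
    recs <- records[ord, , drop = FALSE]
    first <- !duplicated(paste(recs$mirna_id, recs$gene_id, sep = "\r"))
    sel <- recs[first, , drop = FALSE]
    sel$weight <- abs(sel$total_context_score)
    sel <- sel[sel$weight > 0, , drop = FALSE]
  }
  sel <- sel[.radix_order(sel$mirna_id, sel$gene_id), , drop = FALSE]
  sets <- lapply(split(sel[, c("gene_id", "weight")], sel$mirna_id),
                 function(d) stats::setNames(d$weight, d$gene_id))
  sets <- sets[.radix_order(names(sets))]
  .assert_target_sets(sets)
  sets
}

#' Restrict target sets to the measured universe
#'
#' Keeps only miRNAs that were themselves measured and that retain at least
#' `min_targets` predicted targets among the measured genes; surviving sets
#' are intersected with the measured gene universe. Permutation nulls for very
#' small sets are unstable, hence the floor (default 10). Dropped miRNAs and
#' the reason ("miRNA not measured" or "too few measured targets") are
#' reported in the `"dropped"` attribute of the result.
#'
#' @param sets Named list of named numeric weight vectors
#'   (see [build_target_sets()]).
#' @param expressed_genes Character vector: the measured gene universe.
#' @param expressed_mirnas Character vector: the measured miRNAs.
#' @param min_targets Minimum number of measured targets (>= 1).
#' @return The restricted list of target sets, with attribute `"dropped"`:
#'   a data.frame of `mirna_id` and `reason`.
#' @export
restrict_to_universe <- function(sets, expressed_genes, expressed_mirnas,
                                 min_targets = 10L) {
  .assert_target_sets(sets)
  if (!length(expressed_genes))
    stop("'expressed_genes' is empty", call. = FALSE)
  if (!is.numeric(min_targets) || length(min_targets) != 1L || min_targets < 1)
    stop("'min_targets' must be a single integer >= 1", call. = FALSE)
  kept <- list()
  dropped_id <- character(0)
  dropped_reason <- character(0)
  for (m in names(sets)) {
    if (!m %in% expressed_mirnas) {
      dropped_id <- c(dropped_id, m)
      dropped_reason <- c(dropped_reason, "miRNA not measured")
      next
    }
    w <- sets[[m]]
    w <- w[names(w) %in% expressed_genes]
    if (length(w) < min_targets) {
      dropped_id <- c(dropped_id, m)
      dropped_reason <- c(dropped_reason, "too few measured targets")
      next
    }
    kept[[m]] <- w
  }
  attr(kept, "dropped") <- data.frame(mirna_id = dropped_id,
                                      reason = dropped_reason,
                                      stringsAsFactors = FALSE)
  kept
}
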