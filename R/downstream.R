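# Leading-edge extraction and follow-up statistics: annotation-category
# enrichment of leading-edge targets and cross-result-set overlap
# significance, both via the hypergeometric tail.

#' Extract the leading-edge subset of a target set
#'
#' The core genes accounting for the enrichment signal. For a positive score
#' these are the targets appearing in the ranked list up to and including the
#' position where the running sum attains its extreme; for a negative score,
#' the mirror convention: targets after that position through the end of the
#' list (bottom-of-list enrichment, as in GSEA). A zero score has no leading
#' edge. Order follows the ranked list.
#'
#' @param ranked A `"ranked_genes"` object.
#' @param tset Named numeric weight vector for the miRNA.
#' @param es Signed enrichment score.
#' @param argmax_index 1-based position of the score (see
#'   [enrichment_score()]).
#' @return Character vector of leading-edge gene ids (possibly empty).
#' @export
extract_leading_edge <- function(ranked, tset, es, argmax_index) {
  .check_ranked(ranked)
  n <- length(ranked$gene_ids)
  if (argmax_index < 1L || argmax_index > n)
    stop("'argmax_index' out of range", call. = FALSE)
  if (es == 0) return(character(0))
  span <- if (es > 0) seq_len(argmax_index)
          else if (argmax_index < n) seq.int(argmax_index + 1L, n)
          else integer(0)
  ids <- ranked$gene_ids[span]
  ids[ids %in% names(tset)]
}

#' Upper tail of the hypergeometric distribution
#'
#' P(X >= overlap) for the overlap of a query of size `query_size` with a set
#' of `set_size` successes drawn without replacement from `universe_size`
#' items; computed by the exact, log-space-stable tail sum.
#'
#' @param overlap Observed overlap count.
#' @param query_size Number of draws.
#' @param set_size Number of successes in the universe.
#' @param universe_size Universe size.
#' @return The tail probability.
#' @export
hypergeometric_tail <- function(overlap, query_size, set_size, universe_size) {
  counts <- c(overlap, query_size, set_size, universe_size)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (query_size > universe_size || set_size > universe_size)
    stop("query and set must fit in the universe", call. = FALSE)
  if (overlap > min(query_size, set_size))
    stop("overlap exceeds min(query_size, set_size)", call. = FALSE)
  stats::phyper(overlap - 1, set_size, universe_size - set_size, query_size,
                lower.tail = FALSE)
}

#' Annotation-category enrichment of leading-edge targets
#'
#' For every detected miRNA and every annotation set, tests whether the
#' miRNA's leading-edge genes overlap the set more than expected by chance
#' in the measured universe (the N ranked genes — the honest background, not
#' the whole genome). P-values are Bonferroni-corrected over the number of
#' sets actually tested per miRNA (sets with no gene in the universe are
#' excluded from both testing and the correction count).
#'
#' @param results Results data.frame from [run_mirna_analysis()] (or
#'   [read_results_table()]).
#' @param collections Named list of annotation gene sets (see [read_gmt()]).
#' @param universe Character vector: the ranked gene universe.
#' @param bonferroni_threshold Report categories with Bonferroni-corrected
#'   p below this (default 0.01); a threshold >= 1 reports every tested set.
#' @param only_detected Restrict to miRNAs flagged as detected (default
#'   `TRUE`; requires a `detected` or `p_adjusted` column).
#' @return A data.frame of category results: `mirna_id`, `set_name`,
#'   `overlap_count`, `set_size`, `query_size`, `universe_size`, `p_value`,
#'   `p_bonferroni`.
#' @export
annotate_leading_edges <- function(results, collections, universe,
                                   bonferroni_threshold = 0.01,
                                   only_detected = TRUE) {
  stopifnot(is.data.frame(results), is.list(collections))
  if (!length(universe)) stop("'universe' is empty", call. = FALSE)
  if (only_detected) {
    if (!is.null(results$detected)) results <- results[results$detected, ]
    else if (!is.null(results$p_adjusted))
      results <- results[results$p_adjusted < 0.1, ]
  }
  trimmed <- lapply(collections, intersect, universe)
  trimmed <- trimmed[lengths(trimmed) > 0L]
  n_tests <- length(trimmed)
  empty <- data.frame(mirna_id = character(0), set_name = character(0),
                      overlap_count = integer(0), set_size = integer(0),
                      query_size = integer(0), universe_size = integer(0),
                      p_value = numeric(0), p_bonferroni = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(results) || !n_tests) return(empty)
  out <- lapply(seq_len(nrow(results)), function(i) {
    le <- intersect(results$leading_edge[[i]], universe)
    if (!length(le)) return(NULL)
    p <- vapply(trimmed, function(set) {
      hypergeometric_tail(length(intersect(le, set)), length(le),
                          length(set), length(universe))
    }, numeric(1L))
    data.frame(mirna_id = results$mirna_id[i],
               set_name = names(trimmed),
               overlap_count = vapply(trimmed, function(set)
                 length(intersect(le, set)), integer(1L)),
               set_size = lengths(trimmed),
               query_size = length(le),
               universe_size = length(universe),
               p_value = unname(p),
               p_bonferroni = pmin(1, unname(p) * n_tests),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, c(out, list(empty)))
  keep <- if (bonferroni_threshold >= 1) rep(TRUE, nrow(out))
          else out$p_bonferroni < bonferroni_threshold
  out <- out[keep, , drop = FALSE]
  out <- out[.radix_order(out$mirna_id, out$p_value, out$set_name), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Significance of the overlap between two detected-miRNA sets
#'
#' Cross-dataset concordance: given the miRNAs detected in two analyses and
#' the common universe of miRNAs analyzable in both, reports the overlap
#' count and the hypergeometric tail probability of an overlap at least that
#' large.
#'
#' @param detected_a,detected_b Character vectors of detected miRNA ids,
#'   both subsets of `common_universe`.
#' @param common_universe Character vector of miRNAs analyzed in both
#'   datasets.
#' @return A list: `overlap`, `p_value`, `size_a`, `size_b`, `universe_size`.
#' @export
overlap_significance <- function(detected_a, detected_b, common_universe) {
  detected_a <- unique(detected_a)
  detected_b <- unique(detected_b)
  common_universe <- unique(common_universe)
  out_a <- setdiff(detected_a, common_universe)
  out_b <- setdiff(detected_b, common_universe)
  if (length(out_a) || length(out_b))
    stop("detected set(s) not contained in the common universe: ",
         paste(c(out_a, out_b), collapse = ", "), call. = FALSE)
  ov <- length(intersect(detected_a, detected_b))
  list(overlap = ov,
       p_value = hypergeometric_tail(ov, length(detected_a),
                                     length(detected_b),
                                     length(common_universe)),
       size_a = length(detected_a), size_b = length(detected_b),
       universe_size = length(common_universe))
}
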