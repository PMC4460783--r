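# Expression-data cleaning ahead of enrichment analysis: variance-stabilizing
# transform + quantile normalization, low-signal filters, technical-replicate
# averaging and additive batch correction.

#' Inverse-hyperbolic-sine transform followed by quantile normalization
#'
#' Each value is transformed by `asinh` (a log-like transform that is defined
#' at and below zero, suited to background-subtracted array intensities), then
#' all sample columns are forced onto the common reference distribution of
#' per-rank means (mean-of-order-statistics quantile normalization). Tied
#' values within a column receive the mean of the reference values at their
#' tied ranks.
#'
#' @param m Numeric feature x sample matrix with dimnames.
#' @return A matrix of identical shape and dimnames; after normalization, all
#'   columns share the same sorted value distribution.
#' @export
asinh_quantile_normalize <- function(m) {
  .assert_expression_matrix(m)
  if (ncol(m) < 2L)
    stop("quantile normalization needs at least 2 samples", call. = FALSE)
  out <- limma::normalizeQuantiles(asinh(m), ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Drop (or keep) features by a low-signal rule
#'
#' Two rules, matching the conventions for background-subtracted microarray
#' intensities and for sequencing read counts respectively:
#'
#' * `"negative_in_frac"`: a feature is *dropped* when the proportion of
#'   samples with value < 0 is >= `fraction` (e.g. probes negative on 95% or
#'   more of the arrays, `fraction = 0.95`).
#' * `"min_reads_in_frac"`: a feature is *kept* when the proportion of samples
#'   with value > `threshold` is >= `fraction` (e.g. more than 10 reads in at
#'   least 10% of the samples: `threshold = 10`, `fraction = 0.10`).
#'
#' Surviving features keep their original order; the comparison directions
#' (strict `>` for reads, inclusive `>=` for the proportions) follow the
#' stated rules literally.
#'
#' @param m Numeric feature x sample matrix with dimnames.
#' @param rule `"negative_in_frac"` or `"min_reads_in_frac"`.
#' @param threshold Read-count threshold for `"min_reads_in_frac"`; ignored by
#'   `"negative_in_frac"` (which tests `value < 0`).
#' @param fraction Proportion of samples in (0, 1].
#' @return The filtered matrix.
#' @export
filter_low_signal_features <- function(m,
                                       rule = c("negative_in_frac",
                                                "min_reads_in_frac"),
                                       threshold = 10, fraction = 0.95) {
  .assert_expression_matrix(m)
  rule <- match.arg(rule)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("'fraction' must lie in (0, 1]", call. = FALSE)
  keep <- if (rule == "negative_in_frac") {
    rowMeans(m < 0) < fraction
  } else {
    rowMeans(m > threshold) >= fraction
  }
  m[keep, , drop = FALSE]
}

.match_annotation <- function(m, ann, column) {
  if (!is.data.frame(ann) || !all(c("sample_id", column) %in% colnames(ann)))
    stop(sprintf("annotation must have 'sample_id' and '%s' columns", column),
         call. = FALSE)
  idx <- match(colnames(m), ann$sample_id)
  if (anyNA(idx))
    stop("sample(s) missing from annotation: ",
         paste(colnames(m)[is.na(idx)], collapse = ", "), call. = FALSE)
  as.character(ann[[column]][idx])
}

#' Average technical replicates
#'
#' Columns sharing a `replicate_group` in the annotation are replaced by their
#' per-feature arithmetic mean. The output has one column per replicate group,
#' named by the group id, ordered by first occurrence in the input; groups of
#' size one pass through unchanged (apart from the renaming).
#'
#' @param m Numeric feature x sample matrix with dimnames.
#' @param ann Sample annotation data.frame with `sample_id` and
#'   `replicate_group` columns covering every column of `m`.
#' @return A feature x replicate-group matrix.
#' @export
average_technical_replicates <- function(m, ann) {
  .assert_expression_matrix(m)
  grp <- .match_annotation(m, ann, "replicate_group")
  groups <- unique(grp)
  out <- vapply(groups,
                function(g) rowMeans(m[, grp == g, drop = FALSE]),
                numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(rownames(m), groups))
  out
}

#' Remove an additive batch effect
#'
#' Per feature, fits value ~ grand mean + batch fixed effect by least squares
#' and subtracts the fitted batch deviations: each batch's mean is shifted to
#' the feature's grand mean. The per-feature grand mean is preserved and,
#' afterwards, the batch label carries no mean information. The correction is
#' purely additive on the (already transformed) scale — no interactions, no
#' shrinkage — which is why every batch must contain at least two samples.
#'
#' @param m Numeric feature x sample matrix with dimnames.
#' @param ann Sample annotation data.frame with `sample_id` and `batch`
#'   columns covering every column of `m`.
#' @return The corrected matrix, same shape and dimnames.
#' @export
remove_batch_effect <- function(m, ann) {
  .assert_expression_matrix(m)
  batch <- .match_annotation(m, ann, "batch")
  sizes <- table(batch)
  if (length(sizes) < 2L)
    stop("batch correction needs at least 2 batches", call. = FALSE)
  if (any(sizes < 2L))
    stop("batch(es) with a single sample (effect inestimable): ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  grand <- rowMeans(m)
  batch_means <- vapply(names(sizes),
                        function(b) rowMeans(m[, batch == b, drop = FALSE]),
                        numeric(nrow(m)))
  batch_means <- matrix(batch_means, nrow = nrow(m),
                        dimnames = list(rownames(m), names(sizes)))
  m - batch_means[, batch, drop = FALSE] + grand
}
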