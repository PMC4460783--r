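# File-level pipeline: read inputs, optional preprocessing and subtype
# restriction, universe restriction, the per-miRNA analysis, and outputs
# (results table, dropped-miRNA report, reproducibility manifest).

#' Run the full analysis pipeline on files
#'
#' Reads the matched expression matrices and target predictions, optionally
#' applies preprocessing (low-signal filtering, asinh + quantile
#' normalization, batch correction, technical-replicate averaging — in that
#' order, each step opt-in), optionally restricts both matrices to samples of
#' one annotated subtype, restricts target sets to the measured universe,
#' runs [run_mirna_analysis()], and writes to `out_dir`:
#'
#' * `results.tsv` — the per-miRNA results table,
#' * `dropped_mirnas.tsv` — miRNAs excluded from analysis and why,
#' * `target_sets.tsv` — the aggregated (miRNA, gene, weight) table used,
#' * `manifest.json` — every parameter, path and seed of the run; passing it
#'   to [run_from_manifest()] reproduces the outputs byte for byte.
#'
#' @param mrna_path,mirna_path Paths to gene and miRNA expression TSVs
#'   (features in rows; see [read_expression_tsv()]).
#' @param targets_path Path to target predictions.
#' @param out_dir Output directory (created if needed).
#' @param targets_dialect `"targetscan_context"` or `"preaggregated"`.
#' @param annotation_path Optional sample annotation TSV (required for
#'   subtype restriction, batch correction or replicate averaging).
#' @param subtype Optional subtype label; both matrices are first subset to
#'   annotated samples with this label.
#' @param exclude_samples Optional character vector of sample ids dropped
#'   from both matrices before any other step (e.g. known outliers).
#' @param filter_rule,filter_threshold,filter_fraction Optional low-signal
#'   filter applied to the miRNA matrix (see
#'   [filter_low_signal_features()]); `NULL` skips filtering.
#' @param normalize Apply [asinh_quantile_normalize()] to the miRNA matrix.
#' @param batch_correct Apply [remove_batch_effect()] to the miRNA matrix.
#' @param average_replicates Apply [average_technical_replicates()] to the
#'   miRNA matrix.
#' @param min_targets Minimum measured targets per miRNA (default 10).
#' @param alpha,n_perm,seed,fdr_threshold,baseline,p_denominator,smooth
#'   Passed to [run_mirna_analysis()].
#' @return The results data.frame, invisibly, with attribute `"paths"`.
#' @export
run_pipeline <- function(mrna_path, mirna_path, targets_path, out_dir,
                         targets_dialect = c("preaggregated",
                                             "targetscan_context"),
                         annotation_path = NULL, subtype = NULL,
                         exclude_samples = NULL,
                         filter_rule = NULL, filter_threshold = 10,
                         filter_fraction = 0.95,
                         normalize = FALSE, batch_correct = FALSE,
                         average_replicates = FALSE,
                         min_targets = 10L, alpha = 1, n_perm = 1000L,
                         seed = 1L, fdr_threshold = 0.1,
                         baseline = "universe", p_denominator = "signed",
                         smooth = FALSE) {
  targets_dialect <- match.arg(targets_dialect)
  params <- list(mrna_path = mrna_path, mirna_path = mirna_path,
                 targets_path = targets_path, out_dir = out_dir,
                 targets_dialect = targets_dialect,
                 annotation_path = annotation_path, subtype = subtype,
                 exclude_samples = exclude_samples,
                 filter_rule = filter_rule,
                 filter_threshold = filter_threshold,
                 filter_fraction = filter_fraction, normalize = normalize,
                 batch_correct = batch_correct,
                 average_replicates = average_replicates,
                 min_targets = min_targets, alpha = alpha,
                 n_perm = n_perm, seed = seed,
                 fdr_threshold = fdr_threshold, baseline = baseline,
                 p_denominator = p_denominator, smooth = smooth)

  mrna <- read_expression_tsv(mrna_path)
  mirna <- read_expression_tsv(mirna_path)
  ann <- if (!is.null(annotation_path)) read_sample_annotation(annotation_path)

  if (!is.null(exclude_samples)) {
    mrna <- mrna[, !colnames(mrna) %in% exclude_samples, drop = FALSE]
    mirna <- mirna[, !colnames(mirna) %in% exclude_samples, drop = FALSE]
  }
  if (!is.null(subtype)) {
    if (is.null(ann) || !"subtype" %in% colnames(ann))
      stop("subtype restriction needs an annotation with a 'subtype' column",
           call. = FALSE)
    keep <- ann$sample_id[ann$subtype == subtype]
    if (!length(keep))
      stop("no samples annotated with subtype '", subtype, "'",
           call. = FALSE)
    mrna <- mrna[, colnames(mrna) %in% keep, drop = FALSE]
    mirna <- mirna[, colnames(mirna) %in% keep, drop = FALSE]
  }

  if (!is.null(filter_rule))
    mirna <- filter_low_signal_features(mirna, filter_rule, filter_threshold,
                                        filter_fraction)
  if (normalize) mirna <- asinh_quantile_normalize(mirna)
  if (batch_correct) mirna <- remove_batch_effect(mirna, ann)
  if (average_replicates) {
    mirna <- average_technical_replicates(mirna, ann)
    mrna <- average_technical_replicates(mrna, ann)
  }

  common <- intersect(colnames(mrna), colnames(mirna))
  bad <- c(setdiff(colnames(mrna), common), setdiff(colnames(mirna), common))
  if (length(bad))
    stop("sample set mismatch between matrices; unmatched sample(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  common <- common[.radix_order(common)]
  mrna <- mrna[, common, drop = FALSE]
  mirna <- mirna[, common, drop = FALSE]

  records <- read_target_predictions(targets_path, targets_dialect)
  sets <- build_target_sets(records)
  sets <- restrict_to_universe(sets, rownames(mrna), rownames(mirna),
                               min_targets)
  if (!length(sets))
    stop("no miRNA passes the universe restriction", call. = FALSE)

  res <- run_mirna_analysis(mrna, mirna, sets, alpha = alpha,
                            n_perm = n_perm, seed = seed,
                            fdr_threshold = fdr_threshold,
                            baseline = baseline,
                            p_denominator = p_denominator, smooth = smooth)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(results = file.path(out_dir, "results.tsv"),
                dropped = file.path(out_dir, "dropped_mirnas.tsv"),
                target_sets = file.path(out_dir, "target_sets.tsv"),
                manifest = file.path(out_dir, "manifest.json"))
  write_results_table(res, paths$results)
  utils::write.table(attr(sets, "dropped"), paths$dropped, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_target_sets(sets, paths$target_sets)
  manifest <- list(tool = "mirTRS",
                   version = as.character(utils::packageVersion("mirTRS")),
                   parameters = params,
                   universe = list(n_genes = nrow(mrna),
                                   n_samples = ncol(mrna),
                                   n_mirnas_analyzed = length(sets),
                                   n_mirnas_dropped =
                                     nrow(attr(sets, "dropped"))))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       null = "null", digits = NA, pretty = TRUE)
  attr(res, "paths") <- paths
  invisible(res)
}

#' Re-run a pipeline from its manifest
#'
#' Reads the parameter record written by [run_pipeline()] and repeats the run
#' exactly; with unchanged inputs the outputs are byte-identical.
#'
#' @param manifest_path Path to a `manifest.json`.
#' @param out_dir Optional override of the output directory.
#' @return As [run_pipeline()].
#' @export
run_from_manifest <- function(manifest_path, out_dir = NULL) {
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  params <- manifest$parameters
  params <- params[!vapply(params, is.null, logical(1L))]
  if (!is.null(out_dir)) params$out_dir <- out_dir
  do.call(run_pipeline, params)
}

#' Write a simulated dataset to disk
#'
#' Materializes a [generate_null_dataset()] / [generate_planted_dataset()]
#' result as the pipeline's input formats: two expression TSVs, a
#' pre-aggregated target TSV and a ground-truth JSON.
#'
#' @param dataset A simulated dataset list.
#' @param out_dir Output directory (created if needed).
#' @return Named list of the written paths, invisibly.
#' @export
write_simulated_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(mrna = file.path(out_dir, "mrna.tsv"),
                mirna = file.path(out_dir, "mirna.tsv"),
                targets = file.path(out_dir, "targets.tsv"),
                truth = file.path(out_dir, "truth.json"))
  write_expression_tsv(dataset$mrna, paths$mrna, id_column = "gene_id")
  write_expression_tsv(dataset$mirna, paths$mirna, id_column = "mirna_id")
  write_target_sets(dataset$sets, paths$targets)
  jsonlite::write_json(list(planted_regulators = dataset$truth,
                            responsive_targets = dataset$responsive,
                            config = unclass(dataset$config)),
                       paths$truth, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(paths)
}
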