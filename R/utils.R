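# Internal validators and deterministic helpers shared across modules.

.assert_expression_matrix <- function(m, arg = "m") {
  if (!is.matrix(m) || !is.numeric(m))
    stop(sprintf("'%s' must be a numeric matrix (features x samples)", arg),
         call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(sprintf("'%s' must carry feature rownames and sample colnames", arg),
         call. = FALSE)
  dup <- rownames(m)[duplicated(rownames(m))]
  if (length(dup))
    stop(sprintf("duplicated feature id(s) in '%s': %s", arg,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  dup <- colnames(m)[duplicated(colnames(m))]
  if (length(dup))
    stop(sprintf("duplicated sample id(s) in '%s': %s", arg,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  if (anyNA(m))
    stop(sprintf("'%s' contains missing values", arg), call. = FALSE)
  invisible(m)
}

.assert_target_sets <- function(sets, arg = "sets") {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop(sprintf("'%s' must be a named list of named numeric weight vectors", arg),
         call. = FALSE)
  if (anyDuplicated(names(sets)))
    stop(sprintf("duplicated miRNA id(s) in '%s'", arg), call. = FALSE)
  for (m in names(sets)) {
    w <- sets[[m]]
    if (!is.numeric(w) || is.null(names(w)))
      stop(sprintf("target set '%s' must be a named numeric weight vector", m),
           call. = FALSE)
    if (anyDuplicated(names(w)))
      stop(sprintf("target set '%s' has duplicated gene ids", m), call. = FALSE)
    if (any(w <= 0) || any(w > 1))
      stop(sprintf("target set '%s' has weights outside (0, 1]", m),
           call. = FALSE)
  }
  invisible(sets)
}

# Deterministic ordering independent of locale.
.radix_order <- function(...) order(..., method = "radix")

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's stream afterwards so library code never perturbs user simulations.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a per-miRNA permutation seed from the master seed
#'
#' Each miRNA gets its own reproducible permutation stream, derived
#' deterministically from the master seed and the miRNA identifier. Adding or
#' removing miRNAs from an analysis therefore never perturbs the permutation
#' null (and hence the p-value) of any other miRNA, and results are identical
#' regardless of processing order or parallelization.
#'
#' @param master_seed Integer master seed of the analysis.
#' @param mirna_id Character miRNA identifier.
#' @return A non-negative integer seed below 2^31 - 1.
#' @export
#' @examples
#' mirna_perm_seed(42L, "hsa-miR-21-5p")
mirna_perm_seed <- function(master_seed, mirna_id) {
  stopifnot(length(master_seed) == 1L, is.finite(master_seed),
            length(mirna_id) == 1L, is.character(mirna_id), nzchar(mirna_id))
  mod <- 2147483647           # 2^31 - 1; keeps every intermediate exact in double
  h <- 5381
  for (c in utf8ToInt(mirna_id)) h <- (h * 33 + c) %% mod
  as.integer((h * 1000003 + (as.double(master_seed) %% mod)) %% mod)
}
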