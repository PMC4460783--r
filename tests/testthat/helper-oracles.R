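# Independent oracles and fixture builders used across the suite. These stay
# deliberately naive (explicit loops, exhaustive enumeration) so they cannot
# share a defect with the vectorized implementation they check.

# Prefix-sum walk computed step by step in plain doubles.
brute_force_walk <- function(correlations, full_weights, alpha = 1,
                             baseline_n = length(correlations)) {
  n <- length(correlations)
  inc <- numeric(n)
  for (i in seq_len(n)) inc[i] <- full_weights[i] * abs(correlations[i])^alpha
  b <- 0
  for (i in seq_len(n)) b <- b + inc[i]
  b <- b / baseline_n
  prof <- numeric(n)
  run <- 0
  for (i in seq_len(n)) {
    run <- run + inc[i] - b
    prof[i] <- run
  }
  mx <- 0
  for (i in seq_len(n)) if (abs(prof[i]) > mx) mx <- abs(prof[i])
  best <- 1L
  for (i in seq_len(n)) {           # earliest position within the tie
    if (abs(prof[i]) >= mx - mx * 1e-9) { best <- i; break }
  }                                 # tolerance of the score's contract
  list(es = prof[best], argmax_index = best, profile = prof)
}

# A random ranked list plus a weighted target set placed at random positions.
random_instance <- function(n_max = 50L, k_max = 10L) {
  n <- sample(3:n_max, 1L)
  k <- sample(seq_len(min(k_max, n)), 1L)
  ids <- sprintf("g%03d", seq_len(n))
  r <- sort(stats::runif(n, -1, 1), decreasing = TRUE)
  ranked <- structure(list(mirna_id = "mir-test", gene_ids = ids,
                           correlations = r), class = "ranked_genes")
  pos <- sample.int(n, k)
  w <- stats::runif(k)
  list(ranked = ranked, tset = stats::setNames(w, ids[pos]), pos = pos,
       n = n, k = k)
}

# Exhaustive null over every placement of the target weights on the ranked
# list: all ordered assignments of k weights to k of n positions.
enumerate_null_es <- function(ranked, weights, alpha = 1) {
  n <- length(ranked$gene_ids)
  k <- length(weights)
  subsets <- utils::combn(n, k, simplify = FALSE)
  perms <- perms_of(seq_len(k))
  unlist(lapply(subsets, function(pos) {
    vapply(perms, function(p) {
      full <- numeric(n)
      full[pos] <- weights[p]
      brute_force_walk(ranked$correlations, full, alpha)$es
    }, numeric(1L))
  }))
}

# All permutations of a vector, recursively.
perms_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# Exhaustive hypergeometric upper tail by direct enumeration of counts.
enumerate_hyper_tail <- function(overlap, query, set, universe) {
  total <- choose(universe, query)
  hits <- 0
  for (x in overlap:min(query, set)) {
    hits <- hits + choose(set, x) * choose(universe - set, query - x)
  }
  hits / total
}

# Textbook step-up BH computed literally from its definition.
textbook_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  q[ord] <- p[ord] * m / seq_len(m)
  for (i in (m - 1L):1L) if (m > 1L)
    q[ord[i]] <- min(q[ord[i]], q[ord[i + 1L]])
  pmin(q, 1)
}

# Small expression matrix fixture with dimnames.
toy_matrix <- function(values, n_features, n_samples, byrow = FALSE,
                       feature_prefix = "g", sample_prefix = "s") {
  matrix(values, nrow = n_features, ncol = n_samples, byrow = byrow,
         dimnames = list(paste0(feature_prefix, seq_len(n_features)),
                         paste0(sample_prefix, seq_len(n_samples))))
}

write_tsv_lines <- function(lines, path = withr::local_tempfile(
                              fileext = ".tsv", .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}
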