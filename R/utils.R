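`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  force(code)
}

# Canonical unordered-pair key; "\r" cannot occur in identifiers read from TSV.
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

# Canonicalise a two-column pair table: a <= b lexicographically, deduplicated,
# self pairs dropped.
canonical_pairs <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  keep <- a != b
  a <- a[keep]
  b <- b[keep]
  pairs <- data.frame(a = pmin(a, b), b = pmax(a, b), stringsAsFactors = FALSE)
  pairs <- pairs[!duplicated(pair_key(pairs$a, pairs$b)), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

spectral_radius <- function(A) {
  if (length(A) == 0L || all(A == 0)) return(0)
  max(Mod(eigen(A, only.values = TRUE)$values))
}

# Dense P x P interaction-activity matrix A[target, interactor] from a sparse
# edge table.
interaction_matrix <- function(protein_ids, edges) {
  P <- length(protein_ids)
  A <- matrix(0, P, P, dimnames = list(protein_ids, protein_ids))
  if (!is.null(edges) && nrow(edges) > 0L) {
    A[cbind(match(edges$target, protein_ids),
            match(edges$interactor, protein_ids))] <- edges$alpha
  }
  A
}
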