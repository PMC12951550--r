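# Sequence-aware molecular representation. The published pipeline used a
# transformer pretrained on ChEMBL; shipping those weights is out of
# scope, so the default provider is a deterministic hashed character
# n-gram embedding with the same interface. Any function
# (character vector -> numeric matrix with a fixed column count) can be
# dropped in instead, e.g. a wrapper around a pretrained encoder.

# Exact integer hash of an n-gram: base-131 polynomial over the byte
# codes. For n <= 4 the value stays below 2^31, so double arithmetic is
# exact and the embedding is reproducible everywhere.
ngram_hash <- function(codes_matrix) {
  pw <- 131^(rev(seq_len(ncol(codes_matrix))) - 1L)
  as.vector(codes_matrix %*% pw)
}

#' Hashed n-gram sequence embedding of SMILES strings
#'
#' Counts character n-grams (n = 2..4 by default), hashes each n-gram into
#' one of `dim` buckets and L2-normalizes the count vector per molecule.
#' Deterministic: the same string always maps to the same vector.
#'
#' @param smiles character vector of SMILES strings.
#' @param dim embedding dimension (default 512).
#' @param n_min,n_max n-gram sizes (defaults 2 and 4).
#' @return numeric matrix, one row per input string, `dim` columns, rows
#'   L2-normalized (all-zero for strings shorter than `n_min`).
#' @export
sequence_embedding <- function(smiles, dim = 512L, n_min = 2L, n_max = 4L) {
  stopifnot(is.character(smiles), dim >= 2L, n_min >= 1L, n_max >= n_min,
            n_max <= 8L)
  out <- matrix(0, length(smiles), dim)
  for (i in seq_along(smiles)) {
    codes <- utf8ToInt(smiles[i])
    for (n in n_min:n_max) {
      if (length(codes) < n) next
      wins <- stats::embed(codes, n)[, n:1, drop = FALSE]
      idx <- (ngram_hash(wins) %% dim) + 1L
      tab <- tabulate(idx, nbins = dim)
      out[i, ] <- out[i, ] + tab
    }
    nrm <- sqrt(sum(out[i, ]^2))
    if (nrm > 0) out[i, ] <- out[i, ] / nrm
  }
  rownames(out) <- names(smiles)
  out
}
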