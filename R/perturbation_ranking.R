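# Topological perturbation significance: how strongly the L0/L1 sheaf
# Laplacian spectra react when one gene's star is deleted, measured per
# filtration scale and aggregated by intersecting the per-scale top-k.

#' Spectral feature vector of a complex
#'
#' Concatenates the six-number summaries of the L0 and L1 sheaf-Laplacian
#' spectra: 12 values (min, mean, max, std, sum, n_zero for each degree).
#' If the complex has no 1-simplices the L1 block is all zeros (empty
#' spectrum convention).
#'
#' @param complex a `simplicial_complex`.
#' @param sheaf a `sheaf_assignment`.
#' @param zero_tol relative zero tolerance for counting null eigenvalues.
#' @return numeric vector of length 12.
#' @export
feature_vector <- function(complex, sheaf, zero_tol = 1e-8) {
  f0 <- summarize_spectrum(
    laplacian_spectrum(sheaf_laplacian(complex, sheaf, 0L)), zero_tol)
  f1 <- summarize_spectrum(
    laplacian_spectrum(sheaf_laplacian(complex, sheaf, 1L)), zero_tol)
  stats::setNames(c(f0, f1),
                  c(paste0("L0_", names(f0)), paste0("L1_", names(f1))))
}

#' Order-1 Wasserstein distance between two feature vectors
#'
#' Both vectors are read as equal-weight empirical distributions of their
#' entries; the distance is the mean absolute difference of the sorted
#' values. Symmetric, nonnegative, and zero exactly when the two multisets
#' coincide.
#'
#' @param f,g numeric vectors of equal length.
#' @return nonnegative real.
#' @export
wasserstein_1d <- function(f, g) {
  if (length(f) != length(g)) stop("feature vectors have different lengths")
  if (!length(f)) return(0)
  mean(abs(sort(f) - sort(g)))
}

# Summed per-degree variant: W1(L0 block) + W1(L1 block). Available behind
# distance = "per_degree" in score_genes(); the default compares the full
# 12-entry vectors.
wasserstein_per_degree <- function(f, g) {
  wasserstein_1d(f[1:6], g[1:6]) + wasserstein_1d(f[7:12], g[7:12])
}

#' Perturbation scores of genes across the filtration
#'
#' For every requested gene and every filtration scale, computes the
#' Wasserstein distance between the feature vector of the complex at that
#' scale and the feature vector of the same complex with the gene's star
#' deleted. Removing the sole remaining vertex leaves the empty complex,
#' whose feature vector is all zeros by convention.
#'
#' @param network the `labeled_network` the filtration was built from.
#' @param filtration named list of complexes from
#'   [build_confidence_filtration()].
#' @param sheaf a `sheaf_assignment` (defaults to [default_sheaf()] of the
#'   network); vertex-star removal keeps ids stable so the same sheaf
#'   serves every perturbed complex.
#' @param genes genes to score (default: all network genes).
#' @param distance `"concat"` (default) compares the 12-entry vectors;
#'   `"per_degree"` sums an L0-block and an L1-block distance.
#' @return a `data.frame` with columns `gene`, `scale`, `distance`.
#' @export
score_genes <- function(network, filtration, sheaf = default_sheaf(network),
                        genes = network$genes,
                        distance = c("concat", "per_degree")) {
  distance <- match.arg(distance)
  dfun <- if (distance == "concat") wasserstein_1d else wasserstein_per_degree
  unknown <- setdiff(genes, network$genes)
  if (length(unknown)) {
    stop("unknown gene(s): ", paste(utils::head(unknown, 5L), collapse = ", "))
  }
  base <- lapply(filtration, feature_vector, sheaf = sheaf)
  rows <- vector("list", length(genes) * length(filtration))
  k <- 0L
  for (g in genes) {
    for (t in names(filtration)) {
      pert <- remove_vertex_star(filtration[[t]], g)
      f_hat <- if (n_simplices(pert, 0L) == 0L) {
        rep(0, 12L)
      } else {
        feature_vector(pert, sheaf)
      }
      k <- k + 1L
      rows[[k]] <- data.frame(gene = g, scale = as.integer(t),
                              distance = dfun(base[[t]], f_hat))
    }
  }
  do.call(rbind, rows)
}

#' Rank per scale and intersect the top-k prefixes
#'
#' At every scale genes are ordered by decreasing perturbation distance
#' (ties broken by gene symbol); the final gene set is the intersection of
#' the per-scale top-k prefixes. An empty intersection is legal and
#' reported with the per-scale rankings intact. A union-with-frequency
#' table (how many scales each top-k gene appeared in) is returned for
#' diagnostics.
#'
#' @param scores `data.frame` from [score_genes()]; every gene must be
#'   scored at every scale.
#' @param top_k prefix size per scale (default 25, the published setting
#'   for 200-gene networks).
#' @return an object of class `ranking_result`: list with `per_scale`
#'   (named list of ordered gene vectors), `intersected` (character),
#'   `frequency` (data.frame gene/n_scales), `top_k` and `table` (the
#'   scores with per-scale ranks and an `in_final_set` flag).
#' @export
rank_and_intersect <- function(scores, top_k = 25L) {
  if (top_k < 1L) stop("top_k must be >= 1")
  scales <- sort(unique(scores$scale))
  n_per <- table(scores$scale)
  if (length(unique(n_per)) != 1L ||
      any(table(scores$gene) != length(scales))) {
    stop("every gene must be scored at every scale")
  }
  per_scale <- lapply(scales, function(t) {
    s <- scores[scores$scale == t, , drop = FALSE]
    s$gene[order(-s$distance, s$gene)]
  })
  names(per_scale) <- as.character(scales)
  prefixes <- lapply(per_scale, utils::head, n = top_k)
  intersected <- Reduce(intersect, prefixes)
  freq <- sort(table(unlist(prefixes)), decreasing = TRUE)
  frequency <- data.frame(gene = names(freq), n_scales = as.integer(freq))
  tab <- scores
  tab$rank <- NA_integer_
  for (t in scales) {
    idx <- tab$scale == t
    tab$rank[idx] <- match(tab$gene[idx], per_scale[[as.character(t)]])
  }
  tab$in_final_set <- tab$gene %in% intersected
  tab <- tab[order(tab$scale, tab$rank), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(per_scale = per_scale, intersected = sort(intersected),
                 frequency = frequency, top_k = top_k, table = tab),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat("<ranking_result> top_k =", x$top_k, "over",
      length(x$per_scale), "scales\n")
  cat("intersected set (", length(x$intersected), "): ",
      paste(x$intersected, collapse = ", "), "\n", sep = "")
  invisible(x)
}
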