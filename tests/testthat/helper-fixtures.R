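# In-code fixture builders shared across the suite.

# Labeled network straight from vectors: genes get |log2fc| = q_named and
# a tiny p-value; edges as (a, b, score) triples.
make_network <- function(q_named, edges = NULL) {
  degs <- data.frame(gene = names(q_named), log2fc = unname(q_named),
                     pvalue = 1e-4)
  if (is.null(edges)) {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        score = integer())
  }
  build_labeled_network(degs, edges)
}

edge_df <- function(a, b, score) {
  data.frame(gene_a = pmin(a, b), gene_b = pmax(a, b),
             score = as.integer(score))
}

# The trivial sheaf q = 1, F = 1 under which L0 must equal the graph
# Laplacian exactly.
constant_sheaf <- function(network) {
  sh <- default_sheaf(network)
  sh$q[] <- 1
  sh$edge_r[] <- 1
  sh
}

# Random labeled network: Erdos-Renyi edges with uniform STRING-like
# scores and positive labels.
random_network <- function(n, p_edge, seed, score_range = c(100L, 990L)) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n))
  pairs <- t(utils::combn(genes, 2L))
  keep <- stats::runif(nrow(pairs)) < p_edge
  edges <- edge_df(pairs[keep, 1L], pairs[keep, 2L],
                   sample(score_range[1L]:score_range[2L], sum(keep),
                          replace = TRUE))
  q <- stats::runif(n, 0.1, 3)
  names(q) <- genes
  make_network(q, edges)
}

# Unnormalized graph Laplacian assembled independently from the edge list.
graph_laplacian_oracle <- function(network, min_score = 0L) {
  n <- length(network$genes)
  L <- matrix(0, n, n)
  ed <- network$edges[network$edges$score >= min_score, , drop = FALSE]
  for (k in seq_len(nrow(ed))) {
    i <- match(ed$gene_a[k], network$genes)
    j <- match(ed$gene_b[k], network$genes)
    L[i, j] <- L[j, i] <- -1
    L[i, i] <- L[i, i] + 1
    L[j, j] <- L[j, j] + 1
  }
  L
}

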