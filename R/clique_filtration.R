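# Oriented clique complexes over the confidence filtration.
#
# A complex is stored per dimension as an integer matrix with one simplex
# per row, vertex ids strictly ascending within a row (this fixes the
# orientation) and rows in lexicographic order (this fixes the ordinal of
# each simplex). Vertex ids index `vertex_names`, the gene order of the
# network the complex was built from, and stay stable under vertex-star
# removal so a sheaf defined on the network applies to every subcomplex.

new_simplicial_complex <- function(simplices, vertex_names) {
  simplices <- lapply(simplices, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    if (nrow(m) > 1L) m <- m[do.call(order, asplit(m, 2L)), , drop = FALSE]
    m
  })
  structure(list(simplices = simplices, vertex_names = vertex_names,
                 max_dim = length(simplices) - 1L),
            class = "simplicial_complex")
}

#' Number of simplices of one dimension
#' @param complex a `simplicial_complex`.
#' @param dim simplex dimension (0 = vertices).
#' @export
n_simplices <- function(complex, dim) {
  if (dim + 1L > length(complex$simplices)) return(0L)
  nrow(complex$simplices[[dim + 1L]])
}

#' @export
print.simplicial_complex <- function(x, ...) {
  counts <- vapply(x$simplices, nrow, integer(1))
  cat("<simplicial_complex> dims 0..", x$max_dim, ": ",
      paste(counts, collapse = " / "), " simplices\n", sep = "")
  invisible(x)
}

#' Build the clique complex of a thresholded network
#'
#' The k-simplices (k <= `max_dim`) are the (k+1)-cliques of the subgraph
#' keeping edges with confidence score >= `min_score`. All genes enter as
#' 0-simplices regardless of threshold, so vertices never die along the
#' filtration. The result is closed under faces by construction (every
#' subset of a clique is a clique).
#'
#' @param network a `labeled_network`.
#' @param min_score minimum combined confidence score (0-1000 scale).
#' @param max_dim maximum simplex dimension, one of 1, 2, 3 (default 2:
#'   triangles, the highest dimension the L0/L1 spectra need).
#' @return a `simplicial_complex`.
#' @export
build_clique_complex <- function(network, min_score, max_dim = 2L) {
  stopifnot(max_dim %in% 1:3)
  genes <- network$genes
  ed <- network$edges[network$edges$score >= min_score, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = match(ed$gene_a, genes),
                   to = match(ed$gene_b, genes)),
    directed = FALSE,
    vertices = data.frame(id = seq_along(genes)))
  simplices <- vector("list", max_dim + 1L)
  simplices[[1L]] <- matrix(seq_along(genes), ncol = 1L)
  for (d in seq_len(max_dim)) {
    cl <- igraph::cliques(g, min = d + 1L, max = d + 1L)
    if (length(cl)) {
      m <- t(vapply(cl, function(s) sort(as.integer(s)), integer(d + 1L)))
    } else {
      m <- matrix(integer(), ncol = d + 1L)
    }
    simplices[[d + 1L]] <- m
  }
  new_simplicial_complex(simplices, genes)
}

#' Build the inverse confidence filtration
#'
#' One clique complex per confidence threshold, loosest first (the default
#' thresholds are 250, 400, 550, 700 as in STRING's low-to-high confidence
#' bands). Raising the threshold removes edges and every clique that used
#' them, so the complexes are nested: higher threshold is a subcomplex of
#' lower threshold.
#'
#' @param network a `labeled_network`.
#' @param thresholds strictly increasing integer vector in (0, 1000\].
#' @param max_dim maximum simplex dimension (see [build_clique_complex()]).
#' @return a named list of `simplicial_complex`, names = thresholds.
#' @export
build_confidence_filtration <- function(network,
                                        thresholds = c(250L, 400L, 550L, 700L),
                                        max_dim = 2L) {
  stopifnot(length(thresholds) >= 1L, all(thresholds > 0),
            all(thresholds <= 1000), !is.unsorted(thresholds, strictly = TRUE))
  out <- lapply(thresholds, build_clique_complex, network = network,
                max_dim = max_dim)
  names(out) <- as.character(thresholds)
  out
}

#' Delete the star of a vertex
#'
#' Removes a gene's 0-simplex together with every simplex containing it
#' (its star). The remainder is still closed under faces; remaining
#' simplices keep their vertex ids and their lexicographic ordering, only
#' the ordinals shift.
#'
#' @param complex a `simplicial_complex`.
#' @param gene gene symbol naming a 0-simplex of the complex.
#' @return the perturbed `simplicial_complex`.
#' @export
remove_vertex_star <- function(complex, gene) {
  vid <- match(gene, complex$vertex_names)
  if (is.na(vid) || !(vid %in% complex$simplices[[1L]][, 1L])) {
    stop("gene '", gene, "' is not a vertex of the complex")
  }
  simplices <- lapply(complex$simplices, function(m) {
    if (!nrow(m)) return(m)
    m[rowSums(m == vid) == 0L, , drop = FALSE]
  })
  new_simplicial_complex(simplices, complex$vertex_names)
}

#' Export a complex as plain text
#'
#' One simplex per line, tab-separated vertex symbols, dimensions in
#' increasing order — a debugging format easy to diff and to feed to an
#' external oracle.
#'
#' @param complex a `simplicial_complex`.
#' @param path output file.
#' @export
export_complex <- function(complex, path) {
  lines <- unlist(lapply(complex$simplices, function(m) {
    if (!nrow(m)) return(character())
    apply(m, 1L, function(r) paste(complex$vertex_names[r], collapse = "\t"))
  }))
  writeLines(lines, path)
  invisible(path)
}

# TRUE iff every (k-1)-face of every k-simplex is present; used by tests.
is_face_closed <- function(complex) {
  key <- function(m) apply(m, 1L, paste, collapse = ",")
  for (d in seq_len(complex$max_dim)) {
    m <- complex$simplices[[d + 1L]]
    if (!nrow(m)) next
    faces_below <- key(complex$simplices[[d]])
    for (i in seq_len(d + 1L)) {
      f <- m[, -i, drop = FALSE]
      if (!all(key(f) %in% faces_below)) return(FALSE)
    }
  }
  TRUE
}

# TRUE iff `small` is simplexwise contained in `big`; used by tests and by
# the persistent Laplacian guard.
is_subcomplex <- function(small, big) {
  key <- function(m) apply(m, 1L, paste, collapse = ",")
  for (d in 0:small$max_dim) {
    ms <- small$simplices[[d + 1L]]
    if (!nrow(ms)) next
    if (d + 1L > length(big$simplices)) return(FALSE)
    if (!all(key(ms) %in% key(big$simplices[[d + 1L]]))) return(FALSE)
  }
  TRUE
}
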