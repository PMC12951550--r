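# Cellular sheaf on a clique complex, its coboundaries, (persistent)
# Laplacians and spectral summaries.
#
# Every stalk is R (one-dimensional), so a sheaf is fully described by the
# vertex labels q_i > 0 and a nowhere-zero simplex weight F. For the face
# relation tau <= sigma the restriction map is the scalar
#     F(tau) * prod(q_v : v in sigma \ tau) / F(sigma)
# which composes along nested faces automatically (the telescoping product
# of q's and the cancellation of the intermediate F's).

simplex_key <- function(m) {
  if (!nrow(m)) return(character())
  apply(m, 1L, paste, collapse = ",")
}

#' Default sheaf assignment for a labeled network
#'
#' Vertex stalk labels are the dysregulation magnitudes q of the network.
#' The simplex weight F is 1 on vertices and, for a k-simplex with k >= 1,
#' the mean "length" of its edges, where an edge's length is
#' r_ij = max(1 - score_ij/1000, r_floor): high-confidence interactions are
#' short. The floor keeps F nowhere zero (a score of exactly 1000 would
#' otherwise give length 0). Alternative weights can be supplied as
#' `F_strategy`, a function(vertex_ids, q, edge_r) -> positive scalar,
#' without touching any Laplacian code.
#'
#' @param network a `labeled_network` supplying q and the edge scores.
#' @param r_floor minimum edge length (default 1e-3).
#' @param F_strategy optional replacement for the mean-edge-length weight.
#' @return an object of class `sheaf_assignment`.
#' @export
default_sheaf <- function(network, r_floor = 1e-3, F_strategy = NULL) {
  stopifnot(all(network$q > 0), r_floor > 0)
  q <- unname(network$q[network$genes])
  er <- pmax(1 - network$edges$score / 1000, r_floor)
  names(er) <- paste(match(network$edges$gene_a, network$genes),
                     match(network$edges$gene_b, network$genes), sep = ",")
  structure(list(q = q, edge_r = er, r_floor = r_floor,
                 F_strategy = F_strategy),
            class = "sheaf_assignment")
}

# Edge length lookup by a pair of ascending vertex ids.
sheaf_edge_r <- function(sheaf, i, j) {
  r <- sheaf$edge_r[paste(i, j, sep = ",")]
  if (any(is.na(r))) stop("sheaf has no edge length for a requested pair")
  unname(r)
}

# F value of one simplex given as an ascending vertex-id vector.
sheaf_F <- function(sheaf, vids) {
  if (length(vids) == 1L) return(1)
  if (!is.null(sheaf$F_strategy)) {
    return(sheaf$F_strategy(vids, sheaf$q, sheaf$edge_r))
  }
  pairs <- utils::combn(vids, 2L)
  mean(sheaf_edge_r(sheaf, pairs[1L, ], pairs[2L, ]))
}

# Vectorized F over the rows of a simplex matrix.
sheaf_F_rows <- function(sheaf, m) {
  if (!nrow(m)) return(numeric())
  if (ncol(m) == 1L) return(rep(1, nrow(m)))
  if (!is.null(sheaf$F_strategy)) {
    return(apply(m, 1L, function(v) sheaf$F_strategy(v, sheaf$q,
                                                     sheaf$edge_r)))
  }
  pairs <- utils::combn(ncol(m), 2L)
  acc <- 0
  for (k in seq_len(ncol(pairs))) {
    acc <- acc + sheaf_edge_r(sheaf, m[, pairs[1L, k]], m[, pairs[2L, k]])
  }
  acc / ncol(pairs)
}

#' Restriction-map scalar of a face relation
#'
#' For tau a face of sigma (both ascending vertex-id vectors) returns
#' F(tau) times the product of q over the vertices of sigma missing from
#' tau, divided by F(sigma). The identity map (tau == sigma) returns 1.
#' For a vertex v_i inside an edge e_ij this reduces to q_j / r_ij, whose
#' kernel section assigns q_i to v_i and q_i q_j / r_ij to the edge.
#'
#' @param tau,sigma simplices as strictly ascending integer vectors of
#'   vertex ids.
#' @param sheaf a `sheaf_assignment`.
#' @return the restriction scalar (real, nonzero).
#' @export
restriction_scalar <- function(tau, sigma, sheaf) {
  if (!all(tau %in% sigma)) stop("tau is not a face of sigma")
  if (length(tau) == length(sigma)) return(1)
  extra <- setdiff(sigma, tau)
  sheaf_F(sheaf, tau) * prod(sheaf$q[extra]) / sheaf_F(sheaf, sigma)
}

#' Sheaf coboundary matrix of one degree
#'
#' Rows are the (degree+1)-simplices, columns the degree-simplices of the
#' complex, both in their lexicographic ordinal order. The entry for a
#' simplex and its codimension-1 face obtained by dropping the i-th vertex
#' (0-based) is (-1)^i times the restriction scalar of the face relation;
#' all other entries vanish, so each row has exactly degree+2 nonzeros.
#'
#' @param complex a `simplicial_complex`.
#' @param sheaf a `sheaf_assignment` consistent with the complex.
#' @param degree coboundary degree q (maps q-cochains to (q+1)-cochains).
#' @return a sparse `Matrix::dgCMatrix`.
#' @export
coboundary_matrix <- function(complex, sheaf, degree) {
  stopifnot(degree >= 0L)
  n_lo <- n_simplices(complex, degree)
  n_hi <- n_simplices(complex, degree + 1L)
  if (n_hi == 0L || n_lo == 0L) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n_hi, n_lo)))
  }
  lo <- complex$simplices[[degree + 1L]]
  hi <- complex$simplices[[degree + 2L]]
  lo_ord <- stats::setNames(seq_len(n_lo), simplex_key(lo))
  F_lo <- sheaf_F_rows(sheaf, lo)
  F_hi <- sheaf_F_rows(sheaf, hi)
  # codimension-1 faces: dropping the i-th vertex leaves exactly one
  # extra vertex, so the restriction scalar is F(tau) * q(dropped) / F(sigma)
  ii <- jj <- vector("list", degree + 2L)
  xx <- vector("list", degree + 2L)
  for (i in seq_len(degree + 2L)) {
    face <- hi[, -i, drop = FALSE]
    ii[[i]] <- seq_len(n_hi)
    jj[[i]] <- unname(lo_ord[simplex_key(face)])
    xx[[i]] <- (-1)^(i - 1L) * F_lo[jj[[i]]] * sheaf$q[hi[, i]] / F_hi
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n_hi, n_lo))
}

#' Sheaf Laplacian of one degree
#'
#' L_q = D_q^T D_q + D_{q-1} D_{q-1}^T with D the coboundary matrices
#' (D_{-1} = 0). Symmetric positive semidefinite; with the constant sheaf
#' (q = 1, F = 1) L_0 is exactly the unnormalized graph Laplacian. An
#' empty degree yields a 0 x 0 matrix.
#'
#' @inheritParams coboundary_matrix
#' @param degree Laplacian degree.
#' @param max_matrix refuse degrees with more simplices than this
#'   (default 20000): the spectral summaries need full eigendecompositions.
#' @return a dense symmetric base matrix.
#' @export
sheaf_laplacian <- function(complex, sheaf, degree, max_matrix = 20000L) {
  n <- n_simplices(complex, degree)
  if (n == 0L) return(matrix(numeric(), 0L, 0L))
  if (n > max_matrix) {
    stop("degree ", degree, " has ", n, " simplices (> max_matrix = ",
         max_matrix, ")")
  }
  up_d <- coboundary_matrix(complex, sheaf, degree)
  L <- Matrix::crossprod(up_d)
  if (degree > 0L) {
    dn_d <- coboundary_matrix(complex, sheaf, degree - 1L)
    L <- L + Matrix::tcrossprod(dn_d)
  }
  L <- as.matrix(L)
  (L + t(L)) / 2
}

# Moore-Penrose pseudo-inverse with a relative singular-value cutoff.
pseudo_inverse <- function(M, cutoff = 1e-10) {
  if (!length(M)) return(M)
  s <- svd(M)
  keep <- s$d > cutoff * max(s$d, 1e-300)
  if (!any(keep)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Persistent sheaf Laplacian across a pair of nested complexes
#'
#' For K_small contained in K_big, the degree-q persistent Laplacian acts
#' on the q-cochains of K_small. Its down part is the usual
#' D_{q-1} D_{q-1}^T of K_small. Its up part is the Schur complement of
#' the big up-Laplacian D_q(K_big)^T D_q(K_big) onto the columns indexed
#' by K_small's q-simplices, eliminating (via pseudo-inverse) the
#' q-simplices present only in K_big. Its nullity equals the persistent
#' sheaf Betti number of the inclusion. With K_small = K_big it reduces to
#' [sheaf_laplacian()].
#'
#' @param K_small,K_big nested `simplicial_complex` objects
#'   (`K_small` must be a subcomplex of `K_big`).
#' @param sheaf a `sheaf_assignment` consistent with both.
#' @param degree Laplacian degree.
#' @param cutoff relative singular-value cutoff of the pseudo-inverse
#'   (default 1e-10).
#' @return a dense symmetric matrix indexed by K_small's q-simplices.
#' @export
persistent_sheaf_laplacian <- function(K_small, K_big, sheaf, degree,
                                       cutoff = 1e-10) {
  if (!is_subcomplex(K_small, K_big)) {
    stop("K_small is not a subcomplex of K_big")
  }
  n_small <- n_simplices(K_small, degree)
  if (n_small == 0L) return(matrix(numeric(), 0L, 0L))
  D_big <- coboundary_matrix(K_big, sheaf, degree)
  M <- as.matrix(Matrix::crossprod(D_big))
  key_small <- simplex_key(K_small$simplices[[degree + 1L]])
  key_big <- simplex_key(K_big$simplices[[degree + 1L]])
  A <- match(key_small, key_big)
  B <- setdiff(seq_along(key_big), A)
  if (length(key_big) == 0L) {
    up <- matrix(0, n_small, n_small)
  } else if (length(B) == 0L) {
    up <- M[A, A, drop = FALSE]
  } else {
    up <- M[A, A, drop = FALSE] -
      M[A, B, drop = FALSE] %*%
      pseudo_inverse(M[B, B, drop = FALSE], cutoff) %*%
      M[B, A, drop = FALSE]
  }
  L <- up
  if (degree > 0L) {
    dn_d <- coboundary_matrix(K_small, sheaf, degree - 1L)
    L <- L + as.matrix(Matrix::tcrossprod(dn_d))
  }
  (L + t(L)) / 2
}

#' Eigenvalue spectrum of a symmetric matrix
#'
#' @param L symmetric matrix (possibly 0 x 0).
#' @return increasing numeric vector of eigenvalues (empty for 0 x 0).
#' @export
laplacian_spectrum <- function(L) {
  if (!length(L)) return(numeric())
  sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
}

#' Six-number summary of a spectrum
#'
#' Min, mean, max, population standard deviation, sum and the number of
#' (numerical) zeros, counting eigenvalues at most
#' `zero_tol * max(1, lambda_max)` — slightly negative eigenvalues from
#' roundoff count as zeros. The empty spectrum summarizes to all zeros by
#' convention.
#'
#' @param eigenvalues numeric vector of eigenvalues.
#' @param zero_tol relative zero tolerance (default 1e-8).
#' @return named numeric vector `min, mean, max, std, sum, n_zero`.
#' @export
summarize_spectrum <- function(eigenvalues, zero_tol = 1e-8) {
  if (!length(eigenvalues)) {
    return(c(min = 0, mean = 0, max = 0, std = 0, sum = 0, n_zero = 0))
  }
  mu <- mean(eigenvalues)
  c(min = min(eigenvalues),
    mean = mu,
    max = max(eigenvalues),
    std = sqrt(mean((eigenvalues - mu)^2)),
    sum = sum(eigenvalues),
    n_zero = sum(eigenvalues <= zero_tol * max(1, max(eigenvalues))))
}
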