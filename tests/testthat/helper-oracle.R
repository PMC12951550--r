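# Independent homology oracle: exact matrix ranks over two finite fields
# (entries of constant-sheaf boundary matrices are -1/0/1, so the rational
# rank equals the mod-p rank unless p divides a pivotal minor; agreement
# of two ~46000 primes on these tiny matrices settles it). Betti numbers
# come from ranks alone — no Laplacians anywhere in this file.

modp_rank <- function(M, p) {
  if (!length(M)) return(0L)
  A <- M %% p
  n <- nrow(A); m <- ncol(A)
  rank <- 0L
  row <- 1L
  for (col in seq_len(m)) {
    piv <- which(A[row:n, col] != 0)
    if (!length(piv)) next
    piv <- piv[1L] + row - 1L
    if (piv != row) A[c(row, piv), ] <- A[c(piv, row), ]
    # modular inverse via Fermat (p prime), done with exact doubles
    inv <- 1
    base <- A[row, col]; e <- p - 2
    while (e > 0) {
      if (e %% 2 == 1) inv <- (inv * base) %% p
      base <- (base * base) %% p
      e <- e %/% 2
    }
    A[row, ] <- (A[row, ] * inv) %% p
    for (r in seq_len(n)) {
      if (r != row && A[r, col] != 0) {
        A[r, ] <- (A[r, ] - A[r, col] * A[row, ]) %% p
      }
    }
    rank <- rank + 1L
    row <- row + 1L
    if (row > n) break
  }
  rank
}

rational_rank <- function(M) {
  r1 <- modp_rank(M, 46337)
  r2 <- modp_rank(M, 46327)
  stopifnot(r1 == r2)
  r1
}

# Boundary matrix of degree q for the constant sheaf: rows are
# (q-1)-simplices, columns q-simplices, entries (-1)^i for dropping the
# i-th (0-based) vertex. Built directly from the simplex tables.
boundary_matrix_int <- function(complex, q) {
  lo <- complex$simplices[[q]]
  hi <- complex$simplices[[q + 1L]]
  B <- matrix(0L, nrow(lo), nrow(hi))
  if (!nrow(hi) || !nrow(lo)) return(B)
  lo_key <- apply(lo, 1L, paste, collapse = ",")
  for (cidx in seq_len(nrow(hi))) {
    for (i in seq_len(q + 1L)) {
      face <- paste(hi[cidx, -i], collapse = ",")
      B[match(face, lo_key), cidx] <- as.integer((-1)^(i - 1L))
    }
  }
  B
}

# Simplicial Betti number beta_q via ranks.
betti_oracle <- function(complex, q) {
  n_q <- n_simplices(complex, q)
  if (n_q == 0L) return(0L)
  rank_down <- if (q == 0L) 0L else rational_rank(boundary_matrix_int(complex, q))
  rank_up <- if (q + 1L > complex$max_dim) 0L else
    rational_rank(boundary_matrix_int(complex, q + 1L))
  n_q - rank_down - rank_up
}

# Persistent Betti number of the inclusion K_small -> K_big:
#   dim Z_q(K_small) - dim (B_q(K_big) /\ C_q(K_small)),
# the second term via rank(d_{q+1}^big) - rank(d_{q+1}^big without the
# rows of K_small's q-simplices).
persistent_betti_oracle <- function(K_small, K_big, q) {
  n_q <- n_simplices(K_small, q)
  if (n_q == 0L) return(0L)
  z <- if (q == 0L) n_q else
    n_q - rational_rank(boundary_matrix_int(K_small, q))
  if (q + 1L > K_big$max_dim || n_simplices(K_big, q + 1L) == 0L) {
    return(z)
  }
  B <- boundary_matrix_int(K_big, q + 1L)
  key_small <- apply(K_small$simplices[[q + 1L]], 1L, paste, collapse = ",")
  key_big <- apply(K_big$simplices[[q + 1L]], 1L, paste, collapse = ",")
  inside <- match(key_small, key_big)
  outside <- setdiff(seq_along(key_big), inside)
  r_all <- rational_rank(B)
  r_out <- if (length(outside)) rational_rank(B[outside, , drop = FALSE])
           else 0L
  z - (r_all - r_out)
}

# Numerical nullity of a PSD matrix, relative tolerance.
nullity <- function(L, tol = 1e-8) {
  ev <- laplacian_spectrum(L)
  if (!length(ev)) return(0L)
  sum(ev <= tol * max(1, max(ev)))
}

# Brute-force clique complex from an adjacency matrix: test every vertex
# subset of size <= max_dim + 1. Independent of igraph.
brute_clique_complex_counts <- function(adj, max_dim) {
  n <- nrow(adj)
  counts <- integer(max_dim + 1L)
  counts[1L] <- n
  for (d in seq_len(max_dim)) {
    if (n < d + 1L) break
    subsets <- utils::combn(n, d + 1L)
    is_clique <- apply(subsets, 2L, function(s) {
      all(adj[s, s][upper.tri(diag(length(s)))] == 1)
    })
    counts[d + 1L] <- sum(is_clique)
  }
  counts
}
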