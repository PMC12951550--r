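test_that("default sheaf turns scores into edge lengths and mean weights", {
  net <- make_network(c(A = 1, B = 1, C = 1),
                      edge_df(c("A", "A", "B"), c("B", "C", "C"),
                              c(500, 600, 700)))
  sh <- default_sheaf(net)
  expect_equal(pslscreen:::sheaf_edge_r(sh, 1, 2), 0.5)   # score 500
  expect_equal(pslscreen:::sheaf_F(sh, 1L), 1)
  expect_equal(pslscreen:::sheaf_F(sh, 1:3), mean(c(0.5, 0.4, 0.3)))

  maxed <- make_network(c(A = 1, B = 1), edge_df("A", "B", 1000))
  expect_equal(pslscreen:::sheaf_edge_r(default_sheaf(maxed), 1, 2), 1e-3)
})

test_that("restriction scalars follow the F(tau) prod(q) / F(sigma) rule", {
  net <- make_network(c(a = 1.5, b = 2.5), edge_df("a", "b", 700))
  sh <- default_sheaf(net)
  # vertex inside an edge: multiplication by q_other / r
  expect_equal(restriction_scalar(1L, 1:2, sh), 2.5 / 0.3)
  expect_equal(restriction_scalar(2L, 1:2, sh), 1.5 / 0.3)
  expect_equal(restriction_scalar(1:2, 1:2, sh), 1)  # identity
  expect_error(restriction_scalar(3L, 1:2, sh), "not a face")

  # vertex inside a triangle with F == 1: product of the two missing q's
  net3 <- make_network(c(a = 1, b = 2, c = 3),
                       edge_df(c("a", "a", "b"), c("b", "c", "c"), 900))
  sh3 <- default_sheaf(net3, F_strategy = function(v, q, er) 1)
  expect_equal(restriction_scalar(1L, 1:3, sh3), 6)
})

test_that("coboundaries carry incidence signs times restriction scalars", {
  net <- make_network(c(a = 1, b = 2), edge_df("a", "b", 700))
  csh <- constant_sheaf(net)
  D0 <- as.matrix(coboundary_matrix(net |> build_clique_complex(250, 2),
                                    csh, 0))
  expect_equal(D0, matrix(c(-1, 1), 1), ignore_attr = TRUE)

  # the paper's vertex-edge sheaf: row (-q_j/r, +q_i/r) kills the section
  sh <- default_sheaf(net)
  K <- build_clique_complex(net, 250, 2)
  D0s <- as.matrix(coboundary_matrix(K, sh, 0))
  expect_equal(D0s, matrix(c(-2 / 0.3, 1 / 0.3), 1), ignore_attr = TRUE)
  expect_equal(as.numeric(D0s %*% c(1, 2)), 0)

  # chain-complex identity on a filled triangle, constant sheaf
  tri <- make_network(c(a = 1, b = 1, c = 1),
                      edge_df(c("a", "a", "b"), c("b", "c", "c"), 900))
  K <- build_clique_complex(tri, 700, 2)
  cs <- constant_sheaf(tri)
  comp <- coboundary_matrix(K, cs, 1) %*% coboundary_matrix(K, cs, 0)
  expect_equal(max(abs(comp)), 0)
})

test_that("sheaf Laplacians match frozen 2x2/3x3 eigensystems", {
  net <- make_network(c(a = 1, b = 1), edge_df("a", "b", 700))
  K <- build_clique_complex(net, 250, 2)
  L0 <- sheaf_laplacian(K, constant_sheaf(net), 0)
  expect_equal(L0, matrix(c(1, -1, -1, 1), 2), ignore_attr = TRUE)
  expect_equal(laplacian_spectrum(L0), c(0, 2))

  sh <- constant_sheaf(net)
  sh$q <- c(1, 2)
  L0 <- sheaf_laplacian(K, sh, 0)
  expect_equal(L0, matrix(c(4, -2, -2, 1), 2), ignore_attr = TRUE)
  expect_equal(laplacian_spectrum(L0), c(0, 5))

  tri <- make_network(c(a = 1, b = 1, c = 1),
                      edge_df(c("a", "a", "b"), c("b", "c", "c"), 900))
  K1 <- build_clique_complex(tri, 700, 1)  # unfilled triangle
  L0 <- sheaf_laplacian(K1, constant_sheaf(tri), 0)
  expect_equal(laplacian_spectrum(L0), c(0, 3, 3))
})

test_that("constant-sheaf L0 equals the graph Laplacian on random graphs", {
  for (seed in 1:10) {
    net <- random_network(12, 0.4, seed)
    K <- build_clique_complex(net, 400, 2)
    L0 <- sheaf_laplacian(K, constant_sheaf(net), 0)
    expect_lt(max(abs(L0 - graph_laplacian_oracle(net, 400))), 1e-12)
  }
})

test_that("summarize_spectrum computes the six statistics", {
  s <- summarize_spectrum(c(0, 2))
  expect_equal(unname(s), c(0, 1, 2, 1, 2, 1))
  expect_equal(unname(summarize_spectrum(c(3, 3, 3))),
               c(3, 3, 3, 0, 9, 0))
  expect_equal(unname(summarize_spectrum(numeric())), rep(0, 6))
  # n_zero uses a relative tolerance and tolerates tiny negatives
  expect_equal(unname(summarize_spectrum(c(-1e-12, 1e-12, 5))["n_zero"]), 2)
  # sum equals the trace of the matrix it came from
  net <- random_network(8, 0.5, 99)
  K <- build_clique_complex(net, 300, 2)
  L <- sheaf_laplacian(K, default_sheaf(net), 1)
  expect_equal(unname(summarize_spectrum(laplacian_spectrum(L))["sum"]),
               sum(diag(L)))
})

test_that("persistent Laplacian: frozen pairs and the p = 0 reduction", {
  net <- make_network(c(a = 1, b = 1), edge_df("a", "b", 700))
  cs <- constant_sheaf(net)
  K_big <- build_clique_complex(net, 250, 2)
  K_small <- build_clique_complex(net, 900, 2)  # edge gone, vertices stay
  PL <- persistent_sheaf_laplacian(K_small, K_big, cs, 0)
  expect_equal(PL, matrix(c(1, -1, -1, 1), 2), ignore_attr = TRUE)
  expect_equal(nullity(PL), 1L)
  expect_equal(persistent_betti_oracle(K_small, K_big, 0L), 1L)

  # K_small == K_big reduces to the plain Laplacian
  expect_equal(persistent_sheaf_laplacian(K_big, K_big, cs, 0),
               sheaf_laplacian(K_big, cs, 0))

  # the 1-cycle of the triangle boundary dies in the filled triangle
  tri <- make_network(c(a = 1, b = 1, c = 1),
                      edge_df(c("a", "a", "b"), c("b", "c", "c"), 900))
  cs3 <- constant_sheaf(tri)
  hollow <- build_clique_complex(tri, 700, 1)
  filled <- build_clique_complex(tri, 700, 2)
  expect_equal(nullity(sheaf_laplacian(hollow, cs3, 1)), 1L)
  PL1 <- persistent_sheaf_laplacian(hollow, filled, cs3, 1)
  expect_equal(nullity(PL1), 0L)
  expect_equal(persistent_betti_oracle(hollow, filled, 1L), 0L)

  expect_error(persistent_sheaf_laplacian(K_big, K_small, cs, 0),
               "not a subcomplex")
})

test_that("nullity equals Betti numbers from the rank oracle", {
  for (seed in 1:8) {
    net <- random_network(8, 0.45, seed)
    K <- build_clique_complex(net, 300, 2)
    cs <- constant_sheaf(net)
    for (q in 0:1) {
      expect_equal(nullity(sheaf_laplacian(K, cs, q)),
                   betti_oracle(K, q),
                   info = paste("seed", seed, "degree", q))
    }
    # sheaf Laplacians with arbitrary labels keep the same nullity
    sh <- default_sheaf(net)
    expect_equal(nullity(sheaf_laplacian(K, sh, 0)), betti_oracle(K, 0))
  }
})

test_that("all Laplacians are symmetric PSD for generic sheaves", {
  for (seed in 11:16) {
    net <- random_network(10, 0.4, seed)
    K <- build_clique_complex(net, 250, 2)
    sh <- default_sheaf(net)
    for (q in 0:2) {
      L <- sheaf_laplacian(K, sh, q)
      if (!length(L)) next
      expect_true(isSymmetric(L))
      ev <- laplacian_spectrum(L)
      expect_gte(min(ev), -1e-10 * max(1, max(abs(ev))))
    }
  }
})
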