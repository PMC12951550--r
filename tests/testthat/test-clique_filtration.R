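test_that("clique expansion matches hand counts and brute-force enumeration", {
  tri <- make_network(c(A = 1, B = 1, C = 1),
                      edge_df(c("A", "A", "B"), c("B", "C", "C"), 900))
  K <- build_clique_complex(tri, 700, 2)
  expect_equal(vapply(0:2, n_simplices, integer(1), complex = K),
               c(3L, 3L, 1L))

  path <- make_network(c(A = 1, B = 1, C = 1),
                       edge_df(c("A", "B"), c("B", "C"), 900))
  K <- build_clique_complex(path, 700, 2)
  expect_equal(vapply(0:2, n_simplices, integer(1), complex = K),
               c(3L, 2L, 0L))

  four <- make_network(stats::setNames(rep(1, 4), LETTERS[1:4]),
                       edge_df(rep(LETTERS[1:3], times = 3:1),
                               c("B", "C", "D", "C", "D", "D"), 900))
  K <- build_clique_complex(four, 700, 3)
  expect_equal(vapply(0:3, n_simplices, integer(1), complex = K),
               c(4L, 6L, 4L, 1L))

  # brute-force subset enumeration agrees on random graphs
  for (seed in 1:5) {
    net <- random_network(8, 0.5, seed)
    K <- build_clique_complex(net, 400, 3)
    adj <- matrix(0L, 8, 8)
    ed <- net$edges[net$edges$score >= 400, ]
    for (k in seq_len(nrow(ed))) {
      i <- match(ed$gene_a[k], net$genes); j <- match(ed$gene_b[k], net$genes)
      adj[i, j] <- adj[j, i] <- 1L
    }
    expect_equal(vapply(0:3, n_simplices, integer(1), complex = K),
                 brute_clique_complex_counts(adj, 3))
    expect_true(is_face_closed(K))
  }
})

test_that("confidence filtration is nested, loosest first, vertices immortal", {
  net <- make_network(stats::setNames(rep(1, 5), letters[1:5]),
                      edge_df(c("a", "b", "c", "d"), c("b", "c", "d", "e"),
                              c(300, 450, 600, 750)))
  filt <- build_confidence_filtration(net)
  expect_equal(names(filt), c("250", "400", "550", "700"))
  expect_equal(vapply(filt, n_simplices, integer(1), dim = 1),
               c("250" = 4L, "400" = 3L, "550" = 2L, "700" = 1L))
  expect_true(all(vapply(filt, n_simplices, integer(1), dim = 0) == 5L))
  for (i in 1:3) expect_true(is_subcomplex(filt[[i + 1]], filt[[i]]))

  # random networks: monotone nesting at every step
  for (seed in 1:5) {
    net <- random_network(10, 0.4, seed)
    filt <- build_confidence_filtration(net)
    for (i in 1:3) expect_true(is_subcomplex(filt[[i + 1]], filt[[i]]))
    expect_true(all(vapply(filt, is_face_closed, logical(1))))
  }

  none <- make_network(c(a = 1, b = 1))
  filt <- build_confidence_filtration(none)
  expect_true(all(vapply(filt, n_simplices, integer(1), dim = 1) == 0L))
  expect_true(all(vapply(filt, n_simplices, integer(1), dim = 0) == 2L))
})

test_that("vertex-star removal deletes the star and nothing else", {
  tri <- make_network(c(A = 1, B = 1, C = 1),
                      edge_df(c("A", "A", "B"), c("B", "C", "C"), 900))
  K <- build_clique_complex(tri, 700, 2)
  Kp <- remove_vertex_star(K, "A")
  expect_equal(vapply(0:2, n_simplices, integer(1), complex = Kp),
               c(2L, 1L, 0L))
  expect_error(remove_vertex_star(K, "Z"), "Z")

  lone <- build_clique_complex(make_network(c(a = 1, b = 1)), 700, 2)
  expect_equal(n_simplices(remove_vertex_star(lone, "a"), 0L), 1L)

  four <- make_network(stats::setNames(rep(1, 4), LETTERS[1:4]),
                       edge_df(rep(LETTERS[1:3], times = 3:1),
                               c("B", "C", "D", "C", "D", "D"), 900))
  K <- build_clique_complex(four, 700, 2)
  Kp <- remove_vertex_star(K, "B")
  expect_equal(vapply(0:2, n_simplices, integer(1), complex = Kp),
               c(3L, 3L, 1L))

  # two-route equivalence: deleting the vertex from the graph first gives
  # the identical complex
  for (seed in 1:5) {
    net <- random_network(9, 0.5, seed)
    K <- build_clique_complex(net, 300, 2)
    victim <- net$genes[5L]
    route1 <- remove_vertex_star(K, victim)
    keep <- setdiff(net$genes, victim)
    sub <- net$edges[net$edges$gene_a != victim & net$edges$gene_b != victim, ]
    net2 <- make_network(net$q[keep], sub)
    route2 <- build_clique_complex(net2, 300, 2)
    # same simplices up to the vertex-id relabeling of the smaller network
    for (d in 0:2) {
      s1 <- route1$simplices[[d + 1]]
      s2 <- route2$simplices[[d + 1]]
      n1 <- matrix(route1$vertex_names[s1], ncol = d + 1)
      n2 <- matrix(route2$vertex_names[s2], ncol = d + 1)
      expect_equal(n1, n2)
    }
    expect_true(is_face_closed(route1))
  }
})
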