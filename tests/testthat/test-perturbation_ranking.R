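test_that("feature vectors follow the empty-spectrum conventions", {
  bare <- make_network(c(a = 1, b = 2, c = 0.5))
  K <- build_clique_complex(bare, 250, 2)
  fv <- feature_vector(K, default_sheaf(bare))
  # L0 is the 3x3 zero matrix: three zero eigenvalues; no edges: L1 zeros
  expect_equal(unname(fv), c(0, 0, 0, 0, 0, 3, rep(0, 6)))

  net <- make_network(c(a = 1, b = 1), edge_df("a", "b", 700))
  K <- build_clique_complex(net, 250, 2)
  fv <- feature_vector(K, constant_sheaf(net))
  expect_equal(unname(fv[1:6]), c(0, 1, 2, 1, 2, 1))  # spectrum {0, 2}

  # bit-for-bit determinism
  expect_identical(fv, feature_vector(build_clique_complex(net, 250, 2),
                                      constant_sheaf(net)))
})

test_that("wasserstein_1d is the sorted mean absolute difference", {
  expect_equal(wasserstein_1d(c(1, 5, 2), c(1, 5, 2)), 0)
  expect_equal(wasserstein_1d(c(0, 0), c(1, 1)), 1)
  expect_equal(wasserstein_1d(c(0, 1), c(3, 1)), 1.5)
  expect_equal(wasserstein_1d(c(3, 1), c(0, 1)), 1.5)  # symmetry
  expect_equal(wasserstein_1d(c(2, 0), c(0, 2)), 0)    # multiset equality
  expect_error(wasserstein_1d(1:3, 1:4), "lengths")
})

test_that("score_genes: isolated genes barely move the spectra, hubs do", {
  # two connected triangles plus one isolated gene with the floor label
  q <- c(a = 2, b = 0.5, c = 0.6, d = 0.4, e = 0.5, f = 0.6, x = 0)
  ed <- edge_df(c("a", "a", "b", "d", "d", "e", "a"),
                c("b", "c", "c", "e", "f", "f", "d"),
                c(900, 900, 900, 800, 800, 800, 750))
  net <- make_network(q, ed)
  filt <- build_confidence_filtration(net)
  sc <- score_genes(net, filt)
  d_iso <- sc$distance[sc$gene == "x"]
  d_hub <- sc$distance[sc$gene == "a"]
  # removing an isolated floor-label gene only shifts the counting
  # statistics (spectrum cardinality and one zero), not the spectral
  # mass, so its distance sits far below the hub's at every scale
  expect_true(all(d_iso < 0.02 * max(d_hub)))
  expect_true(all(d_hub > 0))

  # sole vertex: the perturbed complex is empty, features all zero
  solo <- make_network(c(z = 1))
  fsolo <- build_confidence_filtration(solo)
  f <- feature_vector(fsolo[[1]], default_sheaf(solo))
  sc1 <- score_genes(solo, fsolo)
  expect_equal(sc1$distance, rep(wasserstein_1d(f, rep(0, 12)), 4))

  expect_error(score_genes(net, filt, genes = "nope"), "unknown gene")
})

test_that("planted hubs outrank the median gene at the loosest scale", {
  # at the 30-gene scale of the recovery criterion; scoring only the
  # loosest complex keeps this cheap
  for (seed in 1:3) {
    net0 <- generate_planted_network(30, 2, 1, seed = seed)
    net <- build_labeled_network(
      select_top_upregulated(read_deg_table(net0$deg_path), n = 200),
      read_interaction_edges(net0$edge_path))
    sc <- score_genes(net, build_confidence_filtration(net)["250"])
    med <- stats::median(sc$distance)
    for (h in net0$hubs) {
      expect_gt(sc$distance[sc$gene == h], med,
                label = paste0("seed ", seed, " hub ", h, " distance"))
    }
  }
})

test_that("rank_and_intersect intersects per-scale top-k prefixes", {
  sc <- data.frame(gene = rep(c("g1", "g2", "g3"), each = 2),
                   scale = rep(c(250L, 700L), 3),
                   distance = c(9, 9, 5, 6, 1, 2))
  rr <- rank_and_intersect(sc, top_k = 1)
  expect_equal(rr$intersected, "g1")
  expect_equal(rr$per_scale[["250"]], c("g1", "g2", "g3"))

  # disjoint per-scale winners: empty intersection is legal
  sc$distance <- c(9, 1, 5, 2, 1, 8)
  rr <- rank_and_intersect(sc, top_k = 1)
  expect_length(rr$intersected, 0)
  expect_equal(rr$per_scale[["700"]][1], "g3")
  expect_equal(sum(rr$table$in_final_set), 0)

  # frequency diagnostic counts scale appearances
  expect_equal(rr$frequency$n_scales[order(rr$frequency$gene)][1], 1L)

  expect_error(rank_and_intersect(sc, top_k = 0), "top_k")
  expect_error(rank_and_intersect(sc[-1, ], top_k = 1), "every scale")
})

test_that("rankings are permutation invariant and deterministic", {
  net0 <- generate_planted_network(15, 2, 1, seed = 9)
  net <- build_labeled_network(
    select_top_upregulated(read_deg_table(net0$deg_path), n = 200),
    read_interaction_edges(net0$edge_path))
  filt <- build_confidence_filtration(net)
  sc1 <- score_genes(net, filt)
  sc2 <- score_genes(net, filt)
  expect_identical(sc1, sc2)

  # consistent relabeling g -> Z<g> permutes scores identically
  relabel <- function(x) paste0("Z", x)
  degs <- read_deg_table(net0$deg_path)
  degs$gene <- relabel(degs$gene)
  ed <- read_interaction_edges(net0$edge_path)
  ed$gene_a <- relabel(ed$gene_a); ed$gene_b <- relabel(ed$gene_b)
  net_p <- build_labeled_network(select_top_upregulated(degs, n = 200), ed)
  sc_p <- score_genes(net_p, build_confidence_filtration(net_p))
  sc_p$orig <- sub("^Z", "", sc_p$gene)
  cmp <- merge(sc1, sc_p[, c("orig", "scale", "distance")],
               by.x = c("gene", "scale"), by.y = c("orig", "scale"))
  expect_equal(cmp$distance.x, cmp$distance.y)
})
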