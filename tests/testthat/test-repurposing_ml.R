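test_that("free-energy conversion hits the anchor points and inverts", {
  expect_equal(round(delta_g_from_activity(180), 1), -9.2)
  expect_equal(delta_g_from_activity(1e9), 0)
  expect_equal(round(delta_g_from_activity(10), 1), -10.9)
  expect_error(delta_g_from_activity(0), "positive")
  expect_error(delta_g_from_activity(-5), "positive")

  # strictly monotone, exact round trip
  act <- 10^seq(-1, 8, length.out = 40)
  dg <- delta_g_from_activity(act)
  expect_true(all(diff(dg) > 0))
  expect_equal(activity_from_delta_g(dg), act, tolerance = 1e-9)
})

test_that("prepare_compound_set canonicalizes, merges and drops", {
  rec <- data.frame(
    compound_id = c("c1", "c2", "c3", "c4"),
    smiles = c("OCC", "CCO", "C(", "CC.O"),
    activity_nM = c(100, 400, 50, 60),
    activity_type = "IC50", stringsAsFactors = FALSE)
  expect_message(out <- prepare_compound_set(rec), "dropped 2")
  expect_equal(nrow(out), 1L)
  expect_equal(out$smiles, "CCO")
  expect_equal(out$activity_nM, 200)  # geometric mean of 100 and 400

  # idempotent on an already-canonical unique set
  again <- prepare_compound_set(out)
  expect_equal(again, out)

  bad <- data.frame(compound_id = "x", smiles = "C(", activity_nM = 1,
                    activity_type = "IC50")
  expect_error(suppressMessages(prepare_compound_set(bad)), "no usable")
})

test_that("ECFP fingerprints are canonical-invariant fixed-length bits", {
  expect_equal(ecfp_fingerprint("CCO"), ecfp_fingerprint("OCC"))
  expect_length(ecfp_fingerprint("CCO"), 2048L)
  expect_length(ecfp_fingerprint("CCO", n_bits = 512L), 512L)
  a <- ecfp_fingerprint("CCO"); b <- ecfp_fingerprint("CCN")
  tanimoto <- sum(a & b) / sum(a | b)
  expect_lt(tanimoto, 1)
  expect_error(ecfp_fingerprint("C("), "unparseable")
  expect_error(ecfp_fingerprint("CC.O"), "multi-fragment")
})

test_that("sequence embedding is deterministic, unit-norm and discriminative", {
  e1 <- sequence_embedding("CCO")
  expect_identical(e1, sequence_embedding("CCO"))
  expect_equal(ncol(e1), 512L)
  expect_equal(sum(e1^2), 1)
  e2 <- sequence_embedding("CCCCCCCC")
  expect_lt(sum(e1 * e2), 1 - 1e-6)
})

test_that("gbdt learns an additive target and refits reproducibly", {
  set.seed(7)
  X <- matrix(rbinom(2000, 1, 0.4), 100, 20)
  y <- as.vector(X[, 1:5] %*% c(2, -1, 1.5, -2, 1))
  f1 <- gbdt(X, y, n_trees = 100, max_depth = 3, learning_rate = 0.1)
  f2 <- gbdt(X, y, n_trees = 100, max_depth = 3, learning_rate = 0.1)
  expect_identical(predict(f1, X), predict(f2, X))
  expect_lt(sqrt(mean((predict(f1, X) - y)^2)), 0.25)
  # staged prediction is a prefix of the full ensemble
  f50 <- gbdt(X, y, n_trees = 50, max_depth = 3, learning_rate = 0.1)
  expect_equal(predict(f1, X, n_trees = 50), predict(f50, X))
})

test_that("ensemble training: floor, determinism, manifest, consensus mean", {
  aff <- generate_affinity_dataset(120, sigma = 0.2, seed = 3)
  prep <- prepare_compound_set(aff$records)
  small_grid <- expand.grid(n_trees = 100L, max_depth = 3L,
                            learning_rate = 0.1)
  expect_error(train_affinity_ensemble(utils::head(prep, 10), seed = 1),
               "at least 50")
  m1 <- train_affinity_ensemble(prep, seed = 4, grid = small_grid)
  m2 <- train_affinity_ensemble(prep, seed = 4, grid = small_grid)
  expect_named(m1$members, c("ecfp", "embedding"))
  expect_equal(m1$manifest$members$ecfp$chosen$n_trees, 100L)
  expect_true(is.finite(m1$manifest$holdout_consensus_rmse))
  # averaging two members never does worse than the weaker one
  expect_lte(m1$manifest$holdout_consensus_rmse,
             max(m1$manifest$members$ecfp$holdout_rmse,
                 m1$manifest$members$embedding$holdout_rmse) + 1e-12)

  cand <- data.frame(compound_id = prep$compound_id[1:25],
                     smiles = prep$smiles[1:25])
  p1 <- predict_consensus(m1, cand)
  p2 <- predict_consensus(m2, cand)
  expect_identical(p1, p2)
  # consensus is exactly the member mean
  expect_identical(p1$delta_g_pred,
                   (p1$delta_g_ecfp + p1$delta_g_embedding) / 2)
})

test_that("predict_consensus records unfeaturizable compounds as failed", {
  aff <- generate_affinity_dataset(80, sigma = 0, seed = 5)
  prep <- prepare_compound_set(aff$records)
  grid <- expand.grid(n_trees = 50L, max_depth = 3L, learning_rate = 0.1)
  mod <- train_affinity_ensemble(prep, seed = 5, grid = grid)
  cand <- data.frame(compound_id = c("ok", "mix", "bad"),
                     smiles = c("CCO", "CC.O", "C("))
  out <- predict_consensus(mod, cand)
  expect_equal(out$failed, c(FALSE, TRUE, TRUE))
  expect_equal(is.na(out$delta_g_pred), c(FALSE, TRUE, TRUE))
  expect_equal(nrow(out), 3L)
})

test_that("call_binders uses a strict threshold and sorts ascending", {
  cmp <- data.frame(compound_id = c("a", "b", "c", "d"),
                    delta_g_pred = c(-13.00, -9.2, -9.3, NA))
  out <- call_binders(cmp, -9.2)
  expect_equal(out$compound_id, c("a", "c"))  # -9.2 exactly is not a binder
  expect_equal(out$delta_g_pred, c(-13.0, -9.3))
  expect_equal(nrow(call_binders(cmp[0, ], -9.2)), 0L)
})
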