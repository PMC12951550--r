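# R wrapper around the compiled gradient-boosted tree engine: feature
# binning, constant-column pruning and staged prediction.

# Bin one numeric column into at most `max_bins` integer codes. Columns
# with few distinct values (fingerprint bits) get one bin per value;
# continuous columns get quantile bins. Returns codes and the breaks
# needed to bin new data identically.
bin_column <- function(x, max_bins = 32L) {
  ux <- sort(unique(x))
  if (length(ux) <= max_bins) {
    breaks <- ux[-length(ux)]
  } else {
    qs <- stats::quantile(x, probs = seq_len(max_bins - 1L) / max_bins,
                          names = FALSE, type = 1L)
    breaks <- sort(unique(qs))
  }
  list(codes = as.integer(findInterval(x, breaks, left.open = TRUE)),
       breaks = breaks)
}

#' Fit a gradient-boosted decision-tree regressor
#'
#' A compact deterministic GBDT with squared-error loss: depth-limited
#' regression trees on histogram-binned features, exact greedy splits, no
#' row/column subsampling, shrinkage `learning_rate`. Constant columns are
#' pruned before fitting. Refitting on identical inputs reproduces
#' identical predictions bit for bit.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y numeric response.
#' @param n_trees number of boosting rounds.
#' @param max_depth maximum tree depth.
#' @param learning_rate shrinkage per tree.
#' @param min_leaf minimum samples per leaf.
#' @param max_bins maximum histogram bins per feature.
#' @return an object of class `gbdt` usable with [predict.gbdt()].
#' @export
gbdt <- function(X, y, n_trees = 500L, max_depth = 6L, learning_rate = 0.1,
                 min_leaf = 5L, max_bins = 32L) {
  stopifnot(nrow(X) == length(y), nrow(X) >= 2L * min_leaf)
  keep <- which(matrixStats_colRange(X) > 0)
  if (!length(keep)) keep <- 1L  # all-constant X: intercept-only model
  binned <- lapply(keep, function(j) bin_column(X[, j], max_bins))
  Xb <- vapply(binned, `[[`, integer(nrow(X)), "codes")
  if (!is.matrix(Xb)) Xb <- matrix(Xb, nrow = nrow(X))
  core <- .gbdt_fit_cpp(Xb, as.numeric(y), as.integer(n_trees),
                        as.integer(max_depth), learning_rate,
                        as.integer(min_leaf), as.integer(max_bins))
  structure(list(core = core, keep = keep,
                 breaks = lapply(binned, `[[`, "breaks"),
                 n_trees = n_trees),
            class = "gbdt")
}

# Range (max - min) per column without matrixStats (not installed).
matrixStats_colRange <- function(X) {
  apply(X, 2L, function(x) max(x) - min(x))
}

#' Predict from a fitted GBDT
#'
#' @param object a `gbdt` model.
#' @param newdata feature matrix with the same columns as at fit time.
#' @param n_trees evaluate the ensemble truncated to this many trees
#'   (default: all) — used to score several tree counts from one fit.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.gbdt <- function(object, newdata, n_trees = object$n_trees, ...) {
  Xb <- vapply(seq_along(object$keep), function(k) {
    as.integer(findInterval(newdata[, object$keep[k]], object$breaks[[k]],
                            left.open = TRUE))
  }, integer(nrow(newdata)))
  if (!is.matrix(Xb)) Xb <- matrix(Xb, nrow = nrow(newdata))
  .gbdt_predict_cpp(object$core, Xb, as.integer(n_trees))
}
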