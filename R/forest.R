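# A compact bagged decision forest (CART with gini splits) for two-class
# problems. The cohorts this package targets are small (tens of samples,
# tens of features), where a plain R implementation is fast enough; it
# exists because no decision-forest package is available in the supported
# dependency set. Randomness: bootstrap resampling per tree and mtry feature
# subsampling per node, both drawn from R's RNG, so wrapping the call in
# set.seed() (or using the adapter's seed) makes training reproducible.

# Best gini split for one feature. y01 is 0/1; returns c(threshold, impurity)
# or NULL when the feature admits no split.
best_split_feature <- function(x, y01) {
  ord <- order(x)
  xs <- unname(x[ord]); ys <- y01[ord]
  n <- length(xs)
  cut_ok <- which(xs[-n] < xs[-1L])    # split between distinct values only
  if (length(cut_ok) == 0L) return(NULL)
  c1 <- cumsum(ys)
  n1 <- c1[n]
  nl <- cut_ok
  l1 <- c1[cut_ok]
  nr <- n - nl
  r1 <- n1 - l1
  gini_l <- 1 - (l1 / nl)^2 - ((nl - l1) / nl)^2
  gini_r <- 1 - (r1 / nr)^2 - ((nr - r1) / nr)^2
  imp <- (nl * gini_l + nr * gini_r) / n
  k <- which.min(imp)
  c(threshold = (xs[cut_ok[k]] + xs[cut_ok[k] + 1L]) / 2, impurity = imp[k])
}

# Recursively grow one CART tree. xs: samples x features; y01: 0/1 outcome.
# Returns a nested list of nodes.
grow_tree <- function(xs, y01, mtry, min_node) {
  n <- length(y01)
  n1 <- sum(y01)
  if (n1 == 0L || n1 == n || n < 2L * min_node) {
    return(list(leaf = TRUE, prob1 = n1 / n))
  }
  p <- ncol(xs)
  feats <- if (mtry < p) sample.int(p, mtry) else seq_len(p)
  best <- NULL
  for (f in feats) {
    sp <- best_split_feature(xs[, f], y01)
    if (!is.null(sp) && (is.null(best) || sp[["impurity"]] < best$impurity)) {
      best <- list(feature = f, threshold = sp[["threshold"]],
                   impurity = sp[["impurity"]])
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, prob1 = n1 / n))
  left <- xs[, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       left = grow_tree(xs[left, , drop = FALSE], y01[left], mtry, min_node),
       right = grow_tree(xs[!left, , drop = FALSE], y01[!left], mtry, min_node))
}

tree_predict_prob <- function(node, xs) {
  if (node$leaf) return(rep(node$prob1, nrow(xs)))
  out <- numeric(nrow(xs))
  left <- xs[, node$feature] <= node$threshold
  if (any(left)) out[left] <- tree_predict_prob(node$left, xs[left, , drop = FALSE])
  if (any(!left)) out[!left] <- tree_predict_prob(node$right, xs[!left, , drop = FALSE])
  out
}

#' Train a bagged decision forest
#'
#' @param X Numeric features x samples matrix.
#' @param y GP/PP labels per sample.
#' @param ntree Number of bootstrap trees (default 500, the usual forest
#'   convention).
#' @param mtry Features tried per split; default `floor(sqrt(p))`.
#' @param min_node Minimum node size to attempt a split (default 1: grow to
#'   purity).
#' @return An object of class `forest_model`.
#' @export
forest_train <- function(X, y, ntree = 500L, mtry = NULL, min_node = 1L) {
  y <- as_prognosis(y)
  if (ncol(X) != length(y)) abort("labels must match samples")
  xs <- t(X)
  p <- ncol(xs); n <- nrow(xs)
  mtry <- mtry %||% max(1L, floor(sqrt(p)))
  y01 <- as.integer(y == "PP")
  trees <- vector("list", ntree)
  for (b in seq_len(ntree)) {
    idx <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- grow_tree(xs[idx, , drop = FALSE], y01[idx], mtry, min_node)
  }
  structure(list(trees = trees, feature_ids = rownames(X)),
            class = "forest_model")
}

#' Predict with a bagged decision forest
#'
#' Majority vote over trees (each tree votes its leaf's majority class);
#' exact vote ties go to GP.
#'
#' @param model A `forest_model`.
#' @param X Numeric features x samples matrix (training features, same
#'   order).
#' @return Factor of GP/PP predictions, named by sample.
#' @export
forest_predict <- function(model, X) {
  if (!identical(rownames(X), model$feature_ids)) {
    abort("feature mismatch: predict needs the training features in order")
  }
  xs <- t(X)
  probs <- vapply(model$trees, function(tr) tree_predict_prob(tr, xs),
                  numeric(nrow(xs)))
  probs <- matrix(probs, nrow = nrow(xs))
  votes <- rowMeans(probs > 0.5)
  pred <- ifelse(votes > 0.5, "PP", "GP")
  stats::setNames(factor(pred, levels = prognosis_levels()), colnames(X))
}
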