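# Tree ensembles built on the compiled CART backend in src/trees.cpp.
# Trees are stored as flat node tables (feature, threshold, left, right, n,
# value, impurity, improvement) so that importance, pure-tree extraction and
# rule printing are plain data manipulations.

as_feature_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

as_binary_label <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (is.character(y)) y <- as.integer(factor(y)) - 1L
  if (!all(y %in% c(0, 1))) stop("labels must be binary")
  as.numeric(y)
}

#' Fit a single classification or regression tree
#'
#' CART with Gini impurity (classification, binary 0/1 labels) or variance
#' reduction (regression). Grown to purity by default (`max_depth = -1`,
#' `min_node = 1`): terminal nodes of the classification tree are then pure
#' whenever the training data are consistent.
#'
#' @param x Feature matrix (samples x features).
#' @param y Labels (binary for classification) or numeric response.
#' @param regression Fit a regression tree.
#' @param mtry Features sampled at each split; default all.
#' @param max_depth Maximum depth (-1 = unlimited).
#' @param min_node Minimum samples per child.
#' @param rows Optional training row indices (for bagging).
#' @return Object of class `valve_tree`.
#' @export
decision_tree <- function(x, y, regression = FALSE, mtry = NULL,
                          max_depth = -1L, min_node = 1L, rows = NULL) {
  x <- as_feature_matrix(x)
  y <- if (regression) as.numeric(y) else as_binary_label(y)
  if (is.null(rows)) rows <- seq_len(nrow(x))
  nodes <- .cpp_grow_tree(x, y, as.integer(rows - 1L), regression,
                          as.integer(mtry %||% ncol(x)),
                          as.integer(max_depth), as.integer(min_node), 1e-12)
  structure(list(nodes = as.data.frame(nodes),
                 features = colnames(x) %||% paste0("f", seq_len(ncol(x))),
                 regression = regression),
            class = "valve_tree")
}

#' @export
predict.valve_tree <- function(object, newdata, ...) {
  .cpp_tree_predict(object$nodes, as_feature_matrix(newdata))
}

#' Fit a random forest
#'
#' Bagged classification trees grown to purity on bootstrap samples with
#' `mtry = floor(sqrt(p))` features per split. Predicted probability of
#' class 1 is the mean of per-tree leaf class proportions; the class vote
#' is probability > 0.5.
#'
#' @param x Feature matrix.
#' @param y Binary labels.
#' @param n_trees Trees in the forest (default 100, the pinned default).
#' @param mtry Features per split; default floor(sqrt(p)).
#' @param min_node Minimum samples per child node.
#' @param seed Integer seed.
#' @return Object of class `valve_forest`.
#' @export
random_forest <- function(x, y, n_trees = 100, mtry = NULL, min_node = 1L,
                          seed = 1L) {
  x <- as_feature_matrix(x)
  y <- as_binary_label(y)
  n <- nrow(x)
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(x))))
  trees <- with_seed(seed, {
    lapply(seq_len(n_trees), function(b) {
      rows <- sample.int(n, n, replace = TRUE)
      decision_tree(x, y, regression = FALSE, mtry = mtry,
                    min_node = min_node, rows = rows)
    })
  })
  structure(list(trees = trees,
                 features = colnames(x) %||% paste0("f", seq_len(ncol(x))),
                 n_trees = n_trees),
            class = "valve_forest")
}

#' @export
predict.valve_forest <- function(object, newdata, type = c("prob", "class"),
                                 ...) {
  type <- match.arg(type)
  newdata <- as_feature_matrix(newdata)
  p <- rowMeans(vapply(object$trees,
                       function(tr) .cpp_tree_predict(tr$nodes, newdata),
                       numeric(nrow(newdata))))
  if (type == "prob") p else as.integer(p > 0.5)
}

#' Fit gradient boosted trees
#'
#' Binary-logistic gradient boosting with depth-limited regression trees fit
#' to the negative gradient and Newton-step leaf values, after Friedman.
#' Pinned defaults: 100 rounds, depth 3, learning rate 0.1.
#'
#' @param x Feature matrix.
#' @param y Binary labels.
#' @param n_rounds Boosting rounds.
#' @param depth Tree depth.
#' @param learning_rate Shrinkage.
#' @param seed Integer seed (subsampling is not used; the seed only affects
#'   split-feature subsampling, which is off by default here).
#' @return Object of class `valve_gbt`.
#' @export
gradient_boosted_trees <- function(x, y, n_rounds = 100, depth = 3,
                                   learning_rate = 0.1, seed = 1L) {
  x <- as_feature_matrix(x)
  y <- as_binary_label(y)
  n <- nrow(x)
  f0 <- stats::qlogis(pmin(pmax(mean(y), 1e-6), 1 - 1e-6))
  fx <- rep(f0, n)
  trees <- vector("list", n_rounds)
  with_seed(seed, {
    for (m in seq_len(n_rounds)) {
      p <- stats::plogis(fx)
      r <- y - p
      tr <- decision_tree(x, r, regression = TRUE, max_depth = depth,
                          min_node = 1L)
      # Newton leaf values: sum(residual) / sum(p(1-p)) per leaf
      leaf <- .cpp_tree_leaf(tr$nodes, x) + 1L
      w <- pmax(p * (1 - p), 1e-12)
      num <- tapply(r, leaf, sum)
      den <- tapply(w, leaf, sum)
      newval <- tr$nodes$value
      newval[as.integer(names(num))] <- as.numeric(num / den)
      tr$nodes$value <- newval
      fx <- fx + learning_rate * .cpp_tree_predict(tr$nodes, x)
      trees[[m]] <- tr
    }
  })
  structure(list(trees = trees, f0 = f0, learning_rate = learning_rate,
                 features = colnames(x) %||% paste0("f", seq_len(ncol(x)))),
            class = "valve_gbt")
}

#' @export
predict.valve_gbt <- function(object, newdata, type = c("prob", "class"),
                              ...) {
  type <- match.arg(type)
  newdata <- as_feature_matrix(newdata)
  fx <- rep(object$f0, nrow(newdata))
  for (tr in object$trees)
    fx <- fx + object$learning_rate * .cpp_tree_predict(tr$nodes, newdata)
  p <- stats::plogis(fx)
  if (type == "prob") p else as.integer(p > 0.5)
}

#' Node-improvement importance weights
#'
#' The weight of a feature is the sum, over every node that splits on it in
#' every tree of the ensemble, of the improvement that split provided at
#' the node: impurity(parent) minus the child-fraction-weighted impurity of
#' the two children (Gini for classification trees, variance for the
#' boosted regression trees). Features never used get weight 0.
#'
#' @param ensemble A `valve_forest`, `valve_gbt`, or single `valve_tree`.
#' @return data.frame of class `importance_table` with columns feature,
#'   weight, rank (ties share the minimum rank).
#' @export
importance_weights <- function(ensemble) {
  trees <- switch(class(ensemble)[1],
                  valve_forest = ensemble$trees,
                  valve_gbt = ensemble$trees,
                  valve_tree = list(ensemble),
                  stop("unfitted or unsupported ensemble"))
  if (length(trees) == 0) stop("ensemble has no trees")
  features <- ensemble$features %||% trees[[1]]$features
  w <- stats::setNames(numeric(length(features)), features)
  for (tr in trees) {
    nd <- tr$nodes
    internal <- nd$feature >= 0
    if (!any(internal)) next
    add <- tapply(nd$improvement[internal], nd$feature[internal] + 1L, sum)
    w[as.integer(names(add))] <- w[as.integer(names(add))] + as.numeric(add)
  }
  out <- data.frame(feature = features, weight = unname(w),
                    rank = rank(-w, ties.method = "min"),
                    stringsAsFactors = FALSE)
  class(out) <- c("importance_table", class(out))
  out
}

#' Extract pure trees from a forest
#'
#' Returns the trees whose predictions on the supplied data make zero
#' classification errors ("pure" trees), each with a readable rule list
#' giving the expression cut-off values along every root-to-leaf path.
#'
#' @param forest A `valve_forest`.
#' @param x Feature matrix to evaluate on (typically the training data).
#' @param y True binary labels.
#' @return List of class `pure_trees`: `index` of pure trees in the forest,
#'   `trees`, and `rules` (character vectors of rule lines).
#' @export
extract_pure_trees <- function(forest, x, y) {
  if (!inherits(forest, "valve_forest")) stop("expected a valve_forest")
  x <- as_feature_matrix(x)
  y <- as_binary_label(y)
  pure <- vapply(forest$trees, function(tr) {
    pred <- as.integer(.cpp_tree_predict(tr$nodes, x) > 0.5)
    all(pred == y)
  }, logical(1))
  idx <- which(pure)
  structure(list(index = idx, trees = forest$trees[idx],
                 rules = lapply(forest$trees[idx], tree_rules)),
            class = "pure_trees")
}

#' Readable rule list for a tree
#'
#' One line per leaf: the conjunction of split conditions (with thresholds,
#' the "expression cut-off values") leading to it, the predicted class and
#' the training sample count.
#'
#' @param tree A `valve_tree`.
#' @return Character vector of rule lines.
#' @export
tree_rules <- function(tree) {
  nd <- tree$nodes
  feats <- tree$features
  out <- character(0)
  recurse <- function(node, conds) {
    if (nd$feature[node] < 0) {
      lab <- if (tree$regression) sprintf("value=%.4g", nd$value[node])
             else sprintf("class=%d (p=%.2f)", as.integer(nd$value[node] > 0.5),
                          nd$value[node])
      cond_txt <- if (length(conds) == 0) "TRUE" else paste(conds, collapse = " & ")
      out <<- c(out, sprintf("IF %s THEN %s [n=%d]", cond_txt, lab, nd$n[node]))
      return(invisible())
    }
    f <- feats[nd$feature[node] + 1L]
    thr <- nd$threshold[node]
    recurse(nd$left[node] + 1L, c(conds, sprintf("%s <= %.4g", f, thr)))
    recurse(nd$right[node] + 1L, c(conds, sprintf("%s > %.4g", f, thr)))
  }
  recurse(1L, character(0))
  out
}
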