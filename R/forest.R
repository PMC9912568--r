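#' Build a leaf node
#'
#' Nodes built with [tree_leaf()] and [tree_split()] nest into a binary
#' decision tree that [tree_ensemble()] accepts. Useful for constructing
#' small ensembles by hand.
#'
#' @param value Case-class probability stored at the leaf, in \[0, 1\].
#' @return A node list.
#' @export
tree_leaf <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1, value >= 0, value <= 1)
  list(leaf = TRUE, value = value)
}

#' Build an internal split node
#'
#' Samples with `x[feature] <= threshold` are routed to `left`, the rest to
#' `right` (the convention used by the common tree libraries, and the one the
#' fitting adapter verifies against).
#'
#' @param feature 1-based feature index tested at this node.
#' @param threshold Split threshold on that feature's abundance.
#' @param left,right Child nodes ([tree_leaf()] or [tree_split()]).
#' @return A node list.
#' @export
tree_split <- function(feature, threshold, left, right) {
  stopifnot(is.numeric(feature), length(feature) == 1, feature >= 1)
  list(leaf = FALSE, feature = as.integer(feature), threshold = threshold,
       left = left, right = right)
}

# nested node -> flat parallel arrays (0-based children, -1 sentinels; leaves
# are the nodes with feature == -1, their threshold slot is 0)
flatten_tree <- function(node) {
  feature <- integer(0); threshold <- numeric(0)
  left <- integer(0); right <- integer(0); value <- numeric(0)
  add <- function(nd) {
    i <- length(feature)
    feature[i + 1L] <<- -1L; threshold[i + 1L] <<- 0
    left[i + 1L] <<- -1L; right[i + 1L] <<- -1L; value[i + 1L] <<- 0
    if (isTRUE(nd$leaf)) {
      value[i + 1L] <<- nd$value
    } else {
      feature[i + 1L] <<- nd$feature - 1L
      threshold[i + 1L] <<- nd$threshold
      left[i + 1L] <<- add(nd$left)
      right[i + 1L] <<- add(nd$right)
    }
    i
  }
  add(node)
  list(feature = feature, threshold = threshold,
       left = left, right = right, value = value)
}

#' Construct a tree ensemble
#'
#' A framework-neutral bagged-tree classifier: a list of binary trees whose
#' leaves hold case-class probabilities; the ensemble prediction is the mean
#' of the per-tree leaf values reached by a sample.
#'
#' @param trees List of trees. Each tree is either a nested node built with
#'   [tree_split()]/[tree_leaf()] or an already-flat list with elements
#'   `feature` (0-based, -1 at leaves), `threshold`, `left`, `right`
#'   (0-based child indices, -1 at leaves) and `value` (leaf values).
#' @param feature_names Character vector naming the feature space (taxon ids).
#' @return An object of class `tree_ensemble`.
#' @export
tree_ensemble <- function(trees, feature_names) {
  stopifnot(length(trees) >= 1, is.character(feature_names))
  n <- length(feature_names)
  trees <- lapply(trees, function(t)
    if (!is.null(t$leaf)) flatten_tree(t) else t)
  for (t in trees) {
    internal <- t$feature >= 0
    if (any(t$feature[internal] >= n))
      stop("tree references feature index beyond the feature space")
    if (any(t$left[internal] < 0) || any(t$right[internal] < 0))
      stop("internal node missing a child")
    leafv <- t$value[!internal]
    if (any(leafv < 0 | leafv > 1))
      stop("leaf values must be probabilities in [0, 1]")
  }
  structure(list(trees = trees, n_features = n, feature_names = feature_names),
            class = "tree_ensemble")
}

#' @export
print.tree_ensemble <- function(x, ...) {
  cat(sprintf("tree_ensemble: %d trees over %d features\n",
              length(x$trees), x$n_features))
  invisible(x)
}

# single flat arrays + offsets, the layout the C++ kernels take
flatten_ensemble <- function(ensemble) {
  tr <- ensemble$trees
  list(feature = as.integer(unlist(lapply(tr, `[[`, "feature"))),
       threshold = as.numeric(unlist(lapply(tr, `[[`, "threshold"))),
       left = as.integer(unlist(lapply(tr, `[[`, "left"))),
       right = as.integer(unlist(lapply(tr, `[[`, "right"))),
       value = as.numeric(unlist(lapply(tr, `[[`, "value"))),
       offset = as.integer(cumsum(c(0L, vapply(tr, function(t) length(t$feature),
                                               integer(1))))[seq_along(tr)]))
}

#' Fit a random-forest case-control classifier
#'
#' Fits a probability random forest on the training table and extracts it
#' into the neutral [tree_ensemble()] representation, so that explanation is
#' independent of the fitting framework. Leaf values are the case-class
#' probabilities of the fitted trees; routing is `x[feature] <= threshold`
#' to the left child.
#'
#' @param train An [abundance_table()] containing both classes.
#' @param n_trees Number of trees (default 500).
#' @param max_depth Maximum tree depth; 0 means unlimited (default).
#' @param seed Integer seed; the fit is deterministic given it.
#' @param mtry Features tried per split; default is the fitting library's
#'   (floor of the square root of the feature count).
#' @return A `tree_ensemble` with the training taxa as feature names.
#' @export
fit_forest <- function(train, n_trees = 500, max_depth = 0, seed = 42,
                       mtry = NULL) {
  stopifnot(inherits(train, "abundance_table"))
  if (n_trees < 1) stop("`n_trees` must be at least 1")
  if (nlevels(droplevels(train$labels)) < 2)
    stop("training data must contain both classes")
  df <- data.frame(train$values, check.names = FALSE)
  colnames(df) <- paste0("f", seq_len(ncol(df)))  # guard against exotic taxon names
  df$.label <- train$labels
  rf <- ranger::ranger(
    dependent.variable.name = ".label", data = df,
    num.trees = n_trees, max.depth = max_depth, mtry = mtry,
    probability = TRUE, seed = seed, num.threads = 1,
    respect.unordered.factors = "ignore")
  trees <- lapply(seq_len(n_trees), function(t) {
    ti <- ranger::treeInfo(rf, t)
    leaf <- ti$terminal
    list(feature = as.integer(ifelse(leaf, -1L, ti$splitvarID)),
         threshold = as.numeric(ifelse(leaf, 0, ti$splitval)),
         left = as.integer(ifelse(leaf, -1L, ti$leftChild)),
         right = as.integer(ifelse(leaf, -1L, ti$rightChild)),
         value = as.numeric(ifelse(leaf, ti$pred.case, 0)))
  })
  ens <- tree_ensemble(trees, colnames(train$values))
  ens$params <- list(n_trees = n_trees, max_depth = max_depth, seed = seed)
  # the underlying fit is kept (attribute, not serialized) so extraction
  # fidelity can be audited against the framework's own predictions
  attr(ens, "fit") <- rf
  ens
}

#' Predict case-class probability
#'
#' Routes each sample down every tree (`x[feature] <= threshold` goes left)
#' and averages the leaf values.
#'
#' @param ensemble A `tree_ensemble`.
#' @param x Abundance vector of length `n_features`, or a samples x features
#'   matrix.
#' @return A probability, or a vector of probabilities for matrix input.
#' @export
predict_proba <- function(ensemble, x) {
  stopifnot(inherits(ensemble, "tree_ensemble"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != ensemble$n_features)
    stop(sprintf("expected %d features, got %d", ensemble$n_features, ncol(x)))
  fl <- flatten_ensemble(ensemble)
  ms_predict(fl$feature, fl$threshold, fl$left, fl$right, fl$value, fl$offset, x)
}

#' Serialize a tree ensemble to JSON
#'
#' Writes the flat node arrays (0-based indices, -1 sentinels) plus the
#' feature names, so a fitted model can be re-explained later without
#' refitting.
#'
#' @param ensemble A `tree_ensemble`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_ensemble <- function(ensemble, path) {
  obj <- list(
    n_features = ensemble$n_features,
    feature_names = ensemble$feature_names,
    trees = lapply(ensemble$trees, function(t)
      list(feature = t$feature, threshold = t$threshold,
           left = t$left, right = t$right, value = t$value)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a tree ensemble from JSON
#'
#' @param path JSON file written by [write_ensemble()].
#' @return A `tree_ensemble`.
#' @export
read_ensemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  trees <- lapply(seq_len(nrow_or_len(obj$trees)), function(i) {
    t <- if (is.data.frame(obj$trees)) lapply(obj$trees, `[[`, i) else obj$trees[[i]]
    list(feature = as.integer(unlist(t$feature)),
         threshold = as.numeric(unlist(t$threshold)),
         left = as.integer(unlist(t$left)),
         right = as.integer(unlist(t$right)),
         value = as.numeric(unlist(t$value)))
  })
  tree_ensemble(trees, as.character(obj$feature_names))
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
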