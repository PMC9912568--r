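as_value_matrix <- function(x) {
  if (inherits(x, "abundance_table")) x$values
  else if (is.matrix(x)) x
  else if (is.numeric(x)) matrix(x, nrow = 1)
  else stop("expected an abundance_table, matrix or numeric vector")
}

#' Expected model output over a background dataset
#'
#' The base value of every explanation: the mean predicted case probability
#' over the background rows (conventionally the training data).
#'
#' @param ensemble A [tree_ensemble()].
#' @param background Background matrix or `abundance_table` (samples x
#'   features, aligned with the ensemble's feature space).
#' @return A probability.
#' @export
base_value <- function(ensemble, background) {
  bg <- as_value_matrix(background)
  if (nrow(bg) == 0) stop("background must contain at least one row")
  mean(predict_proba(ensemble, bg))
}

new_explanation <- function(phi, base, pred, feature_names, feature_values) {
  names(phi) <- feature_names
  structure(list(phi = phi, base_value = base, prediction = pred,
                 feature_names = feature_names,
                 feature_values = stats::setNames(feature_values, feature_names)),
            class = "shap_explanation")
}

#' @export
print.shap_explanation <- function(x, ...) {
  cat(sprintf("shap_explanation: %d features; base %.4f -> prediction %.4f\n",
              length(x$phi), x$base_value, x$prediction))
  top <- order(abs(x$phi), decreasing = TRUE)[seq_len(min(5, length(x$phi)))]
  for (i in top)
    cat(sprintf("  %-30s phi = %+.5f\n", x$feature_names[i], x$phi[i]))
  invisible(x)
}

# v(S, x): mean over background rows of the prediction on the hybrid vector
# taking coordinates in S from x and the rest from the background row.
# Evaluates all 2^n coalitions at once; masks index coalitions bitwise.
coalition_values <- function(ensemble, x, bg) {
  n <- ensemble$n_features
  B <- nrow(bg)
  n_masks <- bitwShiftL(1L, n)
  M <- bg[rep(seq_len(B), times = n_masks), , drop = FALSE]
  masks <- 0:(n_masks - 1L)
  for (j in seq_len(n)) {
    in_s <- bitwAnd(masks, bitwShiftL(1L, j - 1L)) > 0L
    M[rep(in_s, each = B), j] <- x[j]
  }
  preds <- predict_proba(ensemble, M)
  colMeans(matrix(preds, nrow = B))
}

#' Exact Shapley values by subset enumeration
#'
#' Computes, for every feature i, the classical Shapley sum
#' `phi_i = sum over S of |S|! (n - |S| - 1)! / n! * (v(S + i) - v(S))`
#' where the value of a coalition S is the mean model output over the
#' background data with the coordinates in S taken from the explained
#' sample (the interventional value function). Cost is `2^n` coalition
#' evaluations, so the feature count is capped at 20; use [shap_fast()]
#' beyond toy sizes.
#'
#' @param ensemble A [tree_ensemble()].
#' @param x Abundance vector of length `n_features`.
#' @param background Background matrix or `abundance_table`.
#' @return A `shap_explanation` with fields `phi`, `base_value`,
#'   `prediction`, `feature_names`, `feature_values`.
#' @export
shap_exact <- function(ensemble, x, background) {
  n <- ensemble$n_features
  if (n > 20)
    stop("shap_exact enumerates 2^n coalitions and is limited to n <= 20 ",
         "features; use shap_fast()")
  if (length(x) != n)
    stop(sprintf("expected %d features, got %d", n, length(x)))
  bg <- as_value_matrix(background)
  if (nrow(bg) == 0) stop("background must contain at least one row")
  v <- coalition_values(ensemble, x, bg)
  n_masks <- bitwShiftL(1L, n)
  masks <- 0:(n_masks - 1L)
  pc <- integer(n_masks)                     # popcounts
  for (m in seq_len(n_masks - 1L))
    pc[m + 1L] <- pc[bitwShiftR(m, 1L) + 1L] + (m %% 2L)
  w <- exp(lfactorial(0:(n - 1)) + lfactorial(n - (0:(n - 1)) - 1) - lfactorial(n))
  phi <- numeric(n)
  for (j in seq_len(n)) {
    bit <- bitwShiftL(1L, j - 1L)
    S <- masks[bitwAnd(masks, bit) == 0L]
    phi[j] <- sum(w[pc[S + 1L] + 1L] * (v[S + bit + 1L] - v[S + 1L]))
  }
  new_explanation(phi, v[1L], v[n_masks], ensemble$feature_names, x)
}

#' Fast exact interventional Shapley values for tree ensembles
#'
#' Produces the same attributions as [shap_exact()] without the `2^n`
#' enumeration. For each (tree, background row) pair the tree is walked
#' once: every root-to-leaf path partitions its features into those whose
#' split conditions only the explained sample satisfies and those only the
#' background row satisfies, for which the coalition-weight sums have a
#' closed form. Complexity is linear in trees x background rows x nodes.
#'
#' @inheritParams shap_exact
#' @return A `shap_explanation`.
#' @export
shap_fast <- function(ensemble, x, background) {
  n <- ensemble$n_features
  if (length(x) != n)
    stop(sprintf("expected %d features, got %d", n, length(x)))
  bg <- as_value_matrix(background)
  if (nrow(bg) == 0) stop("background must contain at least one row")
  fl <- flatten_ensemble(ensemble)
  phi <- ms_shap(fl$feature, fl$threshold, fl$left, fl$right, fl$value,
                 fl$offset, matrix(x, nrow = 1), bg)[1, ]
  new_explanation(phi, base_value(ensemble, bg),
                  predict_proba(ensemble, matrix(x, nrow = 1)),
                  ensemble$feature_names, x)
}

#' Explain every sample of a table
#'
#' Runs the fast interventional Shapley engine over all rows of `table`,
#' giving the m x n attribution matrix that mirrors the input's shape.
#'
#' @param ensemble A [tree_ensemble()].
#' @param table An [abundance_table()] (or matrix) whose columns are exactly
#'   the ensemble's feature space.
#' @param background Background matrix or `abundance_table` (typically the
#'   training data).
#' @param background_size Optional integer; if smaller than the background
#'   row count, the background is subsampled to this many rows (seeded) to
#'   trade base-value exactness for speed.
#' @param seed Seed for the background subsample.
#' @return A `shap_matrix`: list with `values` (m x n), `base_value`,
#'   `predictions`, `sample_ids`, `feature_names`.
#' @export
explain_table <- function(ensemble, table, background,
                          background_size = NULL, seed = 42) {
  X <- as_value_matrix(table)
  if (!is.null(colnames(X)) &&
      !identical(colnames(X), ensemble$feature_names))
    stop("table features do not match the ensemble's feature space")
  if (ncol(X) != ensemble$n_features)
    stop(sprintf("expected %d features, got %d", ensemble$n_features, ncol(X)))
  bg <- as_value_matrix(background)
  if (nrow(bg) == 0) stop("background must contain at least one row")
  if (!is.null(background_size) && background_size < nrow(bg)) {
    set.seed(seed)
    bg <- bg[sort(sample.int(nrow(bg), background_size)), , drop = FALSE]
  }
  fl <- flatten_ensemble(ensemble)
  vals <- ms_shap(fl$feature, fl$threshold, fl$left, fl$right, fl$value,
                  fl$offset, X, bg)
  dimnames(vals) <- list(rownames(X), ensemble$feature_names)
  structure(list(values = vals,
                 base_value = base_value(ensemble, bg),
                 predictions = stats::setNames(predict_proba(ensemble, X),
                                               rownames(X)),
                 sample_ids = rownames(X),
                 feature_names = ensemble$feature_names),
            class = "shap_matrix")
}

#' @export
print.shap_matrix <- function(x, ...) {
  cat(sprintf("shap_matrix: %d samples x %d features; base value %.4f\n",
              nrow(x$values), ncol(x$values), x$base_value))
  invisible(x)
}

#' Extract one row of a shap_matrix as an explanation
#'
#' @param shap A `shap_matrix`.
#' @param i Row index or sample id.
#' @param feature_values Optional abundance vector for the sample (stored in
#'   the explanation for reporting); defaults to NA.
#' @return A `shap_explanation`.
#' @export
explanation_for <- function(shap, i, feature_values = NULL) {
  if (is.character(i)) i <- match(i, shap$sample_ids)
  if (is.na(i) || i < 1 || i > nrow(shap$values)) stop("sample not found")
  if (is.null(feature_values))
    feature_values <- rep(NA_real_, length(shap$feature_names))
  new_explanation(shap$values[i, ], shap$base_value, shap$predictions[[i]],
                  shap$feature_names, feature_values)
}

#' Global feature importance from a SHAP matrix
#'
#' The dataset-level importance of a taxon is the mean of the absolute SHAP
#' values it receives across samples.
#'
#' @param shap A `shap_matrix`.
#' @return Named numeric vector sorted in decreasing importance (ties broken
#'   by taxon name).
#' @export
global_importance <- function(shap) {
  imp <- colMeans(abs(shap$values))
  imp[order(-imp, names(imp))]
}

#' Write / read a SHAP matrix
#'
#' The attribution matrix goes to a samples x taxa TSV; the base value and
#' per-sample predictions go to a JSON sidecar.
#'
#' @param shap A `shap_matrix`.
#' @param path TSV output path.
#' @param json_path Sidecar path; defaults to `path` with a `.json` suffix.
#' @return Invisibly, `path`.
#' @export
write_shap_matrix <- function(shap, path, json_path = paste0(path, ".json")) {
  df <- data.frame(sample_id = shap$sample_ids, shap$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(base_value = shap$base_value,
         predictions = as.list(shap$predictions)),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_shap_matrix
#' @export
read_shap_matrix <- function(path, json_path = paste0(path, ".json")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  structure(list(values = vals,
                 base_value = meta$base_value,
                 predictions = stats::setNames(as.numeric(meta$predictions),
                                               names(meta$predictions)),
                 sample_ids = rownames(vals),
                 feature_names = colnames(vals)),
            class = "shap_matrix")
}
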