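#' PCA embedding of a SHAP (or abundance) matrix
#'
#' Column-centers the matrix without scaling (SHAP columns share probability
#' units) and projects onto the top principal components. Signs are fixed
#' for reproducibility and comparability across datasets: PC1 is flipped so
#' that the mean score of case-labeled samples is non-negative (cases sit on
#' the right); every other component is flipped so its largest-magnitude
#' loading is positive. Without labels the loading rule is applied to PC1
#' too.
#'
#' @param x A `shap_matrix`, `abundance_table` or plain samples x features
#'   matrix.
#' @param n_components Number of components (default 2).
#' @param labels Optional per-sample labels (`control`/`case`) used to
#'   orient PC1.
#' @return A `shap_embedding`: list with `scores` (m x n_components),
#'   `loadings` (features x n_components, orthonormal columns),
#'   `explained_variance_ratio` and `sample_ids`.
#' @export
pca_embed <- function(x, n_components = 2, labels = NULL) {
  X <- if (inherits(x, "shap_matrix")) x$values else as_value_matrix(x)
  m <- nrow(X)
  if (m <= n_components)
    stop("need more samples than components to embed")
  if (!is.null(labels) && length(labels) != m)
    stop("labels must have one entry per sample")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  scores <- p$x[, k, drop = FALSE]
  loadings <- p$rotation[, k, drop = FALSE]
  evr <- (p$sdev^2 / sum(p$sdev^2))[k]
  for (j in k) {
    flip <- if (j == 1 && !is.null(labels)) {
      mu <- mean(scores[as.character(labels) == "case", 1])
      !is.na(mu) && mu < 0
    } else {
      loadings[which.max(abs(loadings[, j])), j] < 0
    }
    if (flip) {
      scores[, j] <- -scores[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  colnames(scores) <- colnames(loadings) <- paste0("PC", k)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_ratio = evr,
                 sample_ids = rownames(X)),
            class = "shap_embedding")
}

#' @export
print.shap_embedding <- function(x, ...) {
  cat(sprintf("shap_embedding: %d samples x %d components (%s%% variance)\n",
              nrow(x$scores), ncol(x$scores),
              paste(round(100 * x$explained_variance_ratio, 1),
                    collapse = "% + ")))
  invisible(x)
}

#' Keep the correctly predicted case subjects
#'
#' Subsets a SHAP matrix to the rows that are labeled `case` and whose
#' predicted case probability is strictly above `threshold`; this is the
#' subset that gets embedded and subtyped.
#'
#' @param shap A `shap_matrix`.
#' @param labels Per-sample labels aligned with the matrix rows.
#' @param predictions Per-sample case probabilities; defaults to the ones
#'   stored in `shap`.
#' @param threshold Decision threshold (default 0.5, strict).
#' @return A `shap_matrix` restricted to the selected rows.
#' @export
select_correct_cases <- function(shap, labels, predictions = shap$predictions,
                                 threshold = 0.5) {
  m <- nrow(shap$values)
  if (length(labels) != m || length(predictions) != m)
    stop("labels and predictions must align with the SHAP matrix rows")
  keep <- as.character(labels) == "case" & predictions > threshold
  shap$values <- shap$values[keep, , drop = FALSE]
  shap$predictions <- shap$predictions[keep]
  shap$sample_ids <- shap$sample_ids[keep]
  shap
}

# k-means++ seeding followed by Lloyd iterations; best of `restarts` by
# within-cluster SSE. Deterministic given seed.
kmeans_fit <- function(points, k, seed, restarts = 10) {
  points <- as.matrix(points)
  m <- nrow(points)
  if (k > m) stop("k must not exceed the number of points")
  if (k == 1) {
    center <- colMeans(points)
    return(list(cluster = rep(1L, m),
                inertia = sum(sweep(points, 2, center)^2),
                centers = matrix(center, 1)))
  }
  uniq <- unique(points)
  if (nrow(uniq) <= k) {
    # fewer distinct points than clusters: each distinct point is a center
    key <- apply(points, 1, paste, collapse = "\r")
    labels <- match(key, apply(uniq, 1, paste, collapse = "\r"))
    centers <- uniq[c(seq_len(nrow(uniq)),
                      rep(1L, k - nrow(uniq))), , drop = FALSE]
    return(list(cluster = labels, inertia = 0, centers = centers))
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- points[sample.int(m, 1), , drop = FALSE]
    while (nrow(centers) < k) {
      d2 <- apply(points, 1, function(p)
        min(colSums((t(centers) - p)^2)))
      if (sum(d2) == 0) {
        centers <- rbind(centers, points[sample.int(m, 1), , drop = FALSE])
      } else {
        centers <- rbind(centers,
                         points[sample.int(m, 1, prob = d2), , drop = FALSE])
      }
    }
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(points, centers = centers,
                                     algorithm = "Lloyd", iter.max = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed for every restart")
  list(cluster = best$cluster, inertia = best$tot.withinss,
       centers = best$centers)
}

#' Choose the cluster count by the elbow method
#'
#' Runs seeded K-means for k = 1..k_max, records the within-cluster
#' sum-of-squares (inertia) curve, and returns the k whose point on the
#' curve lies farthest (perpendicular distance) from the chord joining
#' (1, inertia_1) and (k_max, inertia_k_max); ties break toward smaller k.
#'
#' @param points Samples x dims matrix (typically the m x 2 PC scores).
#' @param k_max Largest k to consider (default 10); requires at least
#'   `k_max` points.
#' @param seed Seed for the K-means restarts.
#' @return The chosen k, with the inertia curve attached as attribute
#'   `"inertia_curve"`.
#' @export
choose_k_elbow <- function(points, k_max = 10, seed = 42) {
  points <- as.matrix(points)
  if (nrow(points) < k_max)
    stop("need at least k_max points to scan k = 1..k_max")
  inertia <- vapply(seq_len(k_max), function(k)
    kmeans_fit(points, k, seed = seed + k)$inertia, numeric(1))
  # perpendicular distance from (k, I_k) to the chord (1, I_1)-(k_max, I_kmax)
  x1 <- 1; y1 <- inertia[1]; x2 <- k_max; y2 <- inertia[k_max]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  ks <- seq_len(k_max)
  dist <- if (len == 0) rep(0, k_max) else
    abs((y2 - y1) * ks - (x2 - x1) * inertia + x2 * y1 - y2 * x1) / len
  k <- ks[which.max(dist)]  # which.max takes the first maximum: smallest k
  attr(k, "inertia_curve") <- inertia
  k
}

#' K-means subtyping of case subjects
#'
#' Lloyd's algorithm with k-means++ seeding, best of `restarts` seeded
#' restarts by inertia. When per-sample case probabilities are supplied the
#' clusters are renumbered by decreasing median probability, so cluster 1 is
#' always the highest-probability subgroup and indices are comparable
#' across datasets; otherwise clusters are renumbered by decreasing size.
#'
#' @param points Samples x dims matrix (typically m x 2 PC scores).
#' @param k Number of clusters (at most the number of points).
#' @param seed Integer seed; the result is deterministic given it.
#' @param probabilities Optional per-sample case probabilities.
#' @param restarts Number of k-means++ restarts (default 10).
#' @return A `cluster_result`: list with `labels` (1..k, aligned with the
#'   rows of `points`), `k`, `inertia`, `centers` and
#'   `per_cluster_probability` (median and quartiles per cluster, NULL when
#'   no probabilities were given).
#' @export
kmeans_cluster <- function(points, k, seed = 42, probabilities = NULL,
                           restarts = 10) {
  points <- as.matrix(points)
  if (!is.null(probabilities) && length(probabilities) != nrow(points))
    stop("probabilities must align with the rows of points")
  fit <- kmeans_fit(points, k, seed = seed, restarts = restarts)
  labels <- fit$cluster
  ord <- if (!is.null(probabilities)) {
    med <- vapply(seq_len(k), function(c)
      stats::median(probabilities[labels == c]), numeric(1))
    order(-med)
  } else {
    order(-tabulate(labels, k), seq_len(k))
  }
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels <- relabel[labels]
  names(labels) <- rownames(points)
  per_cluster <- NULL
  if (!is.null(probabilities)) {
    per_cluster <- do.call(rbind, lapply(seq_len(k), function(c) {
      q <- stats::quantile(probabilities[labels == c], c(.25, .5, .75),
                           names = FALSE)
      data.frame(cluster = c, n = sum(labels == c),
                 q1 = q[1], median = q[2], q3 = q[3])
    }))
  }
  structure(list(labels = labels, k = k, inertia = fit$inertia,
                 centers = fit$centers[ord, , drop = FALSE],
                 per_cluster_probability = per_cluster),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: k = %d, inertia %.4g\n", x$k, x$inertia))
  if (!is.null(x$per_cluster_probability)) {
    p <- x$per_cluster_probability
    for (i in seq_len(nrow(p)))
      cat(sprintf("  cluster %d: n = %d, median probability %.3f [%.3f, %.3f]\n",
                  p$cluster[i], p$n[i], p$median[i], p$q1[i], p$q3[i]))
  }
  invisible(x)
}
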