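fake_shap <- function(values, base = 0.5, preds = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("s%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("t%02d", seq_len(ncol(values)))
  if (is.null(preds)) preds <- base + rowSums(values)
  structure(list(values = values, base_value = base,
                 predictions = stats::setNames(preds, rownames(values)),
                 sample_ids = rownames(values),
                 feature_names = colnames(values)),
            class = "shap_matrix")
}

test_that("a rank-1 matrix is fully explained by the first component", {
  set.seed(1)
  v <- outer(rnorm(8), c(1, 2, -1)) * 0.05
  emb <- pca_embed(fake_shap(v))
  expect_equal(emb$explained_variance_ratio, c(1, 0), tolerance = 1e-12)
})

test_that("two components reconstruct a rank-2 matrix exactly", {
  set.seed(2)
  v <- (outer(rnorm(10), c(1, 0, 1, 2)) + outer(rnorm(10), c(0, 1, -1, 0))) * 0.03
  emb <- pca_embed(fake_shap(v))
  centered <- scale(v, center = TRUE, scale = FALSE)
  recon <- emb$scores %*% t(emb$loadings)
  expect_equal(unname(recon), unname(centered[, ]), tolerance = 1e-8)
})

test_that("scores match an independent covariance eigendecomposition", {
  v <- matrix(c(0.1, 0.2, 0.05, 0.3, 0.02, 0.15,
                0.07, 0.25, 0.12, 0.01, 0.22, 0.09,
                0.3, 0.02, 0.18, 0.11, 0.04, 0.27), 6, 3) * 0.5
  emb <- pca_embed(fake_shap(v))
  centered <- scale(v, center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(centered), symmetric = TRUE)
  oracle <- centered %*% eig$vectors[, 1:2]
  # components agree up to sign
  for (j in 1:2)
    expect_equal(abs(unname(emb$scores[, j])), abs(unname(oracle[, j])),
                 tolerance = 1e-8)
  # loading columns are orthonormal; variance ratios sorted and sum <= 1
  expect_equal(crossprod(emb$loadings), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(diff(emb$explained_variance_ratio) <= 0)
  expect_lte(sum(emb$explained_variance_ratio), 1 + 1e-12)
})

test_that("PC1 is oriented so case samples sit on the positive side", {
  set.seed(3)
  v <- rbind(matrix(rnorm(20, -0.1, 0.02), 5), matrix(rnorm(20, 0.1, 0.02), 5))
  labels <- rep(c("control", "case"), each = 5)
  emb <- pca_embed(fake_shap(v), labels = labels)
  expect_gte(mean(emb$scores[labels == "case", 1]), 0)
  # and the flip is applied consistently to scores and loadings
  centered <- scale(v, center = TRUE, scale = FALSE)
  expect_equal(unname(emb$scores), unname(centered %*% emb$loadings),
               tolerance = 1e-10)
  expect_error(pca_embed(fake_shap(v[1:2, ])), "more samples")
})

test_that("select_correct_cases keeps strictly-above-threshold case rows", {
  v <- matrix(0.01, 4, 2)
  sm <- fake_shap(v, preds = c(0.73, 0.9, 0.5, 0.51))
  labels <- c("case", "control", "case", "case")
  kept <- select_correct_cases(sm, labels)
  # case at 0.73 kept; control at 0.9 dropped; case at exactly 0.5 dropped
  expect_identical(kept$sample_ids, c("s01", "s04"))
  expect_equal(unname(kept$predictions), c(0.73, 0.51))
  expect_error(select_correct_cases(sm, labels[1:2]), "align")
})

test_that("the elbow criterion recovers planted cluster counts", {
  set.seed(21)
  blob <- function(cx, cy, n = 30) cbind(stats::rnorm(n, cx), stats::rnorm(n, cy))
  four <- rbind(blob(0, 0), blob(12, 0), blob(0, 12), blob(12, 12))
  expect_equal(as.integer(choose_k_elbow(four, k_max = 10, seed = 1)), 4L)
  two <- rbind(blob(-10, 0), blob(10, 0))
  expect_equal(as.integer(choose_k_elbow(two, k_max = 10, seed = 1)), 2L)
  # degenerate: identical points give a flat curve and k = 1
  ident <- matrix(1, 15, 2)
  expect_equal(as.integer(choose_k_elbow(ident, k_max = 10, seed = 1)), 1L)
  expect_error(choose_k_elbow(ident[1:5, ], k_max = 10), "k_max")
  # the attached inertia curve is non-increasing
  expect_true(all(diff(attr(choose_k_elbow(four, 8, seed = 1),
                            "inertia_curve")) <= 1e-8))
})

test_that("kmeans_cluster recovers planted blobs and renumbers by probability", {
  set.seed(22)
  pts <- rbind(cbind(stats::rnorm(20, -10), stats::rnorm(20)),
               cbind(stats::rnorm(20, 10), stats::rnorm(20)))
  rownames(pts) <- sprintf("p%02d", 1:40)
  truth <- rep(1:2, each = 20)
  cl <- kmeans_cluster(pts, 2, seed = 5)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(cl$labels, truth), 1)
  # labels equal the sign of x up to renumbering
  expect_equal(length(unique(cl$labels[pts[, 1] > 0])), 1L)
  # determinism
  cl2 <- kmeans_cluster(pts, 2, seed = 5)
  expect_identical(cl$labels, cl2$labels)
  # renumbering: the high-probability blob must be cluster 1
  probs <- ifelse(pts[, 1] > 0, 0.9, 0.6) + stats::runif(40, 0, 0.01)
  clp <- kmeans_cluster(pts, 2, seed = 5, probabilities = probs)
  expect_equal(unique(unname(clp$labels[pts[, 1] > 0])), 1L)
  expect_true(all(diff(clp$per_cluster_probability$median) <= 0))
  # k = m puts every point in its own cluster with zero inertia
  few <- pts[1:5, ]
  clm <- kmeans_cluster(few, 5, seed = 1)
  expect_equal(sort(unname(clm$labels)), 1:5)
  expect_equal(clm$inertia, 0)
  expect_error(kmeans_cluster(few, 6, seed = 1), "exceed")
})
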