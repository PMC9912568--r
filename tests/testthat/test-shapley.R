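test_that("base_value is the mean model output over the background", {
  e1 <- tree_ensemble(list(tree_leaf(0.7)), "t1")
  expect_equal(base_value(e1, matrix(runif(5))), 0.7)
  e2 <- tree_ensemble(list(tree_split(1, 0.5, tree_leaf(0.1), tree_leaf(0.9))),
                      "t1")
  expect_equal(base_value(e2, matrix(c(0.2, 0.8), 2)), 0.5)
  # a single background row makes the base value that row's prediction
  x <- matrix(0.7, 1, 1)
  expect_equal(base_value(e2, x), predict_proba(e2, x))
  expect_error(base_value(e2, matrix(numeric(0), 0, 1)), "at least one")
})

test_that("a single feature receives the full prediction-minus-base gap", {
  ens <- tree_ensemble(list(tree_split(1, 0.5, tree_leaf(0.2), tree_leaf(0.8))),
                      "t1")
  bg <- matrix(c(0.1, 0.9), 2)
  ex <- shap_exact(ens, 0.7, bg)
  expect_equal(unname(ex$phi), ex$prediction - ex$base_value)
})

test_that("features unused by every tree get exactly zero attribution", {
  # trees split only on feature 1; features 2 and 3 are dummies
  ens <- tree_ensemble(list(
    tree_split(1, 0.3, tree_leaf(0.2), tree_leaf(0.9)),
    tree_split(1, 0.6, tree_leaf(0.4), tree_leaf(0.7))), paste0("t", 1:3))
  set.seed(2)
  bg <- matrix(runif(12), 4, 3)
  for (i in 1:5) {
    x <- runif(3)
    expect_identical(unname(shap_exact(ens, x, bg)$phi[2:3]), c(0, 0))
    expect_identical(unname(shap_fast(ens, x, bg)$phi[2:3]), c(0, 0))
  }
})

test_that("subset-weight formula agrees with the all-orderings permutation oracle", {
  set.seed(31)
  # the spec's structured case: two trees on two different features of three
  ens <- tree_ensemble(list(
    tree_split(1, 0.4, tree_leaf(0.1), tree_leaf(0.8)),
    tree_split(3, 0.5, tree_leaf(0.6), tree_leaf(0.3))), paste0("t", 1:3))
  bg <- matrix(c(0.2, 0.9, 0.7, 0.6, 0.1, 0.9), 2, 3)
  x <- c(0.5, 0.5, 0.2)
  expect_equal(unname(shap_exact(ens, x, bg)$phi), perm_shap_oracle(ens, x, bg),
               tolerance = 1e-12)
  # random ensembles up to n = 5
  for (i in 1:6) {
    n <- sample(2:5, 1)
    ens <- rand_ensemble(n, 2, 3)
    x <- runif(n); bg <- matrix(runif(3 * n), 3, n)
    expect_equal(unname(shap_exact(ens, x, bg)$phi),
                 perm_shap_oracle(ens, x, bg), tolerance = 1e-10)
  }
})

test_that("fast tree algorithm reproduces exact enumeration", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(2:8, 1)
    ens <- rand_ensemble(n, sample(1:4, 1), sample(1:4, 1))
    x <- runif(n); bg <- matrix(runif(4 * n), 4, n)
    ee <- shap_exact(ens, x, bg)
    ef <- shap_fast(ens, x, bg)
    expect_equal(ef$phi, ee$phi, tolerance = 1e-10)
    expect_equal(ef$base_value, ee$base_value, tolerance = 1e-12)
    expect_equal(ef$prediction, ee$prediction, tolerance = 1e-12)
  }
})

test_that("local accuracy: base value plus attributions equals the prediction", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(2:7, 1)
    ens <- rand_ensemble(n, 3, 3)
    x <- runif(n); bg <- matrix(runif(5 * n), 5, n)
    for (ex in list(shap_exact(ens, x, bg), shap_fast(ens, x, bg)))
      expect_equal(ex$base_value + sum(ex$phi), ex$prediction,
                   tolerance = 1e-10)
  }
})

test_that("explaining a sample against itself as background gives zero attributions", {
  set.seed(41)
  ens <- rand_ensemble(4, 3, 3)
  x <- runif(4)
  ex <- shap_fast(ens, x, matrix(x, 1))
  expect_equal(unname(ex$phi), rep(0, 4))
})

test_that("attribution is linear over the tree-mean aggregation", {
  set.seed(43)
  t1 <- rand_tree(3, 3); t2 <- rand_tree(3, 3)
  nm <- paste0("t", 1:3)
  x <- runif(3); bg <- matrix(runif(9), 3, 3)
  both <- shap_fast(tree_ensemble(list(t1, t2), nm), x, bg)
  e1 <- shap_fast(tree_ensemble(list(t1), nm), x, bg)
  e2 <- shap_fast(tree_ensemble(list(t2), nm), x, bg)
  expect_equal(both$phi, (e1$phi + e2$phi) / 2, tolerance = 1e-12)
  # duplicating a tree leaves the explanation unchanged
  dup <- shap_fast(tree_ensemble(list(t1, t1), nm), x, bg)
  expect_equal(dup$phi, e1$phi, tolerance = 1e-12)
})

test_that("symmetric features receive equal attributions on symmetric inputs", {
  # two mirrored trees use features 1 and 2 identically
  ens <- tree_ensemble(list(
    tree_split(1, 0.5, tree_leaf(0.2), tree_leaf(0.8)),
    tree_split(2, 0.5, tree_leaf(0.2), tree_leaf(0.8))), c("a", "b"))
  bg <- matrix(c(0.1, 0.9, 0.1, 0.9), 2, 2)  # symmetric background
  ex <- shap_fast(ens, c(0.7, 0.7), bg)
  expect_equal(ex$phi[["a"]], ex$phi[["b"]], tolerance = 1e-12)
})

test_that("shap_exact refuses feature spaces beyond enumeration reach", {
  ens <- tree_ensemble(list(tree_leaf(0.5)), paste0("t", 1:21))
  expect_error(shap_exact(ens, runif(21), matrix(runif(21), 1)), "n <= 20")
})

test_that("explain_table matches row-by-row exact explanations", {
  set.seed(53)
  ens <- rand_ensemble(3, 3, 3)
  X <- matrix(runif(15), 5, 3,
              dimnames = list(sprintf("s%d", 1:5), paste0("taxon_", 1:3)))
  bg <- matrix(runif(12), 4, 3)
  sm <- explain_table(ens, X, bg)
  expect_equal(dim(sm$values), dim(X))
  for (i in 1:5) {
    ee <- shap_exact(ens, X[i, ], bg)
    expect_equal(unname(sm$values[i, ]), unname(ee$phi), tolerance = 1e-10)
    expect_equal(sm$base_value + sum(sm$values[i, ]), sm$predictions[[i]],
                 tolerance = 1e-10)
  }
  # single-row table equals shap_fast
  sm1 <- explain_table(ens, X[1, , drop = FALSE], bg)
  expect_equal(sm1$values[1, ], shap_fast(ens, X[1, ], bg)$phi)
  # feature mismatch is an error
  bad <- X; colnames(bad) <- paste0("other_", 1:3)
  expect_error(explain_table(ens, bad, bg), "feature space")
})

test_that("global importance is the mean absolute attribution, sorted", {
  sm <- structure(list(
    values = matrix(c(0.3, -0.1, 0, 0, 0.05, 0.15), 2, 3,
                    dimnames = list(c("s1", "s2"), c("a", "zero", "b"))),
    base_value = 0.5, predictions = c(s1 = 0.7, s2 = 0.6),
    sample_ids = c("s1", "s2"), feature_names = c("a", "zero", "b")),
    class = "shap_matrix")
  imp <- global_importance(sm)
  expect_equal(imp[["a"]], 0.2)           # (0.3 + 0.1) / 2
  expect_equal(imp[["zero"]], 0)
  expect_identical(names(imp)[3], "zero") # all-zero column ranked last
  expect_true(all(diff(imp) <= 0))
  # single row: importance equals |phi|
  sm$values <- sm$values[1, , drop = FALSE]
  sm$sample_ids <- "s1"; sm$predictions <- sm$predictions[1]
  expect_equal(unname(global_importance(sm)), c(0.3, 0.05, 0))
})

test_that("shap matrices round-trip through TSV plus JSON sidecar", {
  set.seed(59)
  ens <- rand_ensemble(3, 2, 2)
  X <- matrix(runif(9), 3, 3,
              dimnames = list(sprintf("s%d", 1:3), paste0("taxon_", 1:3)))
  sm <- explain_table(ens, X, X)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_shap_matrix(sm, path)
  back <- read_shap_matrix(path)
  expect_equal(back$values, sm$values)
  expect_equal(back$base_value, sm$base_value)
  expect_equal(back$predictions, sm$predictions)
})
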