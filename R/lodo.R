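#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic divided
#' by `n_case * n_control`; tied scores count one half.
#'
#' @param labels Vector with values `control`/`case` (or a factor with those
#'   levels).
#' @param scores Numeric case-probability scores, same length.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(labels, scores) {
  labels <- as.character(labels)
  stopifnot(length(labels) == length(scores))
  is_case <- labels == "case"
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores)  # midranks handle ties
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Split studies into train and test for one LODO iteration
#'
#' The held-out study becomes the test set; all remaining studies are
#' concatenated on the union of their taxon sets (missing taxa zero-filled)
#' as the training set, and the test study is aligned onto that same space.
#'
#' @param tables A list of [abundance_table()]s (one or more studies each),
#'   or a single multi-study table.
#' @param test_study Name of the study to hold out.
#' @return List with elements `train` and `test`.
#' @export
lodo_split <- function(tables, test_study) {
  if (inherits(tables, "abundance_table")) tables <- list(tables)
  combined <- bind_tables(tables)
  studies <- unique(combined$study)
  if (length(studies) < 2) stop("LODO needs at least two studies")
  if (!test_study %in% studies)
    stop("unknown study: ", test_study,
         " (available: ", paste(studies, collapse = ", "), ")")
  is_test <- combined$study == test_study
  train <- subset_samples(combined, !is_test)
  test <- align_taxa(subset_samples(combined, is_test),
                     colnames(train$values))
  list(train = train, test = test)
}

#' Run the full leave-one-dataset-out analysis
#'
#' For every study in turn: hold it out; filter the training concatenation
#' (abundance filter, then train-derived prevalence filter); align the test
#' study onto the retained taxa (absent taxa become zero columns, so no
#' information flows from test to train); fit the random forest; score the
#' held-out samples (AUC); and, when `explain = TRUE`, attribute every test
#' prediction with the Shapley engine using the filtered training matrix as
#' background.
#'
#' @param tables List of [abundance_table()]s or a single multi-study table.
#' @param n_trees,max_depth,seed Forest hyperparameters, see [fit_forest()].
#' @param abundance_threshold,prevalence_threshold Filtering thresholds, see
#'   [filter_abundance()] and [filter_prevalence()].
#' @param background_size Optional background subsample size for the
#'   explanation stage (see [explain_table()]).
#' @param explain Compute SHAP matrices (default TRUE); disable for
#'   AUC-only runs.
#' @return A list of class `lodo_results`; one element per study, each a
#'   `lodo_result` with `test_study`, `auc`, `predictions`, `labels`,
#'   `retained_taxa`, `shap` (NULL when `explain = FALSE`), `test`
#'   (the filtered, aligned test table) and `ensemble`.
#' @export
run_lodo <- function(tables, n_trees = 500, max_depth = 0, seed = 42,
                     abundance_threshold = 1e-15, prevalence_threshold = 0.9,
                     background_size = NULL, explain = TRUE) {
  if (inherits(tables, "abundance_table")) tables <- list(tables)
  studies <- unique(unlist(lapply(tables, `[[`, "study")))
  if (length(studies) < 2) stop("LODO needs at least two studies")
  res <- lapply(studies, function(s) {
    sp <- lodo_split(tables, s)
    train <- filter_prevalence(
      filter_abundance(sp$train, abundance_threshold), prevalence_threshold)
    test <- align_taxa(filter_abundance(sp$test, abundance_threshold),
                       colnames(train$values))
    ens <- fit_forest(train, n_trees = n_trees, max_depth = max_depth,
                      seed = seed)
    preds <- stats::setNames(predict_proba(ens, test$values),
                             rownames(test$values))
    shap <- if (explain)
      explain_table(ens, test, train$values,
                    background_size = background_size, seed = seed)
    structure(list(test_study = s,
                   auc = compute_auc(test$labels, preds),
                   predictions = preds,
                   labels = test$labels,
                   retained_taxa = colnames(train$values),
                   shap = shap,
                   test = test,
                   ensemble = ens),
              class = "lodo_result")
  })
  names(res) <- studies
  structure(res, class = "lodo_results")
}

#' @export
print.lodo_result <- function(x, ...) {
  cat(sprintf("lodo_result: held-out %s, %d samples, AUC %.3f\n",
              x$test_study, length(x$predictions), x$auc))
  invisible(x)
}

#' @export
print.lodo_results <- function(x, ...) {
  cat("Leave-one-dataset-out results\n")
  for (r in x)
    cat(sprintf("  %-20s AUC %.3f  (%d samples, %d taxa retained)\n",
                r$test_study, r$auc, length(r$predictions),
                length(r$retained_taxa)))
  cat(sprintf("  macro-mean AUC over held-out studies: %.3f\n", mean_auc(x)))
  invisible(x)
}

#' Macro-mean AUC of a LODO run
#'
#' The unweighted mean of the per-held-out-study AUCs.
#'
#' @param results A `lodo_results` object.
#' @return A number in \[0, 1\].
#' @export
mean_auc <- function(results) {
  mean(vapply(results, `[[`, numeric(1), "auc"))
}
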