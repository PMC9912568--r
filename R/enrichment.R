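#' Kruskal-Wallis H test across groups
#'
#' Tie-corrected H with a chi-square p-value on `length(groups) - 1` degrees
#' of freedom. When every pooled value is identical the test is degenerate
#' and (H = 0, p = 1) is returned rather than an error.
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return List with `statistic` (H) and `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) == 0))
    stop("every group must be non-empty")
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1)
    return(list(statistic = 0, p_value = 1))
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Mann-Whitney U test (two-sided)
#'
#' Normal approximation with tie and continuity correction. The reported U
#' counts x-over-y wins. Direction is `"enriched"` when `median(x) >
#' median(y)` and `"depleted"` when smaller; with tied medians (common for
#' sparse taxa, where both medians are zero) the call falls back to the
#' rank-mean comparison implied by the U statistic itself
#' (`U > n_x n_y / 2` means x tends larger). Fully tied data yield p = 1.
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `statistic` (U for x), `p_value` and `direction`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both inputs must be non-empty")
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  p <- wt$p.value
  if (is.na(p)) p <- 1  # fully tied data: zero-variance normal approximation
  u <- unname(wt$statistic)
  mx <- stats::median(x); my <- stats::median(y)
  direction <- if (mx > my) "enriched"
    else if (mx < my) "depleted"
    else if (u > length(x) * length(y) / 2) "enriched" else "depleted"
  list(statistic = u, p_value = p, direction = direction)
}

#' Per-cluster taxon enrichment
#'
#' For every taxon: a Kruskal-Wallis H test of its relative abundance across
#' the case clusters, and a Mann-Whitney U test of each cluster against the
#' healthy (control) samples. Tests run on relative abundances, not on SHAP
#' values. Significance is the raw p-value against `alpha`;
#' Benjamini-Hochberg q-values are reported alongside (computed within each
#' test family) but do not drive the `significant` flag.
#'
#' @param table [abundance_table()] of the clustered case samples.
#' @param clusters A `cluster_result` (or an integer vector of cluster
#'   labels) covering every sample of `table`, in row order.
#' @param healthy [abundance_table()] of control samples on the same taxa.
#' @param alpha Significance threshold on the raw p-value (default 0.05).
#' @return An `enrichment_table` data frame with columns `taxon`, `test`
#'   (`"KW"` or `"MWU"`), `cluster` (`"all"` for KW), `statistic`,
#'   `p_value`, `q_value`, `direction` (NA for KW) and `significant`.
#' @export
enrich_clusters <- function(table, clusters, healthy, alpha = 0.05) {
  labels <- if (inherits(clusters, "cluster_result")) clusters$labels
            else as.integer(clusters)
  if (length(labels) != nrow(table$values))
    stop("cluster labels must cover every sample of the case table")
  if (!identical(colnames(table$values), colnames(healthy$values)))
    stop("case and healthy tables must share the same taxa")
  ks <- sort(unique(labels))
  rows <- lapply(colnames(table$values), function(taxon) {
    v <- table$values[, taxon]
    h <- healthy$values[, taxon]
    kw <- kruskal_wallis(lapply(ks, function(c) v[labels == c]))
    out <- data.frame(taxon = taxon, test = "KW", cluster = "all",
                      statistic = kw$statistic, p_value = kw$p_value,
                      direction = NA_character_)
    for (c in ks) {
      mw <- mann_whitney(v[labels == c], h)
      out <- rbind(out, data.frame(
        taxon = taxon, test = "MWU", cluster = as.character(c),
        statistic = mw$statistic, p_value = mw$p_value,
        direction = mw$direction))
    }
    out
  })
  res <- do.call(rbind, rows)
  res$q_value <- NA_real_
  for (fam in unique(res$test)) {
    i <- res$test == fam
    res$q_value[i] <- stats::p.adjust(res$p_value[i], method = "BH")
  }
  res$significant <- res$p_value < alpha
  res <- res[, c("taxon", "test", "cluster", "statistic", "p_value",
                 "q_value", "direction", "significant")]
  class(res) <- c("enrichment_table", "data.frame")
  res
}

#' Write an enrichment table to TSV
#'
#' @param enrichment An `enrichment_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment <- function(enrichment, path) {
  utils::write.table(enrichment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
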