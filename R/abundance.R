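#' Construct an abundance table
#'
#' Bundles a samples x taxa matrix of relative abundances (fractions in
#' \[0, 1\]) with per-sample phenotype labels and study membership. This is
#' the container every other function in the package consumes.
#'
#' @param values Numeric matrix, samples in rows, taxa in columns. Row names
#'   are sample identifiers, column names are taxon identifiers; both must be
#'   unique and non-missing.
#' @param labels Character or factor of length `nrow(values)` with values
#'   `"control"` or `"case"`.
#' @param study Character of length `nrow(values)` naming the study/dataset
#'   each sample comes from.
#'
#' @return An object of class `abundance_table`: a list with elements
#'   `values`, `labels` (factor with levels control, case) and `study`.
#' @export
abundance_table <- function(values, labels, study) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x taxa)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry sample ids as rownames and taxon ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate taxon ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values)) stop("`values` contains missing entries")
  if (any(values < 0)) stop("relative abundances must be non-negative")
  if (ncol(values) > 0 && any(rowSums(values) > 1 + 1e-6))
    stop("row sums exceed 1 + 1e-6; values must be relative abundances")
  labels <- as.character(labels)
  if (length(labels) != nrow(values))
    stop("`labels` must have one entry per sample")
  bad <- setdiff(unique(labels), c("control", "case"))
  if (length(bad))
    stop("labels must be 'control' or 'case'; found: ", paste(bad, collapse = ", "))
  study <- as.character(study)
  if (length(study) != nrow(values))
    stop("`study` must have one entry per sample")
  structure(
    list(values = values,
         labels = factor(labels, levels = c("control", "case")),
         study = study),
    class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa\n", nrow(x$values), ncol(x$values)))
  cat(sprintf("  labels: %d control, %d case\n",
              sum(x$labels == "control"), sum(x$labels == "case")))
  cat("  studies:", paste(unique(x$study), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Number of samples / taxa in an abundance table
#' @param table An `abundance_table`.
#' @return Integer count.
#' @export
n_samples <- function(table) nrow(table$values)

#' @rdname n_samples
#' @export
n_taxa <- function(table) ncol(table$values)

#' Subset an abundance table by sample
#'
#' @param table An `abundance_table`.
#' @param idx Logical, integer or character index over samples.
#' @return An `abundance_table` with the selected samples.
#' @export
subset_samples <- function(table, idx) {
  abundance_table(table$values[idx, , drop = FALSE],
                  as.character(table$labels)[if (is.character(idx)) match(idx, rownames(table$values)) else idx],
                  table$study[if (is.character(idx)) match(idx, rownames(table$values)) else idx])
}

delim_for <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an abundance table and its sample metadata
#'
#' The abundance file is a TSV/CSV with a header row of taxon names and the
#' first column holding sample ids. The metadata file has columns
#' `sample_id`, `label` and `study`. Every sample must appear in both files;
#' the returned table follows the abundance file's sample order.
#'
#' @param path Path to the abundance TSV/CSV.
#' @param metadata_path Path to the metadata TSV/CSV.
#' @param delim Field delimiter; by default inferred from the file extension
#'   (`.csv` -> comma, otherwise tab).
#' @param allow_extra_metadata If `TRUE`, metadata rows for samples absent
#'   from this abundance file are ignored instead of raising an error —
#'   needed when several per-study tables share one metadata file.
#' @return An [abundance_table()].
#' @export
read_abundance <- function(path, metadata_path, delim = NULL,
                           allow_extra_metadata = FALSE) {
  for (p in c(path, metadata_path))
    if (!file.exists(p)) stop("file not found: ", p)
  ab <- utils::read.table(path, sep = delim_for(path, delim), header = TRUE,
                          check.names = FALSE, row.names = NULL,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(ab) < 2) stop("abundance file must have a sample-id column and at least one taxon")
  ids <- as.character(ab[[1]])
  vals <- as.matrix(ab[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric abundance cell in ", path)
  rownames(vals) <- ids
  md <- utils::read.table(metadata_path, sep = delim_for(metadata_path, delim),
                          header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c("sample_id", "label", "study")
  if (!all(need %in% colnames(md)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  only_ab <- setdiff(ids, md$sample_id)
  only_md <- setdiff(md$sample_id, ids)
  if (length(only_ab))
    stop("samples missing from metadata: ", paste(only_ab, collapse = ", "))
  if (length(only_md) && !allow_extra_metadata)
    stop("samples missing from abundance table: ", paste(only_md, collapse = ", "))
  m <- match(ids, md$sample_id)
  abundance_table(vals, md$label[m], md$study[m])
}

#' Write an abundance table and its sample metadata
#'
#' Inverse of [read_abundance()]; emits the same dialect (delimiter inferred
#' from extension unless given).
#'
#' @inheritParams read_abundance
#' @param table An `abundance_table`.
#' @return Invisibly, `table`.
#' @export
write_abundance <- function(table, path, metadata_path, delim = NULL) {
  sep <- delim_for(path, delim)
  df <- data.frame(sample_id = rownames(table$values),
                   table$values, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  md <- data.frame(sample_id = rownames(table$values),
                   label = as.character(table$labels),
                   study = table$study)
  utils::write.table(md, metadata_path, sep = delim_for(metadata_path, delim),
                     quote = FALSE, row.names = FALSE)
  invisible(table)
}

#' Abundance filtering: zero out trace values
#'
#' Values strictly below `threshold` are set to zero. This is the first of
#' the two filtering stages; run it before [filter_prevalence()].
#'
#' @param table An `abundance_table`.
#' @param threshold Non-negative abundance threshold (default `1e-15`).
#' @return The table with sub-threshold values zeroed; shape unchanged.
#' @export
filter_abundance <- function(table, threshold = 1e-15) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0)
    stop("`threshold` must be a single non-negative number")
  v <- table$values
  v[v < threshold] <- 0
  table$values <- v
  table
}

#' Prevalence filtering: drop mostly-zero taxa
#'
#' A taxon is removed when its fraction of zero entries is strictly greater
#' than `threshold` (so with the default 0.9, a taxon zero in exactly 90% of
#' samples is retained). Apply [filter_abundance()] first so trace values
#' count as zeros.
#'
#' @param table An `abundance_table`.
#' @param threshold Zero-fraction threshold in \[0, 1\] (default 0.9).
#' @return The table restricted to retained taxa; the removed taxon ids are
#'   attached as attribute `"dropped_taxa"`. Sample rows are never touched.
#' @export
filter_prevalence <- function(table, threshold = 0.9) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 1)
    stop("`threshold` must be a single number in [0, 1]")
  zero_frac <- colMeans(table$values == 0)
  drop <- zero_frac > threshold
  dropped <- colnames(table$values)[drop]
  table$values <- table$values[, !drop, drop = FALSE]
  attr(table, "dropped_taxa") <- dropped
  table
}

#' Align a table to a fixed taxon set
#'
#' Restricts and reorders the columns of `table` to `taxon_ids`; taxa absent
#' from the table are added as all-zero columns. Used to project a held-out
#' study onto the feature space derived from training data.
#'
#' @param table An `abundance_table`.
#' @param taxon_ids Character vector of taxon names defining the target space.
#' @return An `abundance_table` whose columns are exactly `taxon_ids`.
#' @export
align_taxa <- function(table, taxon_ids) {
  v <- matrix(0, nrow(table$values), length(taxon_ids),
              dimnames = list(rownames(table$values), taxon_ids))
  common <- intersect(taxon_ids, colnames(table$values))
  v[, common] <- table$values[, common]
  table$values <- v
  table
}

#' Concatenate abundance tables by row
#'
#' Samples are stacked on the union of the tables' taxon sets; taxa missing
#' from a table contribute zeros.
#'
#' @param tables List of `abundance_table`s with disjoint sample ids.
#' @return A single `abundance_table`.
#' @export
bind_tables <- function(tables) {
  stopifnot(length(tables) >= 1)
  all_taxa <- Reduce(union, lapply(tables, function(t) colnames(t$values)))
  aligned <- lapply(tables, align_taxa, taxon_ids = all_taxa)
  abundance_table(do.call(rbind, lapply(aligned, `[[`, "values")),
                  unlist(lapply(aligned, function(t) as.character(t$labels))),
                  unlist(lapply(aligned, `[[`, "study")))
}
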