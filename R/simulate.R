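#' Specification of a synthetic multi-study cohort
#'
#' Describes a case-control relative-abundance cohort: several studies with
#' a shared taxon space, log-normal latent abundances, per-study batch
#' shifts, multiplicative case effects on chosen signal taxa, optional case
#' subtypes driven by their own taxon sets, and a target zero fraction
#' (sparsity) induced before closure.
#'
#' @param n_studies Number of studies (default 5).
#' @param n_control,n_case Samples per class per study (default 40 + 40).
#' @param n_taxa Number of taxa (default 60).
#' @param signal_taxa Data frame with columns `taxon` (index), `direction`
#'   (`"enriched"`/`"depleted"`) and `log2_effect`; applied to every case
#'   sample. Default: taxa 1-5 enriched and taxon 6 depleted, all at log2
#'   effect 2 (a 4-fold change). `NULL` for a null cohort.
#' @param subtypes Optional list of case subtypes, each a list with `taxa`
#'   (indices) and `log2_effect`; case samples are partitioned evenly across
#'   subtypes within each study and each subtype's taxa are enriched only in
#'   its members. Subtype taxon sets must be disjoint.
#' @param batch_sd SD of the per-study, per-taxon log-scale shift
#'   (default 0.25).
#' @param noise_sd Within-sample log-scale noise SD (default 0.7).
#' @param sparsity Target zero fraction in \[0, 1) (default 0.6).
#' @param seed Integer seed; generation is deterministic given it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_studies = 5, n_control = 40, n_case = 40,
                        n_taxa = 60, signal_taxa = default_signal_taxa(),
                        subtypes = NULL, batch_sd = 0.25, noise_sd = 0.7,
                        sparsity = 0.6, seed = 1) {
  stopifnot(n_studies >= 1, n_control >= 1, n_case >= 1, n_taxa >= 1,
            batch_sd >= 0, noise_sd >= 0)
  if (sparsity < 0 || sparsity >= 1)
    stop("`sparsity` must lie in [0, 1)")
  if (!is.null(signal_taxa)) {
    stopifnot(is.data.frame(signal_taxa),
              all(c("taxon", "direction", "log2_effect") %in%
                    colnames(signal_taxa)))
    if (any(signal_taxa$taxon < 1 | signal_taxa$taxon > n_taxa))
      stop("signal taxon index outside 1..n_taxa")
    if (!all(signal_taxa$direction %in% c("enriched", "depleted")))
      stop("signal direction must be 'enriched' or 'depleted'")
  }
  if (!is.null(subtypes)) {
    all_sub <- unlist(lapply(subtypes, `[[`, "taxa"))
    if (any(all_sub < 1 | all_sub > n_taxa))
      stop("subtype taxon index outside 1..n_taxa")
    if (anyDuplicated(all_sub))
      stop("subtype taxon sets must be disjoint")
    if (length(subtypes) > n_case)
      stop("more subtypes than case samples per study")
  }
  structure(list(n_studies = n_studies, n_control = n_control,
                 n_case = n_case, n_taxa = n_taxa,
                 signal_taxa = signal_taxa, subtypes = subtypes,
                 batch_sd = batch_sd, noise_sd = noise_sd,
                 sparsity = sparsity, seed = seed),
            class = "cohort_spec")
}

#' Default planted signal: five enriched taxa and one depleted, log2 effect 2
#' @return A data frame usable as `signal_taxa` in [cohort_spec()].
#' @export
default_signal_taxa <- function() {
  data.frame(taxon = 1:6,
             direction = c(rep("enriched", 5), "depleted"),
             log2_effect = 2)
}

#' Default planted case subtypes: two disjoint five-taxon signatures
#'
#' Two subtypes driven by taxa 1-5 and 6-10 respectively, each at log2
#' effect 3 (8-fold) — the regime of hallmark disease taxa that are
#' near-absent in the other group. Use with `signal_taxa = NULL` so the
#' subtype signatures are the only case signal.
#'
#' @return A list usable as `subtypes` in [cohort_spec()].
#' @export
default_subtypes <- function() {
  list(list(taxa = 1:5, log2_effect = 3),
       list(taxa = 6:10, log2_effect = 3))
}

#' Generate a synthetic multi-study cohort
#'
#' Per sample, latent log abundances are drawn as taxon base level + study
#' batch shift + class/subtype effect + noise; effects act multiplicatively
#' before closure, so the compositional artifacts of real relative-abundance
#' data (a planted enrichment depresses every other taxon's fraction) are
#' present. Values below the study-wide sparsity quantile are zeroed, then
#' rows are renormalized to sum to one.
#'
#' @param spec A [cohort_spec()].
#' @return A list of [abundance_table()]s, one per study, with attributes
#'   `"spec"`, `"signal_taxa"`, and `"subtype_labels"` (named integer vector
#'   over case sample ids; NULL when the spec has no subtypes).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_taxa
  taxa <- sprintf("taxon_%03d", seq_len(n))
  mu <- stats::rnorm(n, 0, 2)           # taxon base levels (log scale)
  # planted biomarkers must be detectable: give signal/subtype taxa base
  # levels from the upper half of the taxon distribution so the sparsity
  # cutoff does not erase them (reported signature taxa are prevalent)
  planted <- unique(c(spec$signal_taxa$taxon,
                      unlist(lapply(spec$subtypes, `[[`, "taxa"))))
  if (length(planted)) mu[planted] <- abs(mu[planted])
  class_eff <- numeric(n)
  if (!is.null(spec$signal_taxa)) {
    sgn <- ifelse(spec$signal_taxa$direction == "enriched", 1, -1)
    class_eff[spec$signal_taxa$taxon] <- sgn * log(2) * spec$signal_taxa$log2_effect
  }
  subtype_labels <- integer(0)
  tables <- vector("list", spec$n_studies)
  for (s in seq_len(spec$n_studies)) {
    study <- sprintf("study%d", s)
    m <- spec$n_control + spec$n_case
    labels <- c(rep("control", spec$n_control), rep("case", spec$n_case))
    ids <- sprintf("%s_s%03d", study, seq_len(m))
    batch <- stats::rnorm(n, 0, spec$batch_sd)
    eff <- matrix(0, m, n)
    is_case <- labels == "case"
    eff[is_case, ] <- matrix(class_eff, sum(is_case), n, byrow = TRUE)
    if (!is.null(spec$subtypes)) {
      assign <- sort(rep_len(seq_along(spec$subtypes), spec$n_case))
      for (g in seq_along(spec$subtypes)) {
        rows <- which(is_case)[assign == g]
        sub <- spec$subtypes[[g]]
        eff[rows, sub$taxa] <- eff[rows, sub$taxa] + log(2) * sub$log2_effect
      }
      st <- stats::setNames(assign, ids[is_case])
      subtype_labels <- c(subtype_labels, st)
    }
    latent <- matrix(mu, m, n, byrow = TRUE) +
      matrix(batch, m, n, byrow = TRUE) + eff +
      matrix(stats::rnorm(m * n, 0, spec$noise_sd), m, n)
    A <- exp(latent)
    if (spec$sparsity > 0) {
      cut <- stats::quantile(A, spec$sparsity, names = FALSE)
      zero <- A < cut
      # never empty a whole sample: keep each row's largest value
      keep <- cbind(seq_len(m), max.col(A))
      zero[keep] <- FALSE
      A[zero] <- 0
    }
    A <- A / rowSums(A)
    dimnames(A) <- list(ids, taxa)
    tables[[s]] <- abundance_table(A, labels, rep(study, m))
  }
  attr(tables, "spec") <- spec
  attr(tables, "signal_taxa") <- spec$signal_taxa
  attr(tables, "subtype_labels") <-
    if (is.null(spec$subtypes)) NULL else subtype_labels
  tables
}

#' Write a generated cohort to disk
#'
#' One abundance TSV per study, a combined metadata TSV, and a ground-truth
#' JSON (signal taxa, subtype labels) for test harnesses.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  md <- list()
  for (t in cohort) {
    study <- t$study[1]
    df <- data.frame(sample_id = rownames(t$values), t$values,
                     check.names = FALSE)
    utils::write.table(df, file.path(dir, paste0(study, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    md[[study]] <- data.frame(sample_id = rownames(t$values),
                              label = as.character(t$labels),
                              study = t$study)
  }
  utils::write.table(do.call(rbind, md), file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(signal_taxa = attr(cohort, "signal_taxa"),
                subtype_labels = as.list(attr(cohort, "subtype_labels")))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
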