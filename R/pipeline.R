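stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else if (is.list(config)) config
  else stop("config must be a YAML path or a list")
}

config_default <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else cfg[[key]]
}

#' Run the full analysis pipeline from a config
#'
#' Executes filtering, leave-one-dataset-out classification and explanation,
#' PCA embedding of the SHAP matrices, K-means subtyping of the correctly
#' predicted cases, and per-cluster enrichment; writes all tables plus a
#' provenance manifest to the output directory. The run is deterministic
#' for a fixed config: re-running produces byte-identical numeric outputs.
#'
#' Config fields (YAML or list): `out_dir` (required); either `simulate`
#' (arguments for [cohort_spec()]) or `tables` (vector of abundance TSV
#' paths) + `metadata`; and optional `seed`, `n_trees`, `max_depth`,
#' `abundance_threshold`, `prevalence_threshold`, `background_size`,
#' `k` (fixed cluster count; by default chosen per study by the elbow
#' method), `k_max`, `max_display`, `alpha`.
#'
#' Per held-out study the directory receives `shap_<study>.tsv(.json)`,
#' `embedding_<study>.tsv` (sample, PC1, PC2, probability, label, cluster),
#' `loadings_<study>.tsv`, `inertia_<study>.tsv`, `enrichment_<study>.tsv`,
#' `summary_features_<study>.tsv` and `waterfall_<study>.tsv`, plus the
#' shared `auc.tsv`, `config.yaml` echo, `manifest.json` and `run.log`.
#'
#' @param config Path to a YAML config or an equivalent named list.
#' @return Invisibly, a list with the `lodo_results` and per-study
#'   embedding/cluster/enrichment objects.
#' @export
run_all <- function(config) {
  cfg <- read_config(config)
  out_dir <- cfg$out_dir
  if (is.null(out_dir)) stop("config is missing required field: out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  log_msg <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  seed <- config_default(cfg, "seed", 42)

  tables <- stage("input", {
    if (!is.null(cfg$simulate)) {
      sim <- cfg$simulate
      sim$seed <- config_default(sim, "seed", seed)
      spec <- do.call(cohort_spec, sim)
      log_msg("simulating cohort: %d studies, %d+%d samples, %d taxa (seed %d)",
              spec$n_studies, spec$n_control, spec$n_case, spec$n_taxa,
              spec$seed)
      generate_cohort(spec)
    } else {
      if (is.null(cfg$tables)) stop("config is missing required field: tables (or simulate)")
      if (is.null(cfg$metadata)) stop("config is missing required field: metadata")
      lapply(cfg$tables, read_abundance, metadata_path = cfg$metadata,
             allow_extra_metadata = TRUE)
    }
  })

  lodo <- stage("lodo", run_lodo(
    tables,
    n_trees = config_default(cfg, "n_trees", 500),
    max_depth = config_default(cfg, "max_depth", 0),
    seed = seed,
    abundance_threshold = config_default(cfg, "abundance_threshold", 1e-15),
    prevalence_threshold = config_default(cfg, "prevalence_threshold", 0.9),
    background_size = cfg$background_size,
    explain = TRUE))

  auc_df <- data.frame(
    study = vapply(lodo, `[[`, character(1), "test_study"),
    n_samples = vapply(lodo, function(r) length(r$predictions), integer(1)),
    n_taxa = vapply(lodo, function(r) length(r$retained_taxa), integer(1)),
    auc = vapply(lodo, `[[`, numeric(1), "auc"))
  utils::write.table(auc_df, file.path(out_dir, "auc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_msg("LODO done: macro-mean AUC %.3f", mean_auc(lodo))

  max_display <- config_default(cfg, "max_display", 10)
  alpha <- config_default(cfg, "alpha", 0.05)
  per_study <- lapply(lodo, function(r) {
    s <- r$test_study
    write_shap_matrix(r$shap, file.path(out_dir, sprintf("shap_%s.tsv", s)))

    emb <- stage("embed", pca_embed(r$shap, labels = r$labels))
    cases <- stage("select", select_correct_cases(r$shap, r$labels))
    case_scores <- emb$scores[match(cases$sample_ids, emb$sample_ids), ,
                              drop = FALSE]

    clusters <- NULL
    if (nrow(case_scores) >= 2) {
      k <- cfg$k
      if (is.null(k)) {
        k_max <- min(config_default(cfg, "k_max", 10), nrow(case_scores))
        k <- stage("cluster", choose_k_elbow(case_scores, k_max = k_max,
                                             seed = seed))
        inertia <- attr(k, "inertia_curve")
        utils::write.table(
          data.frame(k = seq_along(inertia), inertia = inertia),
          file.path(out_dir, sprintf("inertia_%s.tsv", s)),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
      clusters <- stage("cluster", kmeans_cluster(
        case_scores, as.integer(k), seed = seed,
        probabilities = cases$predictions))
      log_msg("%s: k = %d clusters over %d correctly predicted cases",
              s, clusters$k, nrow(case_scores))
    } else {
      log_msg("%s: too few correctly predicted cases to cluster", s)
    }

    cl_col <- rep(NA_integer_, length(emb$sample_ids))
    if (!is.null(clusters))
      cl_col[match(cases$sample_ids, emb$sample_ids)] <- clusters$labels
    utils::write.table(
      data.frame(sample = emb$sample_ids,
                 PC1 = emb$scores[, 1], PC2 = emb$scores[, 2],
                 probability = unname(r$predictions),
                 label = as.character(r$labels), cluster = cl_col),
      file.path(out_dir, sprintf("embedding_%s.tsv", s)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(taxon = rownames(emb$loadings), emb$loadings),
      file.path(out_dir, sprintf("loadings_%s.tsv", s)),
      sep = "\t", quote = FALSE, row.names = FALSE)

    enrichment <- NULL
    if (!is.null(clusters)) {
      case_table <- subset_samples(r$test, cases$sample_ids)
      healthy <- subset_samples(r$test, as.character(r$labels) == "control")
      enrichment <- stage("enrich",
        enrich_clusters(case_table, clusters, healthy, alpha = alpha))
      write_enrichment(enrichment,
                       file.path(out_dir, sprintf("enrichment_%s.tsv", s)))
    }

    sm <- stage("report", build_summary(r$shap, r$test,
                                        max_display = max_display))
    utils::write.table(sm$features,
                       file.path(out_dir, sprintf("summary_features_%s.tsv", s)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(cases$sample_ids)) {
      top <- cases$sample_ids[which.max(cases$predictions)]
      wf <- stage("report", build_waterfall(
        explanation_for(r$shap, top,
                        r$test$values[top, ]), max_display = max_display))
      utils::write.table(wf$rows,
                         file.path(out_dir, sprintf("waterfall_%s.tsv", s)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(embedding = emb, clusters = clusters, enrichment = enrichment)
  })

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  manifest <- list(
    package = "microshap",
    version = as.character(utils::packageVersion("microshap")),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    studies = names(lodo),
    macro_mean_auc = mean_auc(lodo))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, log_path)
  invisible(list(lodo = lodo, per_study = per_study))
}
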