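#' Waterfall data for one local explanation
#'
#' Orders taxa by decreasing |SHAP| (ties broken by taxon name), keeps the
#' top `max_display` taxa with non-zero attribution, collapses the rest into
#' a remainder row, and accumulates the running total from the base value so
#' the final cumulative value is the prediction.
#'
#' @param expl A `shap_explanation`.
#' @param max_display Maximum number of individually displayed taxa
#'   (default 10).
#' @return A `waterfall_data` list: `rows` (data frame with `taxon`, `phi`,
#'   `cumulative`), `remainder` (summed phi of collapsed taxa),
#'   `base_value`, `prediction`, `displayed_count`.
#' @export
build_waterfall <- function(expl, max_display = 10) {
  stopifnot(inherits(expl, "shap_explanation"), max_display >= 1)
  ord <- order(-abs(expl$phi), expl$feature_names)
  nz <- ord[abs(expl$phi[ord]) > 0]
  shown <- nz[seq_len(min(max_display, length(nz)))]
  remainder <- sum(expl$phi) - sum(expl$phi[shown])
  cum <- expl$base_value + cumsum(expl$phi[shown])
  rows <- data.frame(taxon = expl$feature_names[shown],
                     phi = unname(expl$phi[shown]),
                     cumulative = unname(cum))
  rows <- rbind(rows, data.frame(taxon = "(remaining taxa)", phi = remainder,
                                 cumulative = expl$base_value +
                                   sum(expl$phi[shown]) + remainder))
  structure(list(rows = rows, remainder = remainder,
                 base_value = expl$base_value, prediction = expl$prediction,
                 displayed_count = length(shown)),
            class = "waterfall_data")
}

#' @export
print.waterfall_data <- function(x, ...) {
  cat(sprintf("waterfall: base %.4f -> prediction %.4f (%d taxa shown)\n",
              x$base_value, x$prediction, x$displayed_count))
  print(x$rows, row.names = FALSE)
  invisible(x)
}

#' Summary (beeswarm) data for a SHAP matrix
#'
#' Features are ordered by global importance (mean |SHAP|); the top
#' `max_display` features contribute one dot per sample carrying the SHAP
#' value (x-position) and the raw relative abundance (color scale). Features
#' outside the display that still reach, for at least one sample, an
#' absolute SHAP value above the smallest displayed feature's mean |SHAP|
#' are flagged as locally influential: globally minor taxa that matter a lot
#' to individual subjects.
#'
#' @param shap A `shap_matrix`.
#' @param table The [abundance_table()] it explains (same samples and taxa).
#' @param max_display Number of features displayed (default 10).
#' @return A `summary_data` list: `features` (data frame with `feature`,
#'   `mean_abs_shap`, `displayed`, `locally_influential`) ordered by
#'   importance, and `dots` (data frame with `feature`, `sample`, `phi`,
#'   `abundance`) for the displayed features.
#' @export
build_summary <- function(shap, table, max_display = 10) {
  X <- as_value_matrix(table)
  if (!identical(rownames(X), shap$sample_ids) ||
      !identical(colnames(X), shap$feature_names))
    stop("SHAP matrix and abundance table are misaligned")
  imp <- global_importance(shap)
  shown <- names(imp)[seq_len(min(max_display, length(imp)))]
  floor_imp <- min(imp[shown])
  max_abs <- apply(abs(shap$values), 2, max)
  features <- data.frame(
    feature = names(imp),
    mean_abs_shap = unname(imp),
    displayed = names(imp) %in% shown,
    locally_influential = !(names(imp) %in% shown) &
      max_abs[names(imp)] > floor_imp)
  dots <- do.call(rbind, lapply(shown, function(f)
    data.frame(feature = f, sample = shap$sample_ids,
               phi = shap$values[, f], abundance = X[, f])))
  rownames(dots) <- NULL
  structure(list(features = features, dots = dots,
                 max_display = max_display),
            class = "summary_data")
}

#' @export
print.summary_data <- function(x, ...) {
  cat(sprintf("summary_data: %d features (%d displayed, %d locally influential)\n",
              nrow(x$features), sum(x$features$displayed),
              sum(x$features$locally_influential)))
  print(utils::head(x$features, x$max_display), row.names = FALSE)
  invisible(x)
}

#' Plot a waterfall explanation
#'
#' Thin ggplot2 rendering of [build_waterfall()]; all numbers come from the
#' data structure.
#'
#' @param wf A `waterfall_data`.
#' @return A ggplot object.
#' @export
plot_waterfall <- function(wf) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  rows <- wf$rows
  rows$taxon <- factor(rows$taxon, levels = rev(rows$taxon))
  rows$start <- rows$cumulative - rows$phi
  ggplot2::ggplot(rows) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$start, xend = .data$cumulative,
      y = .data$taxon, yend = .data$taxon,
      color = .data$phi > 0), linewidth = 4) +
    ggplot2::geom_vline(xintercept = wf$base_value, linetype = 2) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#d62728",
                                           `FALSE` = "#1f77b4"),
                                guide = "none") +
    ggplot2::labs(x = "model output (case probability)", y = NULL,
                  title = sprintf("base %.3f to prediction %.3f",
                                  wf$base_value, wf$prediction))
}

#' Plot a SHAP summary beeswarm
#'
#' @param sm A `summary_data`.
#' @return A ggplot object.
#' @export
plot_summary <- function(sm) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  d <- sm$dots
  d$feature <- factor(d$feature,
                      levels = rev(sm$features$feature[sm$features$displayed]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$phi, y = .data$feature,
                                  color = .data$abundance)) +
    ggplot2::geom_jitter(height = 0.2, width = 0, size = 0.8) +
    ggplot2::scale_color_gradient(low = "#1f77b4", high = "#d62728",
                                  name = "relative\nabundance") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "SHAP value (impact on case probability)", y = NULL)
}
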