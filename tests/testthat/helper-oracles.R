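# Shared fixtures and independent oracles for the Shapley engine tests.

# random binary tree over n features with leaf probabilities in [0, 1]
rand_tree <- function(n, depth, p_leaf = 0.3) {
  build <- function(d) {
    if (d == 0 || stats::runif(1) < p_leaf) tree_leaf(stats::runif(1))
    else tree_split(sample.int(n, 1), stats::runif(1),
                    build(d - 1), build(d - 1))
  }
  build(depth)
}

rand_ensemble <- function(n, n_trees, depth) {
  tree_ensemble(lapply(seq_len(n_trees), function(i) rand_tree(n, depth)),
                paste0("taxon_", seq_len(n)))
}

# interventional value function v(S, x): mean prediction over background
# rows with the coordinates in S taken from x
coalition_value <- function(ens, x, bg, S) {
  H <- bg
  if (length(S)) H[, S] <- matrix(x[S], nrow(bg), length(S), byrow = TRUE)
  mean(predict_proba(ens, H))
}

# Shapley values as the average over all n! feature orderings of marginal
# contributions -- an oracle wholly independent of the subset-weight formula
perm_shap_oracle <- function(ens, x, bg) {
  n <- length(x)
  permn <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in permn(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  phi <- numeric(n)
  perms <- permn(seq_len(n))
  for (p in perms) {
    prev <- integer(0)
    vprev <- coalition_value(ens, x, bg, prev)
    for (f in p) {
      cur <- c(prev, f)
      vcur <- coalition_value(ens, x, bg, cur)
      phi[f] <- phi[f] + vcur - vprev
      prev <- cur; vprev <- vcur
    }
  }
  phi / length(perms)
}

# small hand-made abundance table
toy_table <- function(values, labels = NULL, study = NULL) {
  m <- nrow(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("s%02d", seq_len(m))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("taxon_%02d", seq_len(ncol(values)))
  abundance_table(values,
                  labels %||% rep(c("control", "case"), length.out = m),
                  study %||% rep("study1", m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
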