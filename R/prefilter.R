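#' Per-gene variances
#'
#' @param ds An [expression_dataset] with no absent entries.
#' @param kind `"population"` (divide by n, the filtering convention,
#'   default) or `"sample"` (divide by n - 1).
#' @return Numeric vector of per-gene variances, length = gene count.
#' @export
gene_variances <- function(ds, kind = c("population", "sample")) {
  stopifnot(inherits(ds, "expression_dataset"))
  kind <- match.arg(kind)
  if (any(ds$missing_mask)) stop("dataset has absent entries; impute first")
  n <- nrow(ds$values)
  if (kind == "sample" && n < 2) {
    stop("sample variance requires at least 2 samples")
  }
  mu <- colMeans(ds$values)
  ss <- colSums(ds$values^2) - n * mu^2
  ss <- pmax(ss, 0)  # guard tiny negative rounding on constant genes
  v <- if (kind == "population") ss / n else ss / (n - 1)
  names(v) <- ds$feature_ids
  v
}

#' Stage 1: variance threshold filter
#'
#' Removes every gene whose variance is strictly below the threshold
#' (a gene with variance exactly equal to the threshold is kept).
#'
#' @param ds An [expression_dataset] with no absent entries.
#' @param threshold Nonnegative variance threshold; default 0.05.
#' @param kind Variance kind, see [gene_variances()].
#' @return A stage result: list with `kept_indices` (strictly increasing
#'   indices into the input genes), `scores` (all per-gene variances) and
#'   `dataset` (the reduced [expression_dataset]).
#' @export
variance_filter <- function(ds, threshold = 0.05,
                            kind = c("population", "sample")) {
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            is.finite(threshold), threshold >= 0)
  v <- gene_variances(ds, kind)
  kept <- which(v >= threshold)
  if (length(kept) == 0) {
    stop("variance filter removed every gene (threshold = ", threshold,
         "); empty stage")
  }
  list(kept_indices = kept, scores = v,
       dataset = subset_genes(ds, kept))
}

#' Stage 2: extremely-randomized-tree gene importances
#'
#' Fits an ensemble of extremely randomized classification trees (each tree
#' on the full sample; at every node, `sqrt(p)` candidate genes are drawn and
#' one uniform random cut point per candidate is scored by Gini decrease) and
#' returns the normalized mean-impurity-decrease importance of every gene.
#' The tree-shape constraints are enforced exactly: `n_estimators` trees,
#' best-first growth to at most `max_leaf_nodes` leaves, and at least
#' `min_samples_leaf` samples in every leaf.
#'
#' @param ds A preprocessed [expression_dataset] with at least 2 classes.
#' @param n_estimators Number of trees; default 100.
#' @param min_samples_leaf Minimum samples per leaf; default 20.
#' @param max_leaf_nodes Maximum leaves per tree; default 10.
#' @param seed Integer seed; importances are deterministic given it.
#' @return Nonnegative numeric vector summing to 1 (named by feature ID).
#' @export
ert_importances <- function(ds, n_estimators = 100, min_samples_leaf = 20,
                            max_leaf_nodes = 10, seed = 1) {
  stopifnot(inherits(ds, "expression_dataset"),
            n_estimators >= 1, min_samples_leaf >= 1, max_leaf_nodes >= 2)
  if (nlevels(droplevels(ds$labels)) < 2) {
    stop("importance requires at least 2 classes present")
  }
  x <- ds$values
  y <- as.integer(droplevels(ds$labels))
  K <- max(y)
  mtry <- max(1L, floor(sqrt(ncol(x))))
  imp <- numeric(ncol(x))
  used <- 0L
  .with_seed(seed, {
    for (b in seq_len(n_estimators)) {
      tr <- grow_tree(x, y, K, splitter = "random", max_features = mtry,
                      min_samples_leaf = min_samples_leaf,
                      max_leaf_nodes = max_leaf_nodes)
      s <- sum(tr$importance)
      if (s > 0) {  # single-leaf trees carry no information
        imp <- imp + tr$importance / s
        used <- used + 1L
      }
    }
  })
  if (used == 0 || sum(imp) == 0) {
    imp[] <- 0
  } else {
    imp <- imp / sum(imp)
  }
  names(imp) <- ds$feature_ids
  imp
}

#' Stage 2 gate: keep genes with strictly positive importance
#'
#' @param scores Finite, nonnegative importance vector.
#' @return Ascending indices of entries strictly greater than zero
#'   (no epsilon).
#' @export
positive_importance_filter <- function(scores) {
  stopifnot(is.numeric(scores), all(is.finite(scores)), all(scores >= 0))
  kept <- which(scores > 0)
  if (length(kept) == 0) {
    stop("no gene has strictly positive importance; empty stage")
  }
  kept
}

#' Export per-gene stage diagnostics as CSV
#'
#' Writes one row per original gene with its variance, importance (NA for
#' genes the variance filter removed) and kept-flags per stage.
#'
#' @param fit A fitted `"veh"` object (see [veh()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stage_diagnostics <- function(fit, path) {
  stopifnot(inherits(fit, "veh"))
  p <- length(fit$feature_ids)
  imp <- rep(NA_real_, p)
  imp[fit$stages$variance$kept_indices] <- fit$stages$importance$scores
  kept_var <- seq_len(p) %in% fit$stages$variance$kept_indices
  kept_imp <- seq_len(p) %in% fit$stages$gate_indices
  utils::write.csv(
    data.frame(feature_id = fit$feature_ids,
               variance = fit$stages$variance$scores,
               importance = imp,
               kept_variance = kept_var,
               kept_importance = kept_imp,
               selected = fit$feature_ids %in% fit$selected$feature_ids),
    path, row.names = FALSE)
  invisible(path)
}

# Evaluate `expr` under a temporary RNG state seeded by `seed`, restoring
# the caller's stream afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}
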