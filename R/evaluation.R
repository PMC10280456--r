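#' Stratified k-fold assignment
#'
#' Partitions samples into `k` folds so that, within every class, fold
#' membership counts differ by at most one.
#'
#' @param labels Per-sample class labels.
#' @param k Number of folds (>= 2); every class must have at least `k`
#'   members.
#' @param seed Integer seed; the assignment is deterministic given it.
#' @return Integer vector of fold ids in `1:k`, one per sample.
#' @export
stratified_kfold_indices <- function(labels, k, seed = 1) {
  labels <- factor(labels)
  stopifnot(k >= 2)
  counts <- tabulate(labels, nlevels(labels))
  if (any(counts < k)) {
    small <- levels(labels)[which(counts < k)[1]]
    stop("class '", small, "' has fewer members (",
         min(counts), ") than folds (", k, ")")
  }
  folds <- integer(length(labels))
  .with_seed(seed, {
    for (cl in seq_len(nlevels(labels))) {
      idx <- which(as.integer(labels) == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Confusion matrix from true and predicted labels
#'
#' @param truth True class labels.
#' @param pred Predicted class labels.
#' @return A square contingency table, true classes in rows, predictions in
#'   columns, over the union of observed classes.
#' @export
confusion_counts <- function(truth, pred) {
  lv <- union(levels(factor(truth)), levels(factor(pred)))
  table(factor(truth, levels = lv), factor(pred, levels = lv),
        dnn = c("truth", "predicted"))
}

#' Accuracy and macro precision / recall / F1
#'
#' Accuracy is the fraction of correctly classified samples (for a binary
#' table, `(TP + TN) / (P + N)`). Precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and `F1 = 2*precision*recall/(precision+recall)` are computed
#' per class and averaged with equal class weights (macro averaging);
#' undefined 0/0 ratios count as 0.
#'
#' @param truth Either true labels (with `pred` supplied) or a square
#'   confusion matrix with true classes in rows.
#' @param pred Predicted labels, when `truth` is a label vector.
#' @return Named list `acc`, `precision`, `recall`, `f1`, each in `[0, 1]`.
#' @export
classification_metrics <- function(truth, pred = NULL) {
  cm <- if (is.null(pred)) as.matrix(truth) else {
    as.matrix(confusion_counts(truth, pred))
  }
  stopifnot(nrow(cm) == ncol(cm), sum(cm) > 0)
  K <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  prec <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * prec * rec, prec + rec)
  # classes absent from the data contribute nothing to the macro mean
  present <- rowSums(cm) > 0 | colSums(cm) > 0
  list(acc = sum(tp) / sum(cm),
       precision = mean(prec[present]),
       recall = mean(rec[present]),
       f1 = mean(f1[present]))
}

#' Repeated stratified k-fold cross-validation of a gene subset
#'
#' For each repeat a fresh stratified fold split is drawn (seed + repeat
#' index); the classifier is trained on the mask-restricted matrix of the
#' training folds and its predictions on the held-out folds are pooled over
#' the whole repeat before the metrics are computed. The report gives metric
#' means (as percentages) over repeats and the standard deviation of the
#' per-repeat accuracies.
#'
#' @param ds A preprocessed [expression_dataset].
#' @param feature_ids Feature IDs (or column indices) restricting the matrix;
#'   `NULL` uses all genes.
#' @param classifier `"dt"`, `"svm"` or `"lr"`.
#' @param repeats Number of independent CV repeats; default 10.
#' @param folds Folds per repeat; default 10.
#' @param seed Base seed; repeat r uses `seed + r - 1`.
#' @param classifier_config Optional overrides of [classifier_defaults()].
#' @param normalize_within_folds Leakage-safe mode: min-max parameters are
#'   estimated on each training fold only and applied to its test fold
#'   (default `FALSE`, i.e. the dataset is used as given).
#' @return An object of class `"cv_report"`: list with `classifier`, `acc`,
#'   `precision`, `recall`, `f1` (percent means over repeats), `sd`
#'   (standard deviation of per-repeat accuracy, percent), `sd_folds` (mean
#'   within-repeat per-fold accuracy SD, percent), `repeats`, `folds`,
#'   `n_features`, and the `per_repeat` data frame.
#' @export
repeated_cv_evaluate <- function(ds, feature_ids = NULL,
                                 classifier = c("svm", "dt", "lr"),
                                 repeats = 10, folds = 10, seed = 1,
                                 classifier_config = NULL,
                                 normalize_within_folds = FALSE) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(ds, "expression_dataset"), repeats >= 1, folds >= 2)
  if (!is.null(feature_ids)) ds <- subset_genes(ds, feature_ids)
  x <- ds$values
  y <- droplevels(ds$labels)
  per <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fid <- stratified_kfold_indices(y, folds, seed + r - 1)
    pred <- character(length(y))
    fold_acc <- numeric(folds)
    for (f in seq_len(folds)) {
      te <- which(fid == f)
      tr <- which(fid != f)
      xtr <- x[tr, , drop = FALSE]
      xte <- x[te, , drop = FALSE]
      if (normalize_within_folds) {
        mins <- apply(xtr, 2, min)
        rng <- apply(xtr, 2, max) - mins
        rng[rng == 0] <- 1
        xtr <- sweep(sweep(xtr, 2, mins, "-"), 2, rng, "/")
        xte <- sweep(sweep(xte, 2, mins, "-"), 2, rng, "/")
      }
      model <- fit_classifier(classifier, xtr, y[tr], classifier_config)
      pred[te] <- predict_classifier(model, xte)
      fold_acc[f] <- mean(pred[te] == as.character(y[te]))
    }
    m <- classification_metrics(as.character(y), pred)
    per[[r]] <- data.frame(repeat_id = r, acc = m$acc,
                           precision = m$precision, recall = m$recall,
                           f1 = m$f1, sd_folds = stats::sd(fold_acc))
  }
  per <- do.call(rbind, per)
  structure(list(
    classifier = classifier,
    acc = 100 * mean(per$acc),
    precision = 100 * mean(per$precision),
    recall = 100 * mean(per$recall),
    f1 = 100 * mean(per$f1),
    sd = if (repeats > 1) 100 * stats::sd(per$acc) else 0,
    sd_folds = 100 * mean(per$sd_folds),
    repeats = repeats, folds = folds,
    n_features = ncol(x),
    per_repeat = per), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "%s (%dx%d-fold CV, %d genes): Acc %.2f%% (SD %.2f), precision %.2f, recall %.2f, F1 %.2f\n",
    toupper(x$classifier), x$repeats, x$folds, x$n_features,
    x$acc, x$sd, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Pick the optimal subset among stochastic runs
#'
#' Orders candidate subsets by (1) highest accuracy, (2) smallest size,
#' (3) highest frequency of the identical gene set among the candidates,
#' and breaks residual ties by the earliest run index.
#'
#' @param candidates Nonempty list; each element needs `feature_ids`,
#'   `accuracy` and `source_run`.
#' @return The winning candidate, with the full ranking attached as
#'   attribute `"audit"` (a data frame listing every candidate's accuracy,
#'   size and frequency).
#' @export
select_optimal_subset <- function(candidates) {
  if (length(candidates) == 0) stop("empty candidate list")
  key <- vapply(candidates,
                function(s) paste(sort(s$feature_ids), collapse = "\r"),
                character(1))
  freq <- as.vector(table(key)[key])
  audit <- data.frame(
    source_run = vapply(candidates, function(s) as.integer(s$source_run),
                        integer(1)),
    accuracy = vapply(candidates, function(s) as.numeric(s$accuracy),
                      numeric(1)),
    size = vapply(candidates, function(s) length(s$feature_ids), integer(1)),
    frequency = freq)
  ord <- order(-audit$accuracy, audit$size, -audit$frequency,
               audit$source_run)
  winner <- candidates[[ord[1]]]
  attr(winner, "audit") <- audit[ord, ]
  winner
}

#' Write a metrics table as CSV
#'
#' One row per classifier: dataset, classifier, Acc, SD, precision, recall,
#' f1 and subset size.
#'
#' @param reports Named list of `cv_report` objects (names = classifier).
#' @param path Output CSV path.
#' @param dataset Dataset tag for the first column.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(reports, path, dataset = "dataset") {
  rows <- lapply(reports, function(r) {
    data.frame(dataset = dataset, classifier = r$classifier,
               n_features = r$n_features, acc = r$acc, sd = r$sd,
               precision = r$precision, recall = r$recall, f1 = r$f1)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
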