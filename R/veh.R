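#' Three-stage hybrid gene selection
#'
#' Fits the full selection pipeline on a labeled expression matrix:
#' mean imputation and per-gene min-max normalization, a variance threshold
#' filter, an extremely-randomized-tree positive-importance gate, and
#' `runs` independent Harris Hawks searches whose KNN-accuracy/size fitness
#' drives the final subset. Each run's subset is scored by repeated
#' stratified cross-validation with the selection classifier; the optimal
#' subset (highest accuracy, then smallest, then most frequent) is evaluated
#' with every configured classifier.
#'
#' @param x An [expression_dataset], or a numeric samples-by-genes matrix /
#'   data frame (then `labels` is required).
#' @param labels Per-sample class labels when `x` is a matrix.
#' @param variance_threshold Stage-1 variance cutoff; genes with variance
#'   strictly below it are removed. Default 0.05.
#' @param variance_scale `"raw"` (default) computes stage-1 variances on the
#'   imputed, unnormalized intensities; `"normalized"` computes them after
#'   min-max scaling (where the attainable maximum is 0.25).
#' @param variance_kind `"population"` or `"sample"` variance.
#' @param ert_trees,ert_min_leaf,ert_max_leaf_nodes Stage-2 ensemble
#'   constraints: number of trees (100), minimum samples per leaf (20) and
#'   maximum leaves per tree (10).
#' @param n_hawks,n_iter Optimizer population size (30) and iterations (100).
#' @param alpha Fitness trade-off between KNN error and subset size (0.99).
#' @param knn_k,eval_folds KNN fitness parameters (5 neighbours, 5 folds).
#' @param dive_variant Hard-dive formula variant, see [hho_select()].
#' @param runs Independent optimizer runs (10), each with its own child seed.
#' @param classifiers Classifiers for the final report, a subset of
#'   `c("dt", "svm", "lr")`.
#' @param selection_classifier Classifier whose CV accuracy ranks the per-run
#'   subsets; default `"svm"`.
#' @param repeats,cv_folds Evaluation protocol: repeats (10) of stratified
#'   `cv_folds`-fold (10) cross-validation.
#' @param leakage_safe_cv If `TRUE`, the final cross-validation re-estimates
#'   the min-max normalization inside every training fold instead of using
#'   the whole-dataset normalization (slower, leakage-free; default `FALSE`,
#'   which matches the conventional whole-dataset preprocessing).
#' @param seed Global seed; every stochastic component derives its stream
#'   from it.
#' @param verbose Print per-stage progress.
#'
#' @return An object of class `"veh"`; see Details. Key elements:
#'   `counts` (gene counts per stage), `stages` (variance scores and kept
#'   indices, importances, gate indices), `runs` (per-run subset, trace and
#'   CV accuracy), `selected` (the chosen subset with `feature_ids`,
#'   `fitness`, `accuracy`, `source_run`), `reports` (per-classifier
#'   [repeated_cv_evaluate()] reports for the selected subset), `config` and
#'   `seeds`.
#' @seealso [evaluate_subset()] to score a fixed gene list,
#'   [predict.veh()] to classify new samples with the selected genes.
#' @export
veh <- function(x, labels = NULL,
                variance_threshold = 0.05,
                variance_scale = c("raw", "normalized"),
                variance_kind = c("population", "sample"),
                ert_trees = 100, ert_min_leaf = 20, ert_max_leaf_nodes = 10,
                n_hawks = 30, n_iter = 100, alpha = 0.99,
                knn_k = 5, eval_folds = 5,
                dive_variant = c("original", "as_printed"),
                runs = 10,
                classifiers = c("dt", "svm", "lr"),
                selection_classifier = "svm",
                repeats = 10, cv_folds = 10,
                leakage_safe_cv = FALSE,
                seed = 1, verbose = FALSE) {
  variance_scale <- match.arg(variance_scale)
  variance_kind <- match.arg(variance_kind)
  dive_variant <- match.arg(dive_variant)
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  stopifnot(runs >= 1, selection_classifier %in% c("dt", "svm", "lr"))

  ds <- if (inherits(x, "expression_dataset")) x else {
    if (is.null(labels)) stop("'labels' is required when 'x' is a matrix")
    expression_dataset(as.matrix(x), labels)
  }
  say <- function(...) if (verbose) message(...)
  seeds <- .with_seed(seed,
                      list(ert = sample.int(.Machine$integer.max - 1, 1),
                           runs = sample.int(.Machine$integer.max - 1, runs),
                           cv = sample.int(.Machine$integer.max - 1, 1)))

  # preprocessing
  ds_imp <- impute_missing_mean(ds)
  say("preprocessing: ", ncol(ds_imp$values), " genes, ",
      nrow(ds_imp$values), " samples")

  # stage 1: variance filter (on raw or normalized scale)
  vf <- if (variance_scale == "raw") {
    variance_filter(ds_imp, variance_threshold, variance_kind)
  } else {
    variance_filter(minmax_normalize(ds_imp), variance_threshold,
                    variance_kind)
  }
  ds_vf <- if (variance_scale == "raw") {
    minmax_normalize(vf$dataset)
  } else {
    vf$dataset
  }
  say("variance filter: ", length(vf$kept_indices), " genes kept")

  # stage 2: extremely-randomized-tree positive-importance gate
  imp <- ert_importances(ds_vf, n_estimators = ert_trees,
                         min_samples_leaf = ert_min_leaf,
                         max_leaf_nodes = ert_max_leaf_nodes,
                         seed = seeds$ert)
  gate <- positive_importance_filter(imp)
  ds_gate <- subset_genes(ds_vf, gate)
  gate_orig <- vf$kept_indices[gate]
  say("importance gate: ", length(gate), " genes kept")

  # stage 3: independent Harris Hawks searches
  run_results <- vector("list", runs)
  for (r in seq_len(runs)) {
    hho <- hho_select(ds_gate, n_hawks = n_hawks, n_iter = n_iter,
                      alpha = alpha, knn_k = knn_k, eval_folds = eval_folds,
                      dive_variant = dive_variant, seed = seeds$runs[r])
    cv <- repeated_cv_evaluate(
      if (leakage_safe_cv) ds_imp else ds_gate,
      feature_ids = hho$subset$feature_ids,
      classifier = selection_classifier,
      repeats = repeats, folds = cv_folds, seed = seeds$cv,
      normalize_within_folds = leakage_safe_cv)
    run_results[[r]] <- list(
      subset = list(feature_ids = hho$subset$feature_ids,
                    fitness = hho$subset$fitness,
                    accuracy = cv$acc, source_run = r),
      trace = hho$trace, cv = cv)
    say("run ", r, ": ", length(hho$subset$feature_ids), " genes, fitness ",
        signif(hho$subset$fitness, 4), ", ", selection_classifier, " acc ",
        round(cv$acc, 2))
  }

  selected <- select_optimal_subset(lapply(run_results, `[[`, "subset"))
  eval_ds <- if (leakage_safe_cv) ds_imp else ds_gate
  reports <- lapply(stats::setNames(classifiers, classifiers), function(cl) {
    repeated_cv_evaluate(eval_ds, feature_ids = selected$feature_ids,
                         classifier = cl, repeats = repeats,
                         folds = cv_folds, seed = seeds$cv,
                         normalize_within_folds = leakage_safe_cv)
  })

  sel_cols <- match(selected$feature_ids, ds$feature_ids)
  raw_sel <- ds_imp$values[, sel_cols, drop = FALSE]
  mins <- apply(raw_sel, 2, min)
  rng <- apply(raw_sel, 2, max) - mins
  rng[rng == 0] <- 1

  structure(list(
    name = ds$name,
    feature_ids = ds$feature_ids,
    counts = c(raw = ncol(ds$values),
               after_variance = length(vf$kept_indices),
               after_importance = length(gate),
               selected = length(selected$feature_ids)),
    stages = list(
      variance = list(kept_indices = vf$kept_indices, scores = vf$scores,
                      threshold = variance_threshold,
                      scale = variance_scale),
      importance = list(scores = imp),
      gate_indices = gate_orig),
    runs = run_results,
    selected = selected,
    selection_audit = attr(selected, "audit"),
    reports = reports,
    config = list(variance_threshold = variance_threshold,
                  variance_scale = variance_scale,
                  variance_kind = variance_kind,
                  ert = list(n_estimators = ert_trees,
                             min_samples_leaf = ert_min_leaf,
                             max_leaf_nodes = ert_max_leaf_nodes),
                  hho = list(n_hawks = n_hawks, n_iter = n_iter,
                             alpha = alpha, knn_k = knn_k,
                             eval_folds = eval_folds,
                             dive_variant = dive_variant),
                  runs = runs, classifiers = classifiers,
                  selection_classifier = selection_classifier,
                  repeats = repeats, cv_folds = cv_folds,
                  leakage_safe_cv = leakage_safe_cv),
    seeds = c(list(global = seed), seeds),
    train = list(values = sweep(sweep(raw_sel, 2, mins, "-"), 2, rng, "/"),
                 labels = ds$labels, mins = mins, range = rng)),
    class = "veh")
}

#' @export
print.veh <- function(x, ...) {
  cat("Hybrid gene selection on '", x$name, "'\n", sep = "")
  cat(sprintf("  genes: %d raw -> %d after variance filter -> %d after importance gate -> %d selected\n",
              x$counts["raw"], x$counts["after_variance"],
              x$counts["after_importance"], x$counts["selected"]))
  cat(sprintf("  selected subset (run %d, fitness %.4g): %s\n",
              x$selected$source_run, x$selected$fitness,
              paste(x$selected$feature_ids, collapse = ", ")))
  for (r in x$reports) {
    cat("  ")
    print(r)
  }
  invisible(x)
}

#' @export
summary.veh <- function(object, ...) {
  runs <- data.frame(
    run = vapply(object$runs, function(r) r$subset$source_run, integer(1)),
    size = vapply(object$runs, function(r) length(r$subset$feature_ids),
                  integer(1)),
    fitness = vapply(object$runs, function(r) r$subset$fitness, numeric(1)),
    accuracy = vapply(object$runs, function(r) r$subset$accuracy, numeric(1)))
  metrics <- do.call(rbind, lapply(object$reports, function(r) {
    data.frame(classifier = r$classifier, acc = r$acc, sd = r$sd,
               precision = r$precision, recall = r$recall, f1 = r$f1)
  }))
  rownames(metrics) <- NULL
  structure(list(name = object$name, counts = object$counts,
                 runs = runs, metrics = metrics,
                 selected = object$selected), class = "summary.veh")
}

#' @export
print.summary.veh <- function(x, ...) {
  cat("Dataset:", x$name, "\n")
  cat("Stage gene counts:", paste(names(x$counts), x$counts, sep = "=",
                                  collapse = ", "), "\n\n")
  cat("Per-run subsets (selection-classifier accuracy):\n")
  print(x$runs, row.names = FALSE)
  cat("\nSelected subset:", paste(x$selected$feature_ids, collapse = ", "),
      "\n\nCross-validation of the selected subset:\n")
  print(x$metrics, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot optimizer convergence traces
#'
#' Draws the best-fitness-so-far trace of every independent run against the
#' iteration number.
#'
#' @param x A fitted `"veh"` object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.veh <- function(x, ...) {
  traces <- vapply(x$runs, function(r) r$trace$best_fitness_per_iter,
                   numeric(length(x$runs[[1]]$trace$best_fitness_per_iter)))
  graphics::matplot(seq_len(nrow(traces)) - 1, traces, type = "l", lty = 1,
                    xlab = "iteration", ylab = "best fitness",
                    main = paste("Harris Hawks convergence:", x$name), ...)
  invisible(x)
}

#' Classify new samples with the selected genes
#'
#' Applies the training-set min-max transform of the selected genes to
#' `newdata` and predicts with a classifier trained on the full training
#' data restricted to the selected subset.
#'
#' @param object A fitted `"veh"` object.
#' @param newdata Numeric matrix or data frame; either named columns
#'   containing the selected feature IDs, or exactly one column per selected
#'   gene in order.
#' @param classifier `"svm"`, `"dt"` or `"lr"`.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.veh <- function(object, newdata,
                        classifier = c("svm", "dt", "lr"), ...) {
  classifier <- match.arg(classifier)
  newdata <- as.matrix(newdata)
  ids <- object$selected$feature_ids
  if (!is.null(colnames(newdata)) && all(ids %in% colnames(newdata))) {
    newdata <- newdata[, ids, drop = FALSE]
  } else if (ncol(newdata) != length(ids)) {
    stop("'newdata' must contain the selected genes (",
         paste(ids, collapse = ", "), ")")
  }
  newdata <- sweep(sweep(newdata, 2, object$train$mins, "-"),
                   2, object$train$range, "/")
  model <- fit_classifier(classifier, object$train$values,
                          object$train$labels)
  predict_classifier(model, newdata)
}

#' Evaluate a fixed gene subset with the repeated CV protocol
#'
#' Preprocesses the dataset (mean imputation, min-max normalization),
#' restricts it to a given list of feature IDs, and runs the repeated
#' stratified cross-validation protocol with each requested classifier.
#' This is how a published subset is re-scored without re-running selection.
#'
#' @param ds An [expression_dataset] (raw; preprocessing is applied here).
#' @param feature_ids Character vector of feature IDs; an unknown ID raises
#'   an error naming it.
#' @param classifiers Classifiers to evaluate.
#' @param repeats,folds Protocol size; default 10 x 10-fold.
#' @param seed Base seed for the fold splits.
#' @param leakage_safe_cv Re-estimate normalization within training folds,
#'   see [veh()].
#' @return Named list of `cv_report` objects, one per classifier.
#' @export
evaluate_subset <- function(ds, feature_ids,
                            classifiers = c("dt", "svm", "lr"),
                            repeats = 10, folds = 10, seed = 1,
                            leakage_safe_cv = FALSE) {
  stopifnot(inherits(ds, "expression_dataset"), length(feature_ids) >= 1)
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  unknown <- setdiff(feature_ids, ds$feature_ids)
  if (length(unknown) > 0) {
    stop("unknown feature ID(s): ", paste(unknown, collapse = ", "))
  }
  ds_imp <- impute_missing_mean(ds)
  eval_ds <- if (leakage_safe_cv) ds_imp else minmax_normalize(ds_imp)
  lapply(stats::setNames(classifiers, classifiers), function(cl) {
    repeated_cv_evaluate(eval_ds, feature_ids = feature_ids,
                         classifier = cl, repeats = repeats, folds = folds,
                         seed = seed,
                         normalize_within_folds = leakage_safe_cv)
  })
}
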