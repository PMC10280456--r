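# Classifier wrappers used by the evaluation protocol. Each classifier is
# fit at fixed, conventional settings: decision tree (random_state 0, max
# depth 8, up to 10 candidate features per node), RBF support vector machine
# (C = 1, one-vs-one), and l2-regularized logistic regression (C = 1,
# one-vs-rest).

#' Classifier configuration defaults
#'
#' @return Named list of the default settings for the three evaluation
#'   classifiers.
#' @export
classifier_defaults <- function() {
  list(dt = list(random_state = 0, max_depth = 8, max_features = 10),
       svm = list(C = 1.0, kernel = "radial"),
       lr = list(C = 1.0, penalty = "l2", tol = 1e-4, max_iter = 100))
}

# fit_classifier / predict_classifier: uniform interface over the three kinds
fit_classifier <- function(kind, x, y, config = NULL) {
  cfg <- utils::modifyList(classifier_defaults()[[kind]],
                           if (is.null(config)) list() else config)
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) stop("degenerate training fold: a single class present")
  switch(kind,
    dt = {
      mf <- min(cfg$max_features, ncol(x))  # capped at available features
      tree <- .with_seed(cfg$random_state,
                         grow_tree(x, as.integer(y), K = nlevels(y),
                                   splitter = "best", max_features = mf,
                                   max_depth = cfg$max_depth))
      list(kind = "dt", tree = tree, levels = levels(y))
    },
    svm = {
      fit <- e1071::svm(x, y, kernel = cfg$kernel, cost = cfg$C,
                        scale = FALSE)
      list(kind = "svm", fit = fit, levels = levels(y))
    },
    lr = {
      fit <- ridge_logistic(x, y, C = cfg$C, tol = cfg$tol,
                            max_iter = cfg$max_iter)
      list(kind = "lr", fit = fit, levels = levels(y))
    },
    stop("unknown classifier kind: ", kind))
}

predict_classifier <- function(model, x) {
  switch(model$kind,
    dt = model$levels[predict_tree(model$tree, x)],
    svm = as.character(predict(model$fit, x)),
    lr = predict_ridge_logistic(model$fit, x),
    stop("unknown classifier kind"))
}

#' l2-regularized logistic regression (Newton/IRLS)
#'
#' Minimizes `0.5 * ||w||^2 + C * sum(log(1 + exp(-margin)))` with an
#' unpenalized intercept, by damped Newton iterations to a gradient
#' tolerance. Multi-class problems are decomposed one-vs-rest and predicted
#' by the largest linear score. Non-convergence within the iteration cap is
#' recorded on the returned object, not silently ignored.
#'
#' @param x Numeric predictor matrix (any number of columns >= 1).
#' @param y Factor of class labels.
#' @param C Inverse regularization strength (> 0); default 1.
#' @param tol Maximum absolute gradient component at convergence.
#' @param max_iter Newton iteration cap per binary problem.
#' @return An object of class `"ridge_logistic"` with per-class coefficient
#'   vectors and a `converged` flag.
#' @export
ridge_logistic <- function(x, y, C = 1.0, tol = 1e-4, max_iter = 100) {
  x <- as.matrix(x)
  y <- droplevels(factor(y))
  stopifnot(C > 0, nlevels(y) >= 2)
  lv <- levels(y)
  # binary: one discriminant for the second level; multiclass: one per level
  targets <- if (nlevels(y) == 2) lv[2] else lv
  fits <- lapply(targets, function(cl) {
    .ridge_logistic_binary(x, as.numeric(y == cl), C, tol, max_iter)
  })
  structure(list(levels = lv, targets = targets, fits = fits,
                 converged = all(vapply(fits, `[[`, logical(1), "converged"))),
            class = "ridge_logistic")
}

.ridge_logistic_binary <- function(x, y01, C, tol, max_iter) {
  n <- nrow(x); p <- ncol(x)
  Xd <- cbind(1, x)
  beta <- numeric(p + 1)
  pen <- c(0, rep(1, p))  # intercept unpenalized
  obj <- function(b) {
    eta <- drop(Xd %*% b)
    0.5 * sum(pen * b^2) + C * sum(log1p(exp(-abs(eta))) +
                                     pmax(eta, 0) - y01 * eta)
  }
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    grad <- C * drop(crossprod(Xd, mu - y01)) + pen * beta
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- C * crossprod(Xd, Xd * w) + diag(pen + 1e-10, p + 1)
    step <- solve(H, grad)
    # halving line search keeps the damped Newton step monotone
    f0 <- obj(beta)
    lam <- 1
    repeat {
      cand <- beta - lam * step
      if (obj(cand) <= f0 || lam < 1e-8) break
      lam <- lam / 2
    }
    beta <- cand
  }
  list(beta = beta, converged = converged, iterations = it)
}

predict_ridge_logistic <- function(fit, x) {
  x <- as.matrix(x)
  scores <- vapply(fit$fits,
                   function(f) drop(cbind(1, x) %*% f$beta),
                   numeric(nrow(x)))
  scores <- matrix(scores, nrow = nrow(x))
  if (length(fit$targets) == 1) {
    ifelse(scores[, 1] > 0, fit$levels[2], fit$levels[1])
  } else {
    fit$targets[max.col(scores, ties.method = "first")]
  }
}
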