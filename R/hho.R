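# Binary Harris Hawks optimization over gene-inclusion masks.
#
# Hawks are continuous positions in [0,1]^D; a position is decoded to a
# binary mask by rounding (>= 0.5 -> keep the gene). The escape-energy
# schedule E = 2*E0*(1 - t/T) switches between global exploration (|E| >= 1)
# and four exploitation moves (soft/hard besiege, each with or without
# progressive rapid dives) chosen by |E| and the capture-probability draw r.
# Fitness (minimized) couples KNN cross-validation error with a subset-size
# penalty: alpha*(1 - acc) + (1 - alpha)*f_num/F_num.

.clip <- function(x, lb = 0, ub = 1) pmin(pmax(x, lb), ub)

#' Initialize a hawk population
#'
#' @param n_hawks Number of hawks (>= 2).
#' @param D Dimension (number of candidate genes), >= 1.
#' @param lb,ub Position bounds, default `[0, 1]`.
#' @param seed Optional integer seed; `NULL` draws from the current RNG
#'   stream.
#' @return An `n_hawks` x `D` matrix of i.i.d. uniform positions.
#' @export
initialize_population <- function(n_hawks, D, lb = 0, ub = 1, seed = NULL) {
  stopifnot(n_hawks >= 2, D >= 1, lb < ub)
  draw <- function() matrix(stats::runif(n_hawks * D, lb, ub), n_hawks, D)
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}

#' Escape energy schedule
#'
#' @param E0 Initial energy in (-1, 1).
#' @param t Current iteration, `0 <= t <= T`.
#' @param T Total iterations (> 0).
#' @return `2 * E0 * (1 - t / T)`.
#' @export
escape_energy <- function(E0, t, T) {
  stopifnot(T > 0, t >= 0, t <= T)
  2 * E0 * (1 - t / T)
}

#' Exploration move (|E| >= 1)
#'
#' With probability draw `q >= 0.5` the hawk perches relative to a random
#' flock member; otherwise relative to the rabbit and the flock mean.
#'
#' @param x Current position.
#' @param x_rand Position of a randomly chosen hawk.
#' @param x_rabbit Best position found so far.
#' @param x_mean Mean position of the population.
#' @param q,r1,r2,r3,r4 Uniform(0,1) draws.
#' @param lb,ub Bounds.
#' @return The updated position, clipped to `[lb, ub]`.
#' @export
exploration_update <- function(x, x_rand, x_rabbit, x_mean,
                               q, r1, r2, r3, r4, lb = 0, ub = 1) {
  stopifnot(length(x_rand) == length(x), length(x_rabbit) == length(x),
            length(x_mean) == length(x))
  new <- if (q >= 0.5) {
    x_rand - r1 * abs(x_rand - 2 * r2 * x)
  } else {
    (x_rabbit - x_mean) - r3 * (lb + r4 * (ub - lb))
  }
  .clip(new, lb, ub)
}

#' Soft besiege (r >= 0.5, 0.5 <= |E| < 1)
#'
#' `X(t+1) = D(t) - E * |J * x_rabbit - x|` with `D(t) = x_rabbit - x` and
#' jump strength `J = 2 * (1 - r5)`.
#'
#' @param x,x_rabbit Positions.
#' @param E Escape energy.
#' @param J Jump strength in (0, 2).
#' @param lb,ub Bounds.
#' @return Updated position, clipped.
#' @export
soft_besiege <- function(x, x_rabbit, E, J, lb = 0, ub = 1) {
  stopifnot(length(x_rabbit) == length(x))
  .clip((x_rabbit - x) - E * abs(J * x_rabbit - x), lb, ub)
}

#' Hard besiege (r >= 0.5, |E| < 0.5)
#'
#' `X(t+1) = x_rabbit - E * |D(t)|` with `D(t) = x_rabbit - x`.
#'
#' @inheritParams soft_besiege
#' @return Updated position, clipped.
#' @export
hard_besiege <- function(x, x_rabbit, E, lb = 0, ub = 1) {
  stopifnot(length(x_rabbit) == length(x))
  .clip(x_rabbit - E * abs(x_rabbit - x), lb, ub)
}

#' Levy flight step (Mantegna construction)
#'
#' Heavy-tailed steps `scale * u * sigma(beta) / |v|^(1/beta)` with u, v
#' standard normal, emulating the erratic jumps of escaping prey during
#' rapid dives.
#'
#' @param D Number of dimensions.
#' @param beta Stability index in (1, 2]; default 1.5.
#' @param scale Step scale; default 0.01.
#' @return Numeric vector of `D` steps (uses the current RNG stream).
#' @export
levy_flight <- function(D, beta = 1.5, scale = 0.01) {
  stopifnot(beta > 1, beta <= 2, D >= 1)
  sigma <- (gamma(1 + beta) * sin(pi * beta / 2) /
              (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  u <- stats::rnorm(D, 0, sigma)
  v <- stats::rnorm(D)
  scale * u / abs(v)^(1 / beta)
}

#' Decode a continuous position to a gene mask by rounding
#'
#' @param x Numeric vector with entries in `[0, 1]`.
#' @return Integer 0/1 vector; an entry is 1 iff `x >= 0.5` (half rounds up).
#' @export
binarize <- function(x) {
  if (any(x < 0 | x > 1)) stop("position entries must lie in [0, 1]")
  as.integer(x >= 0.5)
}

#' Repair an all-zero mask
#'
#' The fitness is undefined for an empty gene set, so one uniformly chosen
#' coordinate is switched on (in the mask and, consistently, in the
#' continuous position).
#'
#' @param mask All-zero integer mask.
#' @param x Matching continuous position.
#' @return List with repaired `mask` and `x` (uses the current RNG stream).
#' @export
repair_empty_mask <- function(mask, x) {
  stopifnot(length(mask) == length(x), all(mask == 0))
  j <- sample.int(length(mask), 1)
  mask[j] <- 1L
  x[j] <- 1.0
  list(mask = mask, x = x)
}

# Pooled stratified k-fold KNN accuracy on the mask-restricted matrix.
# Fold assignment is passed in so every candidate is scored on identical
# folds; tie-breaking inside class::knn is made deterministic by isolating
# the RNG on a fixed seed.
knn_cv_accuracy <- function(x, labels, mask, k = 5, fold_ids, tie_seed = 1) {
  cols <- which(mask == 1)
  xm <- x[, cols, drop = FALSE]
  n <- nrow(xm)
  pred <- character(n)
  .with_seed(tie_seed, {
    for (f in sort(unique(fold_ids))) {
      te <- which(fold_ids == f)
      tr <- which(fold_ids != f)
      if (k >= length(tr)) {
        stop("knn_k (", k, ") must be smaller than the training-fold size (",
             length(tr), ")")
      }
      pred[te] <- as.character(
        class::knn(xm[tr, , drop = FALSE], xm[te, , drop = FALSE],
                   labels[tr], k = k))
    }
  })
  mean(pred == as.character(labels))
}

#' Subset fitness: KNN error plus size penalty
#'
#' `fitness = alpha * (1 - KNN_acc) + (1 - alpha) * f_num / F_num`, where
#' `KNN_acc` is the stratified k-fold cross-validation accuracy of a
#' k-nearest-neighbour classifier (Euclidean distance) restricted to the
#' masked genes, `f_num` the number of selected genes and `F_num` the total
#' dimension. Lower is better; the value lies in `[0, 1]`.
#'
#' @param mask Integer 0/1 vector with at least one 1.
#' @param ds A preprocessed [expression_dataset] whose gene count equals
#'   `length(mask)`.
#' @param alpha Accuracy/size trade-off in `[0, 1]`; default 0.99.
#' @param knn_k Neighbours, default 5; must be smaller than every training
#'   fold.
#' @param eval_folds Number of stratified folds, default 5.
#' @param eval_seed Seed fixing the folds (and KNN tie-breaks).
#' @param fold_ids Optional precomputed fold assignment (overrides
#'   `eval_folds`/`eval_seed` fold construction), so a whole optimizer run
#'   scores all candidates on identical folds.
#' @return The fitness value.
#' @export
evaluate_fitness <- function(mask, ds, alpha = 0.99, knn_k = 5,
                             eval_folds = 5, eval_seed = 1, fold_ids = NULL) {
  stopifnot(inherits(ds, "expression_dataset"),
            length(mask) == ncol(ds$values), alpha >= 0, alpha <= 1)
  f_num <- sum(mask == 1)
  if (f_num == 0) stop("empty mask: fitness is undefined for zero genes")
  if (is.null(fold_ids)) {
    fold_ids <- stratified_kfold_indices(ds$labels, eval_folds, eval_seed)
  }
  acc <- knn_cv_accuracy(ds$values, ds$labels, mask, k = knn_k,
                         fold_ids = fold_ids, tie_seed = eval_seed)
  alpha * (1 - acc) + (1 - alpha) * f_num / length(mask)
}

#' Harris Hawks gene-subset search
#'
#' Runs the full binary optimizer: uniform population initialization, then
#' `n_iter` sweeps in which every hawk redraws its energy and jump strength,
#' moves by the exploration rule or one of the four besiege rules selected by
#' `|E|` and `r`, is clipped to `[0,1]^D`, decoded by rounding, repaired if
#' empty, and scored; the rabbit (incumbent) is the best-fitness candidate
#' ever evaluated, with ties kept by the earliest encounter.
#'
#' @param ds A preprocessed [expression_dataset]; may be `NULL` when a
#'   custom `fitness_fn` and `D` are supplied (surrogate mode).
#' @param n_hawks Population size, default 30.
#' @param n_iter Iterations `T`, default 100.
#' @param alpha,knn_k,eval_folds Fitness parameters, see
#'   [evaluate_fitness()].
#' @param levy_beta,levy_scale Levy-flight parameters for the dive moves.
#' @param dive_variant `"original"` (the hard dive's first candidate uses the
#'   population mean) or `"as_printed"` (hard dive identical to the soft
#'   dive).
#' @param seed Integer seed controlling the entire run.
#' @param fitness_fn Optional function `mask -> fitness in [0,1]` replacing
#'   the KNN fitness (used for surrogate benchmarks); requires `D`.
#' @param D Dimension when `ds` is `NULL`.
#' @param cache Memoize fitness by mask (default `TRUE`); results are
#'   identical with the cache off.
#' @param trace_candidates Record every evaluated candidate (mask key and
#'   fitness) in the trace; for audit/verification.
#' @return List with `subset` (list: `feature_ids`, `indices`, `mask`,
#'   `fitness`) and `trace` (list: `best_fitness_per_iter` of length
#'   `n_iter + 1`, `best_size_per_iter`, `evaluations`, and `candidates` if
#'   requested).
#' @export
hho_select <- function(ds, n_hawks = 30, n_iter = 100, alpha = 0.99,
                       knn_k = 5, eval_folds = 5,
                       levy_beta = 1.5, levy_scale = 0.01,
                       dive_variant = c("original", "as_printed"),
                       seed = 1, fitness_fn = NULL, D = NULL,
                       cache = TRUE, trace_candidates = FALSE) {
  dive_variant <- match.arg(dive_variant)
  stopifnot(n_hawks >= 2, n_iter >= 1)
  if (is.null(fitness_fn)) {
    stopifnot(inherits(ds, "expression_dataset"))
    D <- ncol(ds$values)
  } else {
    if (is.null(D)) stop("'D' is required with a custom fitness_fn")
  }
  stopifnot(D >= 1)

  # derive child seeds: one per substream (init, search, fitness folds)
  seeds <- .with_seed(seed, sample.int(.Machine$integer.max - 1, 3))
  if (is.null(fitness_fn)) {
    fold_ids <- stratified_kfold_indices(ds$labels, eval_folds, seeds[3])
    fitness_fn <- function(mask) {
      evaluate_fitness(mask, ds, alpha = alpha, knn_k = knn_k,
                       fold_ids = fold_ids, eval_seed = seeds[3])
    }
  }

  cache_env <- new.env(parent = emptyenv())
  n_eval <- 0L
  candidates <- if (trace_candidates) list() else NULL
  score <- function(mask) {
    n_eval <<- n_eval + 1L
    key <- paste(which(mask == 1L), collapse = ",")
    f <- if (cache) cache_env[[key]] else NULL
    if (is.null(f)) {
      f <- fitness_fn(mask)
      if (cache) cache_env[[key]] <- f
    }
    if (trace_candidates) {
      candidates[[length(candidates) + 1L]] <<- list(key = key, fitness = f)
    }
    f
  }
  # clip -> decode -> repair -> score; returns the (possibly repaired)
  # position with its mask and fitness
  eval_position <- function(x) {
    x <- .clip(x)
    mask <- binarize(x)
    if (sum(mask) == 0) {
      rep <- repair_empty_mask(mask, x)
      mask <- rep$mask
      x <- rep$x
    }
    list(x = x, mask = mask, fitness = score(mask))
  }

  # isolate the run's RNG from the caller's stream
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old_rng <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_rng, envir = globalenv()), add = TRUE)
  }
  pos <- initialize_population(n_hawks, D, seed = seeds[1])
  set.seed(seeds[2])  # search substream: hawk draws, Levy steps, repairs

  hawks <- lapply(seq_len(n_hawks), function(i) eval_position(pos[i, ]))
  best <- hawks[[which.min(vapply(hawks, `[[`, numeric(1), "fitness"))[1]]]
  trace_f <- numeric(n_iter + 1)
  trace_s <- integer(n_iter + 1)
  trace_f[1] <- best$fitness
  trace_s[1] <- sum(best$mask)

  dive <- function(hawk, x_mean, E, J, hard) {
    x <- hawk$x
    y_anchor <- if (hard && dive_variant == "original") x_mean else x
    Y <- .clip(best$x - E * abs(J * best$x - y_anchor))
    cand <- eval_position(Y)
    if (cand$fitness < hawk$fitness) return(cand)
    S <- stats::runif(D)
    Z <- .clip(cand$x + S * levy_flight(D, levy_beta, levy_scale))
    cand2 <- eval_position(Z)
    if (cand2$fitness < hawk$fitness) return(cand2)
    hawk
  }

  for (t in seq_len(n_iter)) {
    x_mean <- colMeans(do.call(rbind, lapply(hawks, `[[`, "x")))
    for (i in seq_len(n_hawks)) {
      hawk <- hawks[[i]]
      E0 <- stats::runif(1, -1, 1)
      r5 <- stats::runif(1)
      J <- 2 * (1 - r5)
      r <- stats::runif(1)
      q <- stats::runif(1)
      E <- escape_energy(E0, t, n_iter)
      if (abs(E) >= 1) {
        x_rand <- hawks[[sample.int(n_hawks, 1)]]$x
        rr <- stats::runif(4)
        newx <- exploration_update(hawk$x, x_rand, best$x, x_mean,
                                   q, rr[1], rr[2], rr[3], rr[4])
        hawks[[i]] <- eval_position(newx)
      } else if (r >= 0.5 && abs(E) >= 0.5) {
        hawks[[i]] <- eval_position(soft_besiege(hawk$x, best$x, E, J))
      } else if (r >= 0.5) {
        hawks[[i]] <- eval_position(hard_besiege(hawk$x, best$x, E))
      } else {
        hawks[[i]] <- dive(hawk, x_mean, E, J, hard = abs(E) < 0.5)
      }
      if (hawks[[i]]$fitness < best$fitness) best <- hawks[[i]]
    }
    trace_f[t + 1] <- best$fitness
    trace_s[t + 1] <- sum(best$mask)
  }

  indices <- which(best$mask == 1L)
  subset <- list(
    feature_ids = if (!is.null(ds)) ds$feature_ids[indices] else NULL,
    indices = indices, mask = best$mask, fitness = best$fitness)
  trace <- list(best_fitness_per_iter = trace_f,
                best_size_per_iter = trace_s,
                evaluations = n_eval)
  if (trace_candidates) trace$candidates <- candidates
  list(subset = subset, trace = trace)
}

#' Soft besiege with progressive rapid dives (r < 0.5, |E| >= 0.5)
#'
#' First candidate `Y = clip(x_rabbit - E*|J*x_rabbit - x|)`; if not better
#' than the current position, a Levy dive `Z = clip(Y + S * LF(D))` is tried;
#' if neither improves, the hawk stays put (greedy acceptance).
#'
#' @param x Current position; `fx` its fitness.
#' @param x_rabbit Incumbent position.
#' @param E,J Energy and jump strength.
#' @param eval_fn Function taking a position and returning
#'   `list(x, mask, fitness)` after clip/decode/repair.
#' @param fx Fitness of `x`.
#' @param S Uniform(0,1) dive vector; drawn if `NULL`.
#' @param lf Levy step vector; drawn if `NULL`.
#' @param levy_beta,levy_scale Levy parameters used when drawing `lf`.
#' @return The accepted candidate as `list(x, mask, fitness)`; the input
#'   position (with fitness `fx`) if both candidates are rejected.
#' @export
soft_besiege_dive <- function(x, x_rabbit, E, J, eval_fn, fx,
                              S = NULL, lf = NULL,
                              levy_beta = 1.5, levy_scale = 0.01) {
  Y <- .clip(x_rabbit - E * abs(J * x_rabbit - x))
  cand <- eval_fn(Y)
  if (cand$fitness < fx) return(cand)
  if (is.null(S)) S <- stats::runif(length(x))
  if (is.null(lf)) lf <- levy_flight(length(x), levy_beta, levy_scale)
  cand2 <- eval_fn(.clip(cand$x + S * lf))
  if (cand2$fitness < fx) return(cand2)
  list(x = x, mask = binarize(.clip(x)), fitness = fx)
}

#' Hard besiege with progressive rapid dives (r < 0.5, |E| < 0.5)
#'
#' As [soft_besiege_dive()] but, under `dive_variant = "original"`, the first
#' candidate is anchored at the population mean:
#' `Y = clip(x_rabbit - E*|J*x_rabbit - x_mean|)`. With `"as_printed"` the
#' move is identical to the soft dive.
#'
#' @inheritParams soft_besiege_dive
#' @param x_mean Population mean position.
#' @param dive_variant `"original"` or `"as_printed"`.
#' @return The accepted candidate, as in [soft_besiege_dive()].
#' @export
hard_besiege_dive <- function(x, x_rabbit, x_mean, E, J, eval_fn, fx,
                              S = NULL, lf = NULL,
                              dive_variant = c("original", "as_printed"),
                              levy_beta = 1.5, levy_scale = 0.01) {
  dive_variant <- match.arg(dive_variant)
  anchor <- if (dive_variant == "original") x_mean else x
  Y <- .clip(x_rabbit - E * abs(J * x_rabbit - anchor))
  cand <- eval_fn(Y)
  if (cand$fitness < fx) return(cand)
  if (is.null(S)) S <- stats::runif(length(x))
  if (is.null(lf)) lf <- levy_flight(length(x), levy_beta, levy_scale)
  cand2 <- eval_fn(.clip(cand$x + S * lf))
  if (cand2$fitness < fx) return(cand2)
  list(x = x, mask = binarize(.clip(x)), fitness = fx)
}

#' Export an optimizer trace as CSV
#'
#' @param trace A trace from [hho_select()].
#' @param path Output CSV path with columns iteration, best_fitness,
#'   subset_size.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(
    data.frame(iteration = seq_along(trace$best_fitness_per_iter) - 1L,
               best_fitness = trace$best_fitness_per_iter,
               subset_size = trace$best_size_per_iter),
    path, row.names = FALSE)
  invisible(path)
}
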