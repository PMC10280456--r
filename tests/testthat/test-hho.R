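test_that("escape energy follows the linear cooling schedule", {
  expect_equal(escape_energy(0.8, 25, 100), 1.2)
  expect_equal(escape_energy(-0.5, 50, 100), -0.5)
  expect_equal(escape_energy(0.9, 100, 100), 0)
  expect_equal(escape_energy(-0.7, 100, 100), 0)
  expect_error(escape_energy(0.5, 1, 0))
})

test_that("exploration update matches hand arithmetic and collapses correctly", {
  x <- c(0.2, 0.8); xr <- c(0.9, 0.1)
  rabbit <- c(0.5, 0.5); xm <- c(0.4, 0.4)
  # q >= 0.5, r1 = 0: perch exactly on the random hawk
  expect_equal(exploration_update(x, xr, rabbit, xm, q = 0.7,
                                  r1 = 0, r2 = 0.3, r3 = 0, r4 = 0), xr)
  # q < 0.5, r3 = 0: rabbit minus flock mean, clipped
  expect_equal(exploration_update(x, xr, rabbit, xm, q = 0.2,
                                  r1 = 0, r2 = 0, r3 = 0, r4 = 0.9),
               pmin(pmax(rabbit - xm, 0), 1))
  # hand arithmetic: (0.9,0.1) - 0.5*|(0.9,0.1) - 2*0.25*(0.2,0.8)|
  expect_equal(exploration_update(x, xr, rabbit, xm, q = 0.9,
                                  r1 = 0.5, r2 = 0.25, r3 = 0, r4 = 0),
               c(0.5, 0.0))
  expect_error(exploration_update(c(0.1), xr, rabbit, xm, 0.5, 0, 0, 0, 0))
})

test_that("soft and hard besiege match hand arithmetic", {
  # E = 0 collapses the soft besiege to the rabbit-distance move
  expect_equal(soft_besiege(c(0.4, 0.6), c(0.8, 0.2), E = 0, J = 1.3),
               pmin(pmax(c(0.4, -0.4), 0), 1))
  # pinned draws: (0.4,-0.4) - 0.4*(0.4,0.4) = (0.24,-0.56) -> clip
  expect_equal(soft_besiege(c(0.4, 0.6), c(0.8, 0.2), E = 0.4, J = 1),
               c(0.24, 0.0))
  # J = 0 (r5 = 1) reduces the bracket to |x|
  x <- c(0.3, 0.9); rb <- c(0.6, 0.1)
  expect_equal(soft_besiege(x, rb, E = 0.2, J = 0),
               pmin(pmax((rb - x) - 0.2 * abs(x), 0), 1))

  expect_equal(hard_besiege(c(0.1), c(0.5), E = 0.2), 0.42)
  expect_equal(hard_besiege(c(0.1, 0.9), c(0.5, 0.5), E = 0), c(0.5, 0.5))
  expect_equal(hard_besiege(rb, rb, E = 0.77), rb)
})

test_that("Levy flight reproduces the Mantegna construction exactly", {
  beta <- 1.5; scale <- 0.01
  set.seed(99)
  lf <- levy_flight(8, beta, scale)
  # oracle: recompute from the same pinned normal draws
  sigma <- (gamma(1 + beta) * sin(pi * beta / 2) /
              (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  set.seed(99)
  u <- rnorm(8, 0, sigma); v <- rnorm(8)
  expect_equal(lf, scale * u / abs(v)^(1 / beta))
  set.seed(99)
  expect_identical(levy_flight(8, beta, scale), lf)
  expect_error(levy_flight(8, beta = 0.5))
})

test_that("Levy step tail index is consistent with beta = 1.5", {
  set.seed(123)
  draws <- abs(levy_flight(1e5, 1.5, 1))
  ord <- sort(draws, decreasing = TRUE)
  k <- 1000
  hill <- 1 / mean(log(ord[1:k] / ord[k + 1]))
  expect_lt(abs(hill - 1.5), 0.2)
})

test_that("binarize rounds half up and repair switches on one coordinate", {
  expect_equal(binarize(c(0.49, 0.5, 1.0)), c(0L, 1L, 1L))
  expect_equal(binarize(c(0, 1, 1)), c(0L, 1L, 1L))
  expect_equal(binarize(c(0.1, 0.49, 0.2)), c(0L, 0L, 0L))
  expect_error(binarize(c(-0.1, 0.5)), "\\[0, 1\\]")

  set.seed(5)
  rep1 <- repair_empty_mask(rep(0L, 5), rep(0.2, 5))
  expect_equal(sum(rep1$mask), 1L)
  j <- which(rep1$mask == 1)
  expect_equal(rep1$x[j], 1.0)
  expect_equal(rep1$x[-j], rep(0.2, 4))
  expect_error(repair_empty_mask(c(0L, 1L), c(0.1, 0.9)))
})

test_that("repair picks the switched-on coordinate uniformly", {
  set.seed(11)
  picks <- replicate(1e4, which(repair_empty_mask(rep(0L, 5),
                                                  rep(0, 5))$mask == 1))
  expect_gt(chisq.test(tabulate(picks, 5))$p.value, 0.01)
})

test_that("population initialization is deterministic, bounded and uniform", {
  a <- initialize_population(20, 10, seed = 4)
  b <- initialize_population(20, 10, seed = 4)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
  big <- initialize_population(1000, 100, seed = 6)
  se <- sqrt(1 / 12) / sqrt(length(big))
  expect_lt(abs(mean(big) - 0.5), 3 * se)
})

test_that("fitness equals the accuracy/size trade-off computed independently", {
  toy <- make_separable_toy(40, 20, seed = 8)
  ds <- minmax_normalize(toy$dataset)
  folds <- stratified_kfold_indices(ds$labels, 5, seed = 2)
  cases <- list(
    list(mask = c(1L, rep(0L, 19)), alpha = 0.99),   # perfect acc, 1 gene
    list(mask = rep(1L, 20), alpha = 0.99),          # all genes
    list(mask = c(1L, 1L, 1L, rep(0L, 17)), alpha = 0.9),
    list(mask = c(0L, 1L, rep(0L, 18)), alpha = 0.99))  # noise-only gene
  for (cs in cases) {
    acc <- veh:::knn_cv_accuracy(ds$values, ds$labels, cs$mask, k = 5,
                                 fold_ids = folds)
    got <- evaluate_fitness(cs$mask, ds, alpha = cs$alpha, fold_ids = folds)
    expect_equal(got, cs$alpha * (1 - acc) +
                   (1 - cs$alpha) * sum(cs$mask) / 20)
  }
  # the separable gene alone gives acc 1, so fitness is the pure size penalty
  expect_equal(evaluate_fitness(c(1L, rep(0L, 19)), ds, fold_ids = folds),
               0.01 * 1 / 20)
  expect_error(evaluate_fitness(rep(0L, 20), ds), "empty mask")
  expect_error(evaluate_fitness(rep(1L, 20), ds, knn_k = 50), "smaller")
})

test_that("fitness is monotone in accuracy and size as the trade-off dictates", {
  # direct consequence of the formula: fix one argument, vary the other
  f <- function(acc, fn, Fn, a = 0.99) a * (1 - acc) + (1 - a) * fn / Fn
  expect_lt(f(0.95, 5, 100), f(0.90, 5, 100))
  expect_lt(f(0.95, 5, 100), f(0.95, 10, 100))
  expect_equal(f(1, 5, 100), 0.0005)
  expect_equal(f(0, 100, 100), 1)
  expect_equal(f(0.9, 10, 200), 0.0995)
})

test_that("dive moves accept only improving candidates", {
  toy <- make_separable_toy(40, 10, seed = 14)
  ds <- minmax_normalize(toy$dataset)
  folds <- stratified_kfold_indices(ds$labels, 5, seed = 3)
  eval_fn <- function(x) {
    x <- pmin(pmax(x, 0), 1)
    mask <- binarize(x)
    if (sum(mask) == 0) {
      r <- repair_empty_mask(mask, x); mask <- r$mask; x <- r$x
    }
    list(x = x, mask = mask,
         fitness = evaluate_fitness(mask, ds, fold_ids = folds))
  }
  set.seed(21)
  for (trial in 1:50) {
    x <- runif(10); rabbit <- runif(10)
    fx <- eval_fn(x)$fitness
    E <- runif(1, -1, 1); J <- 2 * (1 - runif(1))
    out <- soft_besiege_dive(x, rabbit, E, J, eval_fn, fx)
    expect_lte(out$fitness, fx)
    out2 <- hard_besiege_dive(x, rabbit, runif(10), E, J, eval_fn, fx)
    expect_lte(out2$fitness, fx)
    # candidate-set oracle: the accepted fitness is either an improvement
    # or exactly the starting fitness
    expect_true(out$fitness < fx || identical(out$x, x))
  }
  # with identical draws, the as_printed hard dive equals the soft dive
  x <- c(0.2, 0.7, 0.4); rabbit <- c(0.9, 0.1, 0.6); xm <- c(0.5, 0.5, 0.5)
  cheap <- function(x2) {
    x2 <- pmin(pmax(x2, 0), 1); m <- binarize(x2)
    if (sum(m) == 0) m[1] <- 1L
    list(x = x2, mask = m, fitness = sum(m) / 3)
  }
  S <- c(0.3, 0.3, 0.3); lf <- c(0.01, -0.02, 0.005)
  a <- soft_besiege_dive(x, rabbit, 0.6, 1.1, cheap, 0.9, S = S, lf = lf)
  b <- hard_besiege_dive(x, rabbit, xm, 0.6, 1.1, cheap, 0.9, S = S, lf = lf,
                         dive_variant = "as_printed")
  expect_identical(a, b)
  # original variant with x_mean = x collapses to the soft dive
  d <- hard_besiege_dive(x, rabbit, x, 0.6, 1.1, cheap, 0.9, S = S, lf = lf,
                         dive_variant = "original")
  expect_identical(a, d)
})

test_that("a one-iteration run returns the best of every evaluated candidate", {
  toy <- make_separable_toy(30, 8, seed = 31)
  ds <- minmax_normalize(toy$dataset)
  res <- hho_select(ds, n_hawks = 6, n_iter = 1, seed = 17,
                    trace_candidates = TRUE)
  fits <- vapply(res$trace$candidates, `[[`, numeric(1), "fitness")
  expect_equal(res$subset$fitness, min(fits))
  # the returned mask's fitness re-evaluates to the same value
  folds_fit <- res$subset$fitness
  expect_equal(res$trace$best_fitness_per_iter[2], folds_fit)
})

test_that("the rabbit trace is non-increasing and positions stay in bounds", {
  toy <- make_separable_toy(30, 12, seed = 41)
  ds <- minmax_normalize(toy$dataset)
  for (sd_ in c(1, 2, 3)) {
    res <- hho_select(ds, n_hawks = 8, n_iter = 15, seed = sd_)
    expect_true(all(diff(res$trace$best_fitness_per_iter) <= 0))
    expect_true(all(res$subset$mask %in% c(0L, 1L)))
    expect_gte(sum(res$subset$mask), 1)
  }
})

test_that("runs are reproducible and unaffected by the fitness cache", {
  toy <- make_separable_toy(30, 10, seed = 51)
  ds <- minmax_normalize(toy$dataset)
  a <- hho_select(ds, n_hawks = 6, n_iter = 8, seed = 23)
  b <- hho_select(ds, n_hawks = 6, n_iter = 8, seed = 23)
  expect_identical(a$subset, b$subset)
  expect_identical(a$trace$best_fitness_per_iter, b$trace$best_fitness_per_iter)
  nc <- hho_select(ds, n_hawks = 6, n_iter = 8, seed = 23, cache = FALSE)
  expect_identical(a$subset, nc$subset)
  expect_identical(a$trace$best_fitness_per_iter,
                   nc$trace$best_fitness_per_iter)
  # caller's RNG stream is untouched by a run
  set.seed(77); before <- runif(3)
  set.seed(77); invisible(hho_select(ds, n_hawks = 6, n_iter = 3, seed = 1))
  expect_identical(runif(3), before)
})

test_that("the optimizer solves a surrogate one-max problem", {
  D <- 12
  onemax <- function(mask) 1 - sum(mask) / D  # optimum: all ones, value 0
  # exhaustive-enumeration oracle over all 2^12 masks
  masks <- as.matrix(expand.grid(rep(list(0:1), D)))
  opt <- min(apply(masks[rowSums(masks) > 0, ], 1, onemax))
  expect_equal(opt, 0)
  res <- hho_select(NULL, n_hawks = 10, n_iter = 40, seed = 3,
                    fitness_fn = onemax, D = D)
  expect_equal(res$subset$fitness, opt)
})
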