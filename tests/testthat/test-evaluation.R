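test_that("stratified folds partition samples and balance every class", {
  labels <- rep(c("a", "b"), each = 10)
  f <- stratified_kfold_indices(labels, 10, seed = 1)
  expect_setequal(unique(f), 1:10)
  for (k in 1:10) {
    expect_equal(sum(f == k & labels == "a"), 1)
    expect_equal(sum(f == k & labels == "b"), 1)
  }
  # partition contract on an unbalanced 3-class problem
  labels2 <- rep(c("a", "b", "c"), c(13, 7, 9))
  f2 <- stratified_kfold_indices(labels2, 5, seed = 2)
  expect_length(f2, 29)
  for (cl in c("a", "b", "c")) {
    counts <- tabulate(f2[labels2 == cl], 5)
    expect_lte(diff(range(counts)), 1)
  }
  expect_identical(f2, stratified_kfold_indices(labels2, 5, seed = 2))
  expect_error(stratified_kfold_indices(rep(c("a", "b"), c(9, 20)), 10),
               "fewer members")
})

test_that("metrics match direct arithmetic on a fixed confusion table", {
  # binary counts TP = 3, FP = 1, FN = 1, TN = 5 (positive class first row)
  cm <- matrix(c(3, 1, 1, 5), 2, 2, byrow = TRUE,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  m <- classification_metrics(cm)
  expect_equal(m$acc, 0.8)
  # positive class: precision 3/4, recall 3/4, f1 3/4
  # negative class: precision 5/6, recall 5/6, f1 5/6
  expect_equal(m$precision, (3 / 4 + 5 / 6) / 2)
  expect_equal(m$recall, (3 / 4 + 5 / 6) / 2)
  expect_equal(m$f1, (3 / 4 + 5 / 6) / 2)

  perfect <- classification_metrics(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(unlist(perfect), c(acc = 1, precision = 1, recall = 1, f1 = 1))

  # a class never predicted contributes 0 precision to the macro mean
  m0 <- classification_metrics(c("a", "a", "b"), c("a", "a", "a"))
  expect_equal(m0$precision, (2 / 3 + 0) / 2)
  expect_equal(m0$recall, (1 + 0) / 2)
})

test_that("macro metrics are invariant under class relabeling", {
  set.seed(5)
  truth <- sample(c("x", "y", "z"), 60, replace = TRUE)
  pred <- sample(c("x", "y", "z"), 60, replace = TRUE)
  m1 <- classification_metrics(truth, pred)
  relab <- c(x = "z", y = "x", z = "y")
  m2 <- classification_metrics(relab[truth], relab[pred])
  expect_equal(m1, m2)
})

test_that("repeated CV reports pooled accuracy consistent with a per-sample tally", {
  toy <- make_separable_toy(40, 6, seed = 8)
  ds <- minmax_normalize(toy$dataset)
  rep1 <- repeated_cv_evaluate(ds, feature_ids = "g1", classifier = "svm",
                               repeats = 3, folds = 5, seed = 4)
  expect_equal(rep1$acc, 100)
  expect_equal(rep1$sd, 0)  # all repeats equal
  expect_true(all(rep1$per_repeat$acc == 1))
  # report means lie within [min, max] of per-repeat values
  syn <- make_synthetic_expression(60, 20, 2, shift = 1, seed = 9)
  nds <- minmax_normalize(impute_missing_mean(syn$dataset))
  rep2 <- repeated_cv_evaluate(nds, classifier = "dt", repeats = 4,
                               folds = 5, seed = 6)
  expect_gte(rep2$acc / 100, min(rep2$per_repeat$acc))
  expect_lte(rep2$acc / 100, max(rep2$per_repeat$acc))
  expect_gte(rep2$sd, 0)
})

test_that("every classifier reaches 100 on a gene that encodes the label", {
  toy <- make_separable_toy(30, 8, seed = 10)
  ds <- minmax_normalize(toy$dataset)
  for (cl in c("dt", "svm", "lr")) {
    r <- repeated_cv_evaluate(ds, feature_ids = "g1", classifier = cl,
                              repeats = 2, folds = 5, seed = 1)
    expect_equal(r$acc, 100)
    expect_equal(r$f1, 100)
  }
  expect_error(repeated_cv_evaluate(ds, feature_ids = "nope",
                                    classifier = "svm"), "unknown feature")
})

test_that("optimal-subset selection applies accuracy, size, then frequency", {
  cand <- function(ids, acc, run) {
    list(feature_ids = ids, accuracy = acc, source_run = run)
  }
  # rules 1-2: same accuracy prefers the smaller subset
  got <- select_optimal_subset(list(cand(letters[1:5], 95, 1),
                                    cand(letters[1:3], 95, 2),
                                    cand(letters[1:2], 90, 3)))
  expect_equal(got$feature_ids, letters[1:3])
  # single candidate: itself
  single <- cand("a", 80, 1)
  expect_equal(select_optimal_subset(list(single))$feature_ids, "a")
  # rule 3: same accuracy and size prefers the more frequent set
  got3 <- select_optimal_subset(list(cand(c("a", "b"), 95, 1),
                                     cand(c("c", "d"), 95, 2),
                                     cand(c("c", "d"), 95, 3),
                                     cand(c("c", "d"), 95, 4)))
  expect_setequal(got3$feature_ids, c("c", "d"))
  # residual tie: earliest run
  got4 <- select_optimal_subset(list(cand(c("x", "y"), 95, 2),
                                     cand(c("p", "q"), 95, 1)))
  expect_equal(got4$source_run, 1)
  expect_error(select_optimal_subset(list()), "empty")
  audit <- attr(got3, "audit")
  expect_equal(nrow(audit), 4)
  expect_true(all(c("accuracy", "size", "frequency") %in% names(audit)))
})
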