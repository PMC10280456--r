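test_that("a small samples-in-rows CSV parses with auto-detected label column", {
  path <- write_tiny_csv(withr::local_tempfile(fileext = ".csv"))
  ds <- read_expression_table(path)
  expect_s3_class(ds, "expression_dataset")
  expect_equal(dim(ds), c(3L, 2L))
  expect_equal(ds$feature_ids, c("g1", "g2"))
  expect_equal(as.character(ds$labels), c("a", "b", "a"))
  expect_equal(unname(ds$values[, 1]), c(1, 2, 3))
  expect_false(any(ds$missing_mask))
})

test_that("missing tokens are flagged in the mask, not altered silently", {
  path <- write_tiny_csv(withr::local_tempfile(fileext = ".csv"),
                         c("g1,g2,label", "1,NA,a", "2,5,b", ",6,a"))
  ds <- read_expression_table(path)
  expect_true(ds$missing_mask[1, 2])
  expect_true(ds$missing_mask[3, 1])
  expect_equal(sum(ds$missing_mask), 2L)
  expect_true(is.na(ds$values[1, 2]))
  expect_equal(unname(ds$values[2, 2]), 5)
})

test_that("reader rejects malformed inputs", {
  dup <- write_tiny_csv(withr::local_tempfile(fileext = ".csv"),
                        c("g1,g1,label", "1,2,a", "3,4,b"))
  expect_error(read_expression_table(dup), "duplicate")
  onecls <- write_tiny_csv(withr::local_tempfile(fileext = ".csv"),
                           c("g1,g2,label", "1,2,a", "3,4,a"))
  expect_error(read_expression_table(onecls), "2 distinct class")
  ragged <- write_tiny_csv(withr::local_tempfile(fileext = ".csv"),
                           c("g1,g2,label", "1,2,a", "3,4"))
  expect_error(read_expression_table(ragged))
  expect_error(read_expression_table(withr::local_tempfile(fileext = ".csv")),
               "not found")
  nolab <- write_tiny_csv(withr::local_tempfile(fileext = ".csv"),
                          c("g1,g2,g3", "1,2,a", "3,4,b"))
  expect_error(read_expression_table(nolab), "label")
})

test_that("genes-in-rows and samples-in-rows layouts round-trip identically", {
  ds <- random_dataset(6, 4, seed = 42)
  ds$values[2, 3] <- NA
  ds$missing_mask[2, 3] <- TRUE
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(ds, p1, orientation = "samples")
  write_expression_table(ds, p2, delimiter = "\t", orientation = "genes")
  a <- read_expression_table(p1, orientation = "samples")
  b <- read_expression_table(p2, delimiter = "\t", orientation = "genes")
  expect_equal(a$values, b$values)
  expect_equal(a$feature_ids, b$feature_ids)
  expect_equal(a$labels, b$labels)
  expect_equal(a$missing_mask, b$missing_mask)
  expect_equal(unname(a$values[1, ]), unname(ds$values[1, ]))
})

test_that("mean imputation fills absent entries with the gene mean and is idempotent", {
  vals <- cbind(c(1, NA, 3), c(2, 2, 2))
  ds <- expression_dataset(vals, c("a", "b", "a"), c("g1", "g2"))
  imp <- impute_missing_mean(ds)
  expect_equal(unname(imp$values[, 1]), c(1, 2, 3))
  expect_false(any(imp$missing_mask))
  # observed entries and per-gene means unchanged
  expect_equal(mean(imp$values[, 1]), mean(vals[, 1], na.rm = TRUE))
  expect_identical(impute_missing_mean(imp)$values, imp$values)
  # identity on a complete dataset
  full <- random_dataset(5, 3)
  expect_identical(impute_missing_mean(full)$values, full$values)
})

test_that("imputation errors on an all-absent gene", {
  vals <- cbind(c(NA, NA, NA), c(1, 2, 3))
  ds <- expression_dataset(vals, c("a", "b", "a"), c("g1", "g2"))
  expect_error(impute_missing_mean(ds), "no observed values")
})

test_that("min-max normalization forces [0,1] endpoints and zeroes constant genes", {
  ds <- expression_dataset(cbind(c(2, 4, 6), c(5, 5, 5)),
                           c("a", "b", "a"), c("g1", "g2"))
  nm <- minmax_normalize(ds)
  expect_equal(unname(nm$values[, 1]), c(0, 0.5, 1))
  expect_equal(unname(nm$values[, 2]), c(0, 0, 0))

  rnd <- random_dataset(6, 4, seed = 3)
  nr <- minmax_normalize(rnd)$values
  # independent per-column scan of the endpoints
  for (j in 1:4) {
    expect_equal(min(nr[, j]), 0)
    expect_equal(max(nr[, j]), 1)
  }
  # idempotent on normalized non-constant genes; order preserving
  expect_equal(minmax_normalize(minmax_normalize(rnd))$values, nr)
  for (j in 1:4) expect_equal(order(nr[, j]), order(rnd$values[, j]))
  # absent entries must be imputed first
  miss <- expression_dataset(cbind(c(1, NA), c(2, 3)), c("a", "b"))
  expect_error(minmax_normalize(miss), "absent")
})

test_that("gene lists and run reports round-trip through disk", {
  p <- withr::local_tempfile(fileext = ".txt")
  write_gene_list(c("33039_at", "41609_at"), p)
  expect_equal(readLines(p), c("33039_at", "41609_at"))
  expect_error(write_gene_list(character(0), p), "empty")

  rp <- withr::local_tempfile(fileext = ".json")
  result <- list(counts = c(raw = 10, selected = 2),
                 selected = list(feature_ids = c("g1", "g2"), fitness = 0.01),
                 seeds = list(global = 7))
  write_run_report(result, rp)
  back <- read_run_report(rp)
  expect_equal(back$selected$feature_ids, c("g1", "g2"))
  expect_equal(back$selected$fitness, 0.01)
  expect_equal(back$seeds$global, 7)
  expect_error(write_run_report(list(), rp), "empty")
})
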