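# Shared fixture builders for the test suite. Everything is generated in
# code; no data files are read.

# tiny 3-sample, 2-gene CSV with a label column
write_tiny_csv <- function(path, body = c("g1,g2,label",
                                          "1,4,a",
                                          "2,5,b",
                                          "3,6,a")) {
  writeLines(body, path)
  path
}

# brute-force per-gene population variance, independent of gene_variances()
brute_variances <- function(vals) {
  apply(vals, 2, function(v) mean((v - mean(v))^2))
}

# random small labeled dataset
random_dataset <- function(n = 20, p = 10, seed = 1) {
  set.seed(seed)
  expression_dataset(matrix(rnorm(n * p), n, p),
                     labels = rep(c("a", "b"), length.out = n))
}
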