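# Synthetic stand-ins for the eight public microarray benchmark collections
# commonly used to test gene-selection methods. The real collections (CNS,
# Leukemia, DLBCL, Prostate, Gastric2, ALL1, Ovarian, SRBCT) must be
# downloaded by the user; everything generated here is SYNTHETIC data that
# only reproduces each collection's shape (samples, class split, gene count)
# and attaches the published optimal probe subsets as ground-truth
# informative genes, so the fixed-subset evaluation protocol can be
# exercised without any download.

#' Shapes and published optimal subsets of the microarray benchmarks
#'
#' Metadata for eight widely used cancer microarray collections: sample
#' count per class, gene count, and the published optimal probe subset for
#' each (the gene sets reported to reach the best repeated-CV accuracy on
#' these collections).
#'
#' @return Named list; each element has `name`, `class_counts` (named
#'   integer vector), `n_genes`, and `reference_subset` (character vector of
#'   probe/feature IDs).
#' @export
microarray_benchmarks <- function() {
  list(
    CNS = list(name = "CNS", class_counts = c(c1 = 21, c2 = 39),
               n_genes = 7129,
               reference_subset = c("M22092_at", "M33521_at", "U28687_at",
                                    "U95740_rna1_at")),
    Leukemia = list(name = "Leukemia", class_counts = c(ALL = 47, AML = 25),
                    n_genes = 7129,
                    reference_subset = c("J05243_at", "M23197_at",
                                         "U79296_at", "U05259_rna1_at")),
    DLBCL = list(name = "DLBCL", class_counts = c(c1 = 58, c2 = 19),
                 n_genes = 7129,
                 reference_subset = c("AFFX-HUMGAPDH/M33197_5_st",
                                      "L42324_at", "L49209_s_at",
                                      "U00957_at", "X60955_s_at",
                                      "X67951_at", "U19495_s_at",
                                      "U89922_s_at")),
    Prostate = list(name = "Prostate", class_counts = c(c1 = 52, c2 = 50),
                    n_genes = 12625,
                    reference_subset = c("1060_g_at", "1315_at", "198_g_at",
                                         "31509_at", "32210_at", "32242_at",
                                         "33102_at")),
    Gastric2 = list(name = "Gastric2", class_counts = c(c1 = 62, c2 = 62),
                    n_genes = 22283,
                    reference_subset = c("396_f_at", "202726_at",
                                         "207392_x_at", "212353_at",
                                         "212462_at")),
    ALL1 = list(name = "ALL1", class_counts = c(c1 = 95, c2 = 33),
                n_genes = 12625,
                reference_subset = c("33039_at", "41609_at")),
    Ovarian = list(name = "Ovarian",
                   class_counts = c(Normal = 91, Cancer = 162),
                   n_genes = 15154,
                   reference_subset = c("MZ0.008796743", "MZ28.202695",
                                        "MZ244.95245", "MZ290.41236",
                                        "MZ554.4233", "MZ674.57738",
                                        "MZ4101.0731", "MZ8607.049")),
    SRBCT = list(name = "SRBCT",
                 class_counts = c(c1 = 29, c2 = 11, c3 = 18, c4 = 25),
                 n_genes = 2308,
                 reference_subset = c("gene3", "gene74", "gene246",
                                      "gene749", "gene836", "gene1084",
                                      "gene1093", "gene1210", "gene1389",
                                      "gene2186"))
  )
}

#' Synthetic stand-in for a microarray benchmark
#'
#' Generates a SYNTHETIC dataset with the same shape (samples, class split,
#' gene count) as one of the [microarray_benchmarks()] collections. The
#' published reference-subset probes are planted as strongly class-shifted
#' informative genes; all other genes are class-independent noise. This is
#' not the real collection: it exists so the fixed-subset evaluation
#' protocol has a same-shaped, separable input when the real data is not
#' on disk.
#'
#' @param name Benchmark name, one of `names(microarray_benchmarks())`.
#' @param shift Marker elevation of the planted genes in noise-SD units.
#'   Each planted gene is a marker for one class (classes are assigned
#'   cyclically over the reference subset); the default 6 makes the
#'   reference subset unambiguously separable by construction, as the
#'   published subsets are on the real collections.
#' @param missing_rate Fraction of entries masked missing (exercises the
#'   imputation path); default 0.01. Missing entries are injected only into
#'   noise genes, so the planted subset's signal stays intact, as measured
#'   marker values are on the real collections.
#' @param n_genes Override the gene count (smaller = faster); default the
#'   collection's true count.
#' @param seed Integer seed.
#' @return A list with `dataset` (an [expression_dataset]) and `truth`
#'   (`informative_indices`, `reference_subset`).
#' @export
make_synthetic_benchmark <- function(name, shift = 6, missing_rate = 0.01,
                                     n_genes = NULL, seed = 1) {
  bm <- microarray_benchmarks()[[name]]
  if (is.null(bm)) {
    stop("unknown benchmark '", name, "'; available: ",
         paste(names(microarray_benchmarks()), collapse = ", "))
  }
  if (is.null(n_genes)) n_genes <- bm$n_genes
  n_ref <- length(bm$reference_subset)
  stopifnot(n_genes >= n_ref)
  n_samples <- sum(bm$class_counts)
  n_classes <- length(bm$class_counts)

  set.seed(seed)
  labels <- factor(rep(names(bm$class_counts), bm$class_counts))
  vals <- matrix(stats::rnorm(n_samples * n_genes), n_samples, n_genes)
  informative <- sort(sample.int(n_genes, n_ref))
  # each planted gene is a marker elevated in one class (cyclic assignment)
  marker_class <- rep_len(seq_len(n_classes), n_ref)
  for (i in seq_len(n_ref)) {
    up <- as.integer(labels) == marker_class[i]
    vals[up, informative[i]] <- vals[up, informative[i]] + shift
  }
  feature_ids <- sprintf("p%05d", seq_len(n_genes))
  feature_ids[informative] <- bm$reference_subset
  missing <- matrix(FALSE, n_samples, n_genes)
  if (missing_rate > 0) {
    missing <- matrix(stats::runif(n_samples * n_genes) < missing_rate,
                      n_samples, n_genes)
    missing[, informative] <- FALSE  # planted markers stay fully observed
    # keep at least one observed value per gene
    all_gone <- colSums(!missing) == 0
    missing[1, all_gone] <- FALSE
    vals[missing] <- NA_real_
  }
  ds <- expression_dataset(vals, labels, feature_ids,
                           name = paste0(bm$name, "_synthetic"),
                           missing_mask = missing)
  list(dataset = ds,
       truth = list(informative_indices = informative,
                    reference_subset = bm$reference_subset))
}
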