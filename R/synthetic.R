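#' Generate a synthetic expression dataset with known informative genes
#'
#' Draws a samples-by-genes matrix in which a chosen set of informative genes
#' follows class-conditional normal distributions whose means are separated
#' by `shift * noise_sd` between consecutive classes, while all remaining
#' genes are class-independent Gaussian noise. Optionally masks entries as
#' missing uniformly at random. This is the minimal structure under which a
#' variance filter, a tree-importance gate and a KNN-accuracy fitness all
#' behave as intended, and it provides ground truth to score selections
#' against.
#'
#' @param n_samples Number of samples.
#' @param n_genes Total number of genes.
#' @param n_informative Number of informative (class-shifted) genes.
#' @param n_classes Number of classes (>= 2).
#' @param class_proportions Fractions summing to 1, one per class; default
#'   balanced.
#' @param shift Class-mean separation between consecutive classes, in units
#'   of `noise_sd`.
#' @param noise_sd Within-class standard deviation of every gene.
#' @param missing_rate Fraction of entries masked as absent, in [0, 1).
#' @param log_normal If `TRUE`, exponentiate the latent Gaussian values so
#'   intensities are log-normal (skewed, strictly positive), closer to raw
#'   microarray scale.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param name Dataset tag.
#'
#' @return A list with `dataset` (an [expression_dataset]) and `truth`, a
#'   list with `informative_indices` (column indices of the informative
#'   genes) and `class_means` (classes x informative genes matrix of
#'   class-conditional means on the latent scale).
#' @export
make_synthetic_expression <- function(n_samples, n_genes, n_informative,
                                      n_classes = 2,
                                      class_proportions = NULL,
                                      shift = 2, noise_sd = 1,
                                      missing_rate = 0,
                                      log_normal = FALSE,
                                      seed = 1, name = "synthetic") {
  stopifnot(n_samples >= n_classes, n_genes >= 1,
            n_informative >= 0, n_informative <= n_genes,
            n_classes >= 2, noise_sd > 0,
            missing_rate >= 0, missing_rate < 1)
  if (is.null(class_proportions)) {
    class_proportions <- rep(1 / n_classes, n_classes)
  }
  if (length(class_proportions) != n_classes ||
      any(class_proportions <= 0) ||
      abs(sum(class_proportions) - 1) > 1e-8) {
    stop("'class_proportions' must be ", n_classes,
         " positive fractions summing to 1")
  }

  set.seed(seed)
  # largest-remainder apportionment of samples to classes
  raw <- class_proportions * n_samples
  counts <- floor(raw)
  rem <- n_samples - sum(counts)
  if (rem > 0) {
    counts[order(raw - floor(raw), decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(raw - floor(raw), decreasing = TRUE)[seq_len(rem)]] + 1
  }
  if (any(counts == 0)) stop("a class received zero samples; increase n_samples")
  labels <- factor(rep(paste0("c", seq_len(n_classes)), counts))

  vals <- matrix(stats::rnorm(n_samples * n_genes, mean = 0, sd = noise_sd),
                 n_samples, n_genes)
  informative <- sort(sample.int(n_genes, n_informative))
  class_means <- matrix(0, n_classes, max(n_informative, 1),
                        dimnames = list(paste0("c", seq_len(n_classes)), NULL))
  if (n_informative > 0) {
    # class k mean offset: centred grid with spacing shift * noise_sd
    offsets <- (seq_len(n_classes) - (n_classes + 1) / 2) * shift * noise_sd
    class_means <- outer(offsets, rep(1, n_informative))
    for (k in seq_len(n_classes)) {
      rows <- which(as.integer(labels) == k)
      vals[rows, informative] <- vals[rows, informative] + offsets[k]
    }
  }
  if (log_normal) vals <- exp(vals)

  missing <- matrix(FALSE, n_samples, n_genes)
  if (missing_rate > 0) {
    missing <- matrix(stats::runif(n_samples * n_genes) < missing_rate,
                      n_samples, n_genes)
    vals[missing] <- NA_real_
  }
  ds <- expression_dataset(vals, labels,
                           feature_ids = paste0("g", seq_len(n_genes)),
                           name = name, missing_mask = missing)
  list(dataset = ds,
       truth = list(informative_indices = informative,
                    class_means = class_means))
}

#' Perfectly separable toy dataset
#'
#' Gene 1 is a noiseless numeric encoding of the class (0, 1, 2, ...); all
#' other genes are pure standard-normal noise. The canonical fixture on
#' which any reasonable classifier reaches 100% cross-validation accuracy
#' using gene 1 alone.
#'
#' @param n_samples Number of samples (split as evenly as possible across
#'   classes).
#' @param n_genes Total number of genes (>= 1).
#' @param n_classes Number of classes.
#' @param seed Integer seed.
#' @return A list with `dataset` and `truth` as in
#'   [make_synthetic_expression()]; the single informative index is 1.
#' @export
make_separable_toy <- function(n_samples = 40, n_genes = 20, n_classes = 2,
                               seed = 1) {
  stopifnot(n_genes >= 1, n_classes >= 2, n_samples >= n_classes)
  set.seed(seed)
  counts <- diff(round(seq(0, n_samples, length.out = n_classes + 1)))
  labels <- factor(rep(paste0("c", seq_len(n_classes)), counts))
  vals <- matrix(stats::rnorm(n_samples * n_genes), n_samples, n_genes)
  vals[, 1] <- as.integer(labels) - 1
  ds <- expression_dataset(vals, labels,
                           feature_ids = paste0("g", seq_len(n_genes)),
                           name = "separable_toy")
  list(dataset = ds,
       truth = list(informative_indices = 1L,
                    class_means = matrix(seq_len(n_classes) - 1, n_classes, 1)))
}
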