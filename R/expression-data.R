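#' Labeled expression dataset
#'
#' Constructs the container used throughout the package: a numeric
#' samples-by-genes matrix together with per-sample class labels, ordered
#' feature identifiers and a logical mask of missing entries.
#'
#' @param values Numeric matrix, samples in rows, genes in columns.
#' @param labels Vector of per-sample class identifiers (coerced to factor).
#' @param feature_ids Character vector of unique feature/probe identifiers,
#'   one per column of `values`. Defaults to the column names of `values`.
#' @param name Dataset tag used in printed output and reports.
#' @param missing_mask Logical matrix the same shape as `values`, `TRUE`
#'   where the entry is absent. Defaults to `is.na(values)`.
#'
#' @return An object of class `"expression_dataset"`: a list with elements
#'   `values`, `labels`, `feature_ids`, `name`, `missing_mask`.
#' @export
expression_dataset <- function(values, labels, feature_ids = colnames(values),
                               name = "dataset", missing_mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids)) {
    feature_ids <- paste0("g", seq_len(ncol(values)))
  }
  feature_ids <- as.character(feature_ids)
  labels <- factor(labels)
  names(labels) <- NULL
  rownames(values) <- NULL
  if (nrow(values) != length(labels)) {
    stop("number of rows of 'values' (", nrow(values),
         ") does not match number of labels (", length(labels), ")")
  }
  if (ncol(values) != length(feature_ids)) {
    stop("number of columns of 'values' does not match 'feature_ids'")
  }
  if (anyDuplicated(feature_ids)) {
    dup <- unique(feature_ids[duplicated(feature_ids)])
    stop("duplicate feature IDs: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (nlevels(labels) < 2) {
    stop("at least 2 distinct class labels are required, got ", nlevels(labels))
  }
  if (is.null(missing_mask)) {
    missing_mask <- is.na(values)
  } else {
    missing_mask <- as.matrix(missing_mask)
    if (!identical(dim(missing_mask), dim(values))) {
      stop("'missing_mask' must have the same dimensions as 'values'")
    }
  }
  colnames(values) <- feature_ids
  structure(
    list(values = values, labels = labels, feature_ids = feature_ids,
         name = as.character(name)[1], missing_mask = missing_mask),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("Expression dataset '", x$name, "': ",
      nrow(x$values), " samples x ", ncol(x$values), " genes, ",
      nlevels(x$labels), " classes (",
      paste(sprintf("%s:%d", levels(x$labels), tabulate(x$labels)),
            collapse = ", "), ")\n", sep = "")
  nm <- sum(x$missing_mask)
  if (nm > 0) cat("  ", nm, " missing entries\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Restrict a dataset to a subset of genes
#'
#' @param ds An [expression_dataset].
#' @param j Column indices or feature IDs to keep.
#' @return A new `expression_dataset` containing only the requested genes,
#'   in the requested order.
#' @export
subset_genes <- function(ds, j) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.character(j)) {
    idx <- match(j, ds$feature_ids)
    if (anyNA(idx)) {
      stop("unknown feature ID(s): ",
           paste(j[is.na(idx)], collapse = ", "))
    }
    j <- idx
  }
  if (length(j) == 0) stop("gene subset is empty")
  expression_dataset(ds$values[, j, drop = FALSE], ds$labels,
                     ds$feature_ids[j], ds$name,
                     ds$missing_mask[, j, drop = FALSE])
}

#' Read a delimited expression table
#'
#' Reads a CSV/TSV expression table into an [expression_dataset], handling
#' both layouts found in the wild: samples in rows (one column per gene plus
#' a class-label column) or genes in rows (one column per sample plus a
#' class-label row). Missing-value tokens are flagged in the missing mask,
#' not imputed; values are otherwise returned untouched.
#'
#' @param path Path to the delimited file, with a header line.
#' @param delimiter Field separator, default `","`.
#' @param orientation `"samples"` if samples are in rows (default) or
#'   `"genes"` if genes are in rows.
#' @param label_column Name (or, for the samples-in-rows layout, numeric
#'   index) of the class column/row. `NULL` auto-detects a column named
#'   `"label"` or `"class"` (case-insensitive).
#' @param missing_tokens Character strings treated as absent values.
#' @param name Dataset tag; defaults to the file name without extension.
#' @return An [expression_dataset] with orientation normalized to
#'   samples x genes.
#' @export
read_expression_table <- function(path, delimiter = ",",
                                  orientation = c("samples", "genes"),
                                  label_column = NULL,
                                  missing_tokens = c("", "NA", "na", "?", "null"),
                                  name = NULL) {
  orientation <- match.arg(orientation)
  if (!nzchar(delimiter)) stop("'delimiter' must be a nonempty string")
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))

  raw <- utils::read.table(path, sep = delimiter, header = FALSE,
                           colClasses = "character", fill = FALSE,
                           check.names = FALSE, quote = "\"",
                           na.strings = character(0),
                           comment.char = "", blank.lines.skip = TRUE)
  if (nrow(raw) < 2) stop("file has no data rows: ", path)

  if (orientation == "genes") {
    # first column holds feature IDs / the label-row name; header = sample IDs
    ids <- trimws(as.character(raw[-1, 1]))
    body <- t(as.matrix(raw[-1, -1, drop = FALSE]))
    lab_idx <- .resolve_label(ids, label_column)
    labels <- trimws(body[, lab_idx])
    values_chr <- body[, -lab_idx, drop = FALSE]
    feature_ids <- ids[-lab_idx]
  } else {
    header <- trimws(as.character(raw[1, ]))
    body <- as.matrix(raw[-1, , drop = FALSE])
    lab_idx <- .resolve_label(header, label_column)
    labels <- trimws(body[, lab_idx])
    values_chr <- body[, -lab_idx, drop = FALSE]
    feature_ids <- header[-lab_idx]
  }

  values_chr <- trimws(values_chr)
  missing <- matrix(values_chr %in% missing_tokens, nrow = nrow(values_chr))
  values <- suppressWarnings(array(as.numeric(values_chr), dim = dim(values_chr)))
  bad <- is.na(values) & !missing
  if (any(bad)) {
    stop("non-numeric entries that are not missing tokens, e.g. '",
         values_chr[which(bad)[1]], "'")
  }
  values[missing] <- NA_real_
  expression_dataset(values, labels, feature_ids, name, missing)
}

.resolve_label <- function(ids, label_column) {
  if (is.null(label_column)) {
    hit <- which(tolower(ids) %in% c("label", "class"))
    if (length(hit) == 0) {
      stop("no label column found: no header named 'label' or 'class'; ",
           "pass 'label_column' explicitly")
    }
    return(hit[1])
  }
  if (is.numeric(label_column)) {
    if (label_column < 1 || label_column > length(ids)) {
      stop("label column index out of range")
    }
    return(as.integer(label_column))
  }
  hit <- which(ids == label_column)
  if (length(hit) == 0) stop("label column '", label_column, "' not found")
  hit[1]
}

#' Write an expression table in the dialect the reader consumes
#'
#' @param ds An [expression_dataset].
#' @param path Output file path.
#' @param delimiter Field separator.
#' @param orientation `"samples"` (rows are samples) or `"genes"` (rows are
#'   genes, class labels in a `label` row).
#' @param missing_token Token written for absent entries.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(ds, path, delimiter = ",",
                                   orientation = c("samples", "genes"),
                                   missing_token = "NA") {
  stopifnot(inherits(ds, "expression_dataset"))
  orientation <- match.arg(orientation)
  vals <- ds$values
  chr <- matrix(format(vals, trim = TRUE, digits = 15), nrow = nrow(vals))
  chr[ds$missing_mask] <- missing_token
  if (orientation == "samples") {
    out <- rbind(c(ds$feature_ids, "label"),
                 cbind(chr, as.character(ds$labels)))
  } else {
    out <- cbind(c("id", ds$feature_ids, "label"),
                 rbind(paste0("s", seq_len(nrow(vals))), t(chr),
                       as.character(ds$labels)))
  }
  lines <- apply(out, 1, paste, collapse = delimiter)
  writeLines(lines, path)
  invisible(path)
}

#' Replace missing entries by per-gene means
#'
#' Mean substitution: each absent entry is replaced by the mean of the
#' observed values of the same gene, leaving observed entries and per-gene
#' means unchanged.
#'
#' @param ds An [expression_dataset].
#' @return The dataset with all entries observed and the missing mask cleared.
#' @export
impute_missing_mean <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  vals <- ds$values
  mask <- ds$missing_mask
  cols <- which(colSums(mask) > 0)
  for (j in cols) {
    obs <- vals[!mask[, j], j]
    if (length(obs) == 0) {
      stop("gene '", ds$feature_ids[j], "' has no observed values; ",
           "cannot impute")
    }
    vals[mask[, j], j] <- mean(obs)
  }
  expression_dataset(vals, ds$labels, ds$feature_ids, ds$name,
                     matrix(FALSE, nrow(vals), ncol(vals)))
}

#' Min-max normalize each gene to [0, 1]
#'
#' Rescales every gene by (x - min) / (max - min). Constant genes, for which
#' the denominator vanishes, map to all zeros; they carry no class signal and
#' are removed by the variance filter regardless.
#'
#' @param ds An [expression_dataset] with no absent entries (impute first).
#' @return The normalized dataset.
#' @export
minmax_normalize <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (any(ds$missing_mask)) {
    stop("dataset has absent entries; run impute_missing_mean() first")
  }
  vals <- ds$values
  mins <- apply(vals, 2, min)
  maxs <- apply(vals, 2, max)
  rng <- maxs - mins
  const <- rng == 0
  rng[const] <- 1
  vals <- sweep(sweep(vals, 2, mins, "-"), 2, rng, "/")
  vals[, const] <- 0
  expression_dataset(vals, ds$labels, ds$feature_ids, ds$name,
                     ds$missing_mask)
}

#' Write a selected gene subset as a plain-text list
#'
#' @param feature_ids Character vector of selected feature IDs (or a
#'   `gene_subset` object from the optimizer/pipeline).
#' @param path Output file path; one ID per line.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(feature_ids, path) {
  if (is.list(feature_ids) && !is.null(feature_ids$feature_ids)) {
    feature_ids <- feature_ids$feature_ids
  }
  feature_ids <- as.character(feature_ids)
  if (length(feature_ids) == 0) stop("gene subset is empty; nothing to write")
  writeLines(feature_ids, path)
  invisible(path)
}

#' Write a structured run report as JSON
#'
#' Serializes a run result (per-stage counts, per-classifier CV reports,
#' seeds, configuration echo) to JSON so a run can be audited or re-read.
#'
#' @param result A list-like run result (e.g. a fitted `"veh"` object).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(result, path) {
  if (is.null(result) || length(result) == 0) stop("empty result")
  x <- unclass(result)
  x$data <- NULL  # the expression matrix itself is not part of the report
  jsonlite::write_json(.jsonable(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, null = "null")
  invisible(path)
}

#' Read back a JSON run report
#'
#' @param path Path to a report written by [write_run_report()].
#' @return The deserialized report list.
#' @export
read_run_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# strip matrices/functions that do not belong in a JSON report
.jsonable <- function(x) {
  if (is.function(x)) return(NULL)
  if (is.factor(x)) return(as.character(x))
  if (is.matrix(x)) return(apply(x, 1, function(r) r, simplify = FALSE))
  if (is.list(x)) {
    out <- lapply(unclass(x), .jsonable)
    return(out[!vapply(out, is.null, logical(1))])
  }
  x
}
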