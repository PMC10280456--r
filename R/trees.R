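# Generic best-first CART-style tree grower.
#
# One grower serves two needs that no installed tree package covers with the
# exact constraints required here:
#   * extremely randomized trees (random uniform cut per candidate feature)
#     with n_estimators / min_samples_leaf / max_leaf_nodes all enforced;
#   * a decision-tree classifier with per-node random feature subsampling
#     (max_features) and a depth cap.
# Growth is best-first: the splittable leaf with the largest weighted Gini
# decrease is expanded next, so a max_leaf_nodes budget is spent where it
# buys the most purity.

.gini <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

# Best split of one node. Returns NULL when no valid split exists.
# splitter "random": one uniform cut per candidate feature (extra-trees);
# splitter "best": exhaustive scan of midpoints per candidate feature.
.node_split <- function(x, y, idx, K, n_total, splitter, max_features,
                        min_samples_leaf) {
  n <- length(idx)
  if (n < 2 * min_samples_leaf) return(NULL)
  yk <- y[idx]
  counts <- tabulate(yk, K)
  g0 <- .gini(counts)
  if (g0 <= 0) return(NULL)
  p <- ncol(x)
  feats <- if (max_features >= p) seq_len(p) else sample.int(p, max_features)
  w <- n / n_total
  best <- NULL
  for (j in feats) {
    v <- x[idx, j]
    vmin <- min(v); vmax <- max(v)
    if (vmin == vmax) next
    if (splitter == "random") {
      thr <- stats::runif(1, vmin, vmax)
      left <- v <= thr
      nl <- sum(left); nr <- n - nl
      if (nl < min_samples_leaf || nr < min_samples_leaf) next
      cl <- tabulate(yk[left], K)
      dec <- w * (g0 - (nl / n) * .gini(cl) - (nr / n) * .gini(counts - cl))
      if (dec > 1e-12 && (is.null(best) || dec > best$decrease)) {
        best <- list(feature = j, threshold = thr, decrease = dec, left = left)
      }
    } else {
      o <- order(v)
      vs <- v[o]
      cc <- vapply(seq_len(K), function(k) cumsum(yk[o] == k),
                   numeric(n))  # n x K cumulative class counts
      i <- seq_len(n - 1)
      ok <- vs[i] < vs[i + 1] & i >= min_samples_leaf &
        (n - i) >= min_samples_leaf
      if (!any(ok)) next
      i <- i[ok]
      ccl <- cc[i, , drop = FALSE]
      ccr <- matrix(counts, length(i), K, byrow = TRUE) - ccl
      gl <- 1 - rowSums((ccl / i)^2)
      gr <- 1 - rowSums((ccr / (n - i))^2)
      dec <- w * (g0 - (i / n) * gl - ((n - i) / n) * gr)
      b <- which.max(dec)
      if (dec[b] > 1e-12 && (is.null(best) || dec[b] > best$decrease)) {
        thr <- (vs[i[b]] + vs[i[b] + 1]) / 2
        best <- list(feature = j, threshold = thr, decrease = dec[b],
                     left = v <= thr)
      }
    }
  }
  best
}

# Grow a single classification tree. x: numeric matrix; y: integer classes
# 1..K. Returns a flat node table plus the per-feature impurity-decrease
# importance (unnormalized).
grow_tree <- function(x, y, K = max(y), splitter = c("random", "best"),
                      max_features = ncol(x), min_samples_leaf = 1,
                      max_leaf_nodes = Inf, max_depth = Inf) {
  splitter <- match.arg(splitter)
  stopifnot(nrow(x) == length(y), min_samples_leaf >= 1,
            max_leaf_nodes >= 2 || is.infinite(max_leaf_nodes) ||
              max_leaf_nodes >= 1)
  n_total <- nrow(x)
  nodes <- list(list(counts = tabulate(y, K), depth = 0L,
                     feature = NA_integer_, threshold = NA_real_,
                     left = NA_integer_, right = NA_integer_))
  node_idx <- list(seq_len(n_total))
  importance <- numeric(ncol(x))
  frontier <- list()  # candidate splits keyed by node id

  push <- function(id) {
    nd <- nodes[[id]]
    if (nd$depth >= max_depth) return()
    sp <- .node_split(x, y, node_idx[[id]], K, n_total, splitter,
                      max_features, min_samples_leaf)
    if (!is.null(sp)) frontier[[as.character(id)]] <<- c(sp, node = id)
  }
  push(1L)
  n_leaves <- 1L
  while (length(frontier) > 0 && n_leaves < max_leaf_nodes) {
    decs <- vapply(frontier, function(f) f$decrease, numeric(1))
    key <- names(frontier)[which.max(decs)]
    sp <- frontier[[key]]
    frontier[[key]] <- NULL
    id <- sp$node
    idx <- node_idx[[id]]
    li <- idx[sp$left]; ri <- idx[!sp$left]
    nodes[[id]]$feature <- sp$feature
    nodes[[id]]$threshold <- sp$threshold
    lid <- length(nodes) + 1L; rid <- lid + 1L
    nodes[[id]]$left <- lid; nodes[[id]]$right <- rid
    d <- nodes[[id]]$depth + 1L
    nodes[[lid]] <- list(counts = tabulate(y[li], K), depth = d,
                         feature = NA_integer_, threshold = NA_real_,
                         left = NA_integer_, right = NA_integer_)
    nodes[[rid]] <- list(counts = tabulate(y[ri], K), depth = d,
                         feature = NA_integer_, threshold = NA_real_,
                         left = NA_integer_, right = NA_integer_)
    node_idx[[lid]] <- li; node_idx[[rid]] <- ri
    importance[sp$feature] <- importance[sp$feature] + sp$decrease
    n_leaves <- n_leaves + 1L
    push(lid); push(rid)
  }
  list(nodes = nodes, importance = importance, n_classes = K)
}

# Route samples down a tree; returns the majority class index of the
# reached leaf (ties -> lowest class index).
predict_tree <- function(tree, x) {
  nodes <- tree$nodes
  out <- integer(nrow(x))
  for (s in seq_len(nrow(x))) {
    id <- 1L
    while (!is.na(nodes[[id]]$feature)) {
      id <- if (x[s, nodes[[id]]$feature] <= nodes[[id]]$threshold) {
        nodes[[id]]$left
      } else {
        nodes[[id]]$right
      }
    }
    out[s] <- which.max(nodes[[id]]$counts)
  }
  out
}
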