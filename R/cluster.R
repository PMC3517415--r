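# Clustering protocol: zero replacement, repeated median centering and
# sum-of-squares row normalization, and centroid-linkage hierarchical
# clustering of genes and of stages.

#' Replace exact zeros by a small positive value
#'
#' Undetected genes carry expression 0, which means "below detection", not
#' "absent"; zeros are exchanged for a small floor value before the
#' log-free centering protocol. Idempotent; non-zero values are untouched.
#'
#' @param m numeric matrix.
#' @param eps replacement value (> 0), default 0.0002.
#' @return The matrix with zeros replaced.
#' @export
replace_zeros <- function(m, eps = 0.0002) {
  if (eps <= 0) stop_param("eps must be positive")
  m[m == 0] <- eps
  m
}

#' Median-center and sum-of-squares normalize rows
#'
#' Applies `center_passes` rounds of row median subtraction followed by
#' `norm_passes` rounds of row scaling to unit sum of squares, after which
#' every row has median 0 and sum of squares 1 (the scaling preserves a
#' zero median, so the combination is a fixed point). A constant row
#' becomes all-zero under centering and cannot be normalized; such rows are
#' dropped with a warning.
#'
#' @param m numeric matrix (genes as rows).
#' @param center_passes number of median-centering passes (default 3).
#' @param norm_passes number of normalization passes (default 5).
#' @return The processed matrix (possibly with fewer rows).
#' @export
center_and_normalize <- function(m, center_passes = 3, norm_passes = 5) {
  for (i in seq_len(center_passes))
    m <- m - apply(m, 1, median)
  ss <- rowSums(m^2)
  if (any(ss == 0)) {
    warning("dropping ", sum(ss == 0),
            " constant row(s) that cannot be normalized: ",
            paste(utils::head(rownames(m)[ss == 0], 5), collapse = ", "))
    m <- m[ss > 0, , drop = FALSE]
  }
  for (i in seq_len(norm_passes))
    m <- m / sqrt(rowSums(m^2))
  m
}

# distance from one profile to each row of a profile matrix
.profile_dist <- function(metric, x, M) {
  switch(metric,
    pearson = {
      xc <- x - mean(x)
      Mc <- M - rowMeans(M)
      1 - as.vector(Mc %*% xc) / sqrt(sum(xc^2) * rowSums(Mc^2))
    },
    uncentered = 1 - as.vector(M %*% x) / sqrt(sum(x^2) * rowSums(M^2)),
    euclidean = sqrt(rowSums(sweep(M, 2, x)^2))
  )
}

#' Centroid-linkage hierarchical clustering
#'
#' Agglomerative clustering in which the distance between two clusters is
#' the distance between their centroids (the arithmetic mean of their
#' members' profiles, recomputed after every merge). At each step the pair
#' of clusters with the most similar centroids is merged; exact distance
#' ties are broken by the smallest pair of original item indices. Under
#' centroid linkage merge heights may invert (a later merge lower than an
#' earlier one); inversions are returned as-is.
#'
#' @param m numeric matrix of processed profiles.
#' @param axis `"rows"` (default, cluster genes) or `"cols"` (cluster
#'   stages).
#' @param metric `"pearson"` (centered correlation distance `1 - r`, the
#'   default), `"uncentered"` (uncentered correlation distance) or
#'   `"euclidean"`.
#' @return An object of class `hclust` (merge matrix, heights, leaf order
#'   per [leaf_order()], labels, `method = "centroid"`).
#' @export
centroid_hclust <- function(m, axis = c("rows", "cols"),
                            metric = c("pearson", "uncentered", "euclidean")) {
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  if (axis == "cols") m <- t(m)
  n <- nrow(m)
  if (n < 2) stop_param("need at least 2 items to cluster")

  members <- as.list(seq_len(n))
  node <- -seq_len(n)
  minleaf <- seq_len(n)
  active <- rep(TRUE, n)
  centroids <- m
  D <- matrix(Inf, n, n)
  for (i in seq_len(n - 1)) {
    d <- .profile_dist(metric, m[i, ], m[(i + 1):n, , drop = FALSE])
    D[i, (i + 1):n] <- d
  }

  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (s in seq_len(n - 1)) {
    dmin <- min(D)
    idx <- which(D == dmin, arr.ind = TRUE)
    key1 <- pmin(minleaf[idx[, 1]], minleaf[idx[, 2]])
    key2 <- pmax(minleaf[idx[, 1]], minleaf[idx[, 2]])
    pick <- order(key1, key2)[1]
    i <- idx[pick, 1]; j <- idx[pick, 2]

    merge[s, ] <- sort(c(node[i], node[j]))
    height[s] <- D[i, j]
    members[[i]] <- c(members[[i]], members[[j]])
    minleaf[i] <- min(minleaf[i], minleaf[j])
    node[i] <- s
    active[j] <- FALSE
    D[j, ] <- Inf
    D[, j] <- Inf
    centroids[i, ] <- colMeans(m[members[[i]], , drop = FALSE])

    others <- which(active & seq_len(n) != i)
    if (length(others)) {
      d <- .profile_dist(metric, centroids[i, ],
                         centroids[others, , drop = FALSE])
      D[pmin(i, others) + n * (pmax(i, others) - 1)] <- d
    }
  }

  ord <- .tree_order(merge, height)
  structure(list(merge = merge, height = height, order = ord,
                 labels = rownames(m), method = "centroid",
                 dist.method = metric, call = match.call()),
            class = "hclust")
}

# recursive leaf ordering: tighter-merging (lower) subtree first, leaves
# (height 0) before internal nodes at equal height, ties by smallest leaf id
.tree_order <- function(merge, height) {
  n <- nrow(merge) + 1L
  info <- function(code) {
    if (code < 0) list(leaves = -code, h = 0, id = -code)
    else {
      a <- info(merge[code, 1]); b <- info(merge[code, 2])
      first_a <- a$h < b$h || (a$h == b$h && a$id <= b$id)
      leaves <- if (first_a) c(a$leaves, b$leaves) else c(b$leaves, a$leaves)
      list(leaves = leaves, h = height[code], id = min(a$id, b$id))
    }
  }
  info(n - 1L)$leaves
}

#' Leaf order of a clustering tree
#'
#' The displayed leaf permutation: at every internal node the subtree that
#' merged more tightly (lower height) is placed first, with ties broken by
#' the smallest original item index.
#'
#' @param tree an `hclust` object from [centroid_hclust()].
#' @return Integer permutation of the leaves.
#' @export
leaf_order <- function(tree) .tree_order(tree$merge, tree$height)

#' Cluster a candidate expression matrix end to end
#'
#' Runs the full protocol: zero replacement, median centering (3 passes),
#' row sum-of-squares normalization (5 passes), then centroid-linkage
#' clustering of the genes and of the stages.
#'
#' @param expr candidate genes x stages expression matrix.
#' @param metric clustering metric, see [centroid_hclust()].
#' @param eps zero replacement value.
#' @param center_passes,norm_passes processing passes.
#' @return A list of class `cluster_model`: `processed` matrix, `row_tree`,
#'   `col_tree`, and the `ordered` matrix (leaf orders applied).
#' @export
cluster_expression <- function(expr, metric = "pearson", eps = 0.0002,
                               center_passes = 3, norm_passes = 5) {
  proc <- center_and_normalize(replace_zeros(expr, eps),
                               center_passes, norm_passes)
  row_tree <- centroid_hclust(proc, "rows", metric)
  col_tree <- centroid_hclust(proc, "cols", metric)
  ordered <- proc[row_tree$order, col_tree$order, drop = FALSE]
  structure(list(processed = proc, row_tree = row_tree,
                 col_tree = col_tree, ordered = ordered),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: %d genes x %d stages (centroid linkage, %s)\n",
              nrow(x$processed), ncol(x$processed),
              x$row_tree$dist.method))
  invisible(x)
}

#' Rand index between two partitions
#'
#' Fraction of item pairs on which two labelings agree (same cluster in
#' both, or different in both).
#'
#' @param a,b cluster label vectors of equal length.
#' @return The Rand index in [0, 1].
#' @export
rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_param("label vectors differ in length")
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}
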