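# Naive brute-force centroid-linkage oracle, written independently of the
# package implementation: full O(n^3) recomputation of all centroid
# distances at every step, same tie-break contract (smallest pair of
# original item indices).

oracle_dist <- function(a, b, metric) {
  if (metric == "pearson") {
    1 - stats::cor(a, b)
  } else if (metric == "uncentered") {
    1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  } else {
    sqrt(sum((a - b)^2))
  }
}

oracle_centroid_hclust <- function(m, metric = "pearson") {
  n <- nrow(m)
  clusters <- lapply(seq_len(n), identity)
  codes <- -seq_len(n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        ci <- colMeans(m[clusters[[i]], , drop = FALSE])
        cj <- colMeans(m[clusters[[j]], , drop = FALSE])
        d <- oracle_dist(ci, cj, metric)
        id1 <- min(min(clusters[[i]]), min(clusters[[j]]))
        id2 <- max(min(clusters[[i]]), min(clusters[[j]]))
        better <- is.null(best) || d < best$d ||
          (d == best$d && (id1 < best$id1 ||
                           (id1 == best$id1 && id2 < best$id2)))
        if (better) best <- list(d = d, i = i, j = j, id1 = id1, id2 = id2)
      }
    }
    merge[s, ] <- sort(c(codes[best$i], codes[best$j]))
    height[s] <- best$d
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    codes[best$i] <- s
    clusters[[best$j]] <- NULL
    codes <- codes[-best$j]
  }
  list(merge = merge, height = height)
}
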