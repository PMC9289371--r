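#' Binary detection-pattern distance between two cells
#'
#' `sum_j (sign(x_j) - sign(y_j))^2` over the m genes, where `sign` is 1
#' iff the gene's expression is > 0 — the Hamming distance between the two
#' cells' detection patterns. Lower values mean more similar cells (the
#' quantity is a dissimilarity despite being used as a "similarity"
#' score).
#'
#' @param x,y equal-length expression vectors (raw counts; any positive
#'   value counts as detected).
#' @return non-negative integer distance.
#' @export
binary_distance <- function(x, y) {
  if (length(x) != length(y)) {
    abort(sprintf("length mismatch: %d vs %d genes", length(x), length(y)))
  }
  sum((as.integer(x > 0) - as.integer(y > 0))^2)
}

#' Subsampled pairwise cluster similarity
#'
#' Draws `n_pairs` cells from each cluster (with replacement when a
#' cluster has fewer cells), pairs them positionally, and averages the
#' binary detection-pattern distance — the Monte-Carlo estimate of the
#' expected cell-cell distance between the clusters. Also reported
#' normalized by the gene count m for cross-dataset comparability (an
#' addition to the raw mean, labeled as such).
#'
#' @param x a [count_matrix()].
#' @param cells_x,cells_y non-empty cell index/logical selectors for the
#'   two clusters.
#' @param n_pairs number of sampled pairs (default 1,000).
#' @param seed integer seed.
#' @return tibble with `mean_distance`, `normalized_distance`
#'   (`mean / m`), `n_pairs`, `m`.
#' @export
cluster_similarity <- function(x, cells_x, cells_y, n_pairs = 1000, seed = 1L) {
  stopifnot(inherits(x, "count_matrix"))
  ix <- seq_len(ncol(x$counts))[cells_x]
  iy <- seq_len(ncol(x$counts))[cells_y]
  if (length(ix) == 0 || length(iy) == 0) abort("both clusters must be non-empty")
  det <- x$counts > 0
  with_local_seed(seed, {
    sx <- if (length(ix) >= n_pairs) sample(ix, n_pairs) else
      sample(ix, n_pairs, replace = TRUE)
    sy <- if (length(iy) >= n_pairs) sample(iy, n_pairs) else
      sample(iy, n_pairs, replace = TRUE)
    dx <- det[, sx, drop = FALSE]
    dy <- det[, sy, drop = FALSE]
    dists <- Matrix::colSums(dx + dy == 1)     # XOR of detection patterns
    tibble(mean_distance = mean(dists),
           normalized_distance = mean(dists) / nrow(x$counts),
           n_pairs = n_pairs, m = nrow(x$counts))
  })
}

#' All-pairs cluster-similarity matrix
#'
#' [cluster_similarity()] for every pair of cluster labels, returned long.
#'
#' @param x a [count_matrix()].
#' @param labels per-cell cluster labels (0 = noise, skipped).
#' @param n_pairs,seed passed to [cluster_similarity()].
#' @return tibble `cluster_x`, `cluster_y`, `mean_distance`,
#'   `normalized_distance`.
#' @export
similarity_matrix <- function(x, labels, n_pairs = 1000, seed = 1L) {
  ids <- sort(unique(labels[labels != 0]))
  pairs <- expand.grid(a = ids, b = ids)
  pairs <- pairs[pairs$a <= pairs$b, ]
  purrr::pmap_dfr(pairs, function(a, b) {
    res <- cluster_similarity(x, labels == a, labels == b, n_pairs,
                              seed = seed + a * 1000L + b)
    tibble(cluster_x = a, cluster_y = b,
           mean_distance = res$mean_distance,
           normalized_distance = res$normalized_distance)
  })
}
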