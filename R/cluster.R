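#' Density-clustering parameters
#'
#' Defaults mirror the pipeline's settings: `minpts = 30` (also used as the
#' UMAP `n_neighbors`) and `epsilon = 0.3` (also the UMAP `min_dist`).
#' Clustering runs on the 2-D projected coordinates by default; the 10-D
#' embedding is retained as an option for sensitivity checks.
#'
#' @param minpts DBSCAN core-point neighborhood size (>= 2).
#' @param epsilon DBSCAN neighborhood radius (> 0).
#' @param cluster_space `"2d"` (projected coordinates) or `"10d"`
#'   (embedding).
#' @return a `cluster_params` list.
#' @export
cluster_params <- function(minpts = 30, epsilon = 0.3,
                           cluster_space = c("2d", "10d")) {
  cluster_space <- match.arg(cluster_space)
  if (minpts < 2) stop_field("minpts", "must be >= 2")
  if (!is.finite(epsilon) || epsilon <= 0) stop_field("epsilon", "must be > 0")
  structure(list(minpts = minpts, epsilon = epsilon,
                 cluster_space = cluster_space),
            class = "cluster_params")
}

#' Project an embedding to two dimensions with UMAP
#'
#' Seeded uniform-manifold projection of the cells x 10 embedding to 2-D
#' for visualization and density clustering. Neighborhood preservation is
#' measured by a trustworthiness score (on a subsample when the dataset is
#' large) and attached as the `"trustworthiness"` attribute.
#'
#' @param embedding cells x d matrix.
#' @param n_neighbors UMAP neighborhood size (default 30, matching
#'   `minpts`).
#' @param min_dist UMAP minimum embedding distance (default 0.3).
#' @param seed integer seed; identical seeds give identical layouts.
#' @return cells x 2 coordinate matrix.
#' @export
project_2d <- function(embedding, n_neighbors = 30, min_dist = 0.3, seed = 1L) {
  embedding <- as.matrix(embedding)
  if (!all(is.finite(embedding))) abort("embedding must be finite")
  if (nrow(embedding) <= n_neighbors) {
    abort(sprintf("need more than n_neighbors = %d cells, got %d",
                  n_neighbors, nrow(embedding)))
  }
  # identical cells must map to identical coordinates: run the layout on
  # unique rows and broadcast
  key <- apply(embedding, 1, paste, collapse = "\r")
  first <- match(key, key)
  uniq <- which(first == seq_along(key))
  coords_u <- with_local_seed(seed, {
    uwot::umap(embedding[uniq, , drop = FALSE], n_neighbors = n_neighbors,
               min_dist = min_dist, n_threads = 1, n_sgd_threads = 1,
               batch = TRUE)
  })
  coords <- coords_u[match(first, uniq), , drop = FALSE]
  rownames(coords) <- rownames(embedding)
  attr(coords, "trustworthiness") <- trustworthiness(embedding, coords)
  coords
}

# trustworthiness of a projection: penalizes points entering a 2-D
# neighborhood that were far in the original space (1 = perfect)
trustworthiness <- function(X, Y, k = 10, max_n = 1000) {
  n <- nrow(X)
  idx <- if (n > max_n) sort(sample.int(n, max_n)) else seq_len(n)
  X <- X[idx, , drop = FALSE]; Y <- Y[idx, , drop = FALSE]
  n <- nrow(X)
  dx <- as.matrix(stats::dist(X)); dy <- as.matrix(stats::dist(Y))
  penalty <- 0
  for (i in seq_len(n)) {
    rank_x <- rank(dx[i, ], ties.method = "first") - 1  # self has rank 0
    nn_y <- order(dy[i, ])[2:(k + 1)]
    r <- rank_x[nn_y]
    penalty <- penalty + sum(pmax(r - k, 0))
  }
  1 - 2 / (n * k * (2 * n - 3 * k - 1)) * penalty
}

#' k-distance curve and elbow epsilon
#'
#' For each point, the distance to its k-th nearest neighbor is computed;
#' the sorted curve's elbow — the point at maximum distance from the chord
#' joining the curve's endpoints, an automated stand-in for reading the
#' bend off the plotted curve — is returned as the suggested DBSCAN
#' epsilon. A flat curve (weak elbow) is flagged rather than trusted.
#'
#' @param points cells x d coordinate matrix.
#' @param k neighbor rank (default 30, the `minpts` convention).
#' @return a `kdist_curve`: list with `curve` (tibble `rank`, `kdist`,
#'   ascending), `epsilon`, `k`, and `weak` (logical elbow-quality flag).
#' @export
estimate_epsilon <- function(points, k = 30) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < k + 1) abort(sprintf("need at least k + 1 = %d points", k + 1))
  d <- as.matrix(stats::dist(points))
  kdist <- apply(d, 1, function(r) sort(r, partial = k + 1)[k + 1])
  curve <- sort(kdist)
  rng <- diff(range(curve))
  if (rng == 0) {
    warn("all k-distances identical; epsilon is degenerate")
    eps <- curve[1]
    weak <- TRUE
    elbow_at <- n
  } else {
    # distance from each curve point to the chord between the endpoints
    xs <- (seq_len(n) - 1) / (n - 1)
    ys <- (curve - curve[1]) / rng
    chord <- xs * (ys[n] - ys[1]) + ys[1]       # ys[1]=0, ys[n]=1
    dev <- abs(ys - chord) / sqrt(2)
    elbow_at <- which.max(dev)
    eps <- curve[elbow_at]
    # a nearly flat curve has no density transition to read off
    weak <- rng / max(stats::median(curve), .Machine$double.eps) < 0.1 ||
      max(dev) < 0.05
  }
  structure(
    list(curve = tibble(rank = seq_len(n), kdist = curve),
         epsilon = unname(eps), k = k, weak = weak, elbow_rank = elbow_at),
    class = "kdist_curve"
  )
}

#' Density-based clustering (DBSCAN)
#'
#' Classic DBSCAN semantics: a core point has at least `minpts` neighbors
#' (itself included) within `epsilon`; clusters are the connected
#' components of core points, grown in point-index order; non-core points
#' within `epsilon` of a core point are attached as border points —
#' a border point reachable from several clusters goes to the
#' lowest-numbered one (the documented tie rule); the remainder is noise
#' (label 0).
#'
#' @param points cells x d coordinate matrix.
#' @param params a [cluster_params()].
#' @return integer vector of cluster labels, 0 = noise.
#' @export
density_cluster <- function(points, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  points <- as.matrix(points)
  if (!all(is.finite(points))) abort("points must be finite")
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= params$epsilon))
  core <- vapply(nb, length, integer(1)) >= params$minpts

  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    head <- 1L
    while (head <= length(queue)) {
      p <- queue[head]; head <- head + 1L
      fresh <- nb[[p]][core[nb[[p]]] & labels[nb[[p]]] == 0L]
      if (length(fresh) > 0) {
        labels[fresh] <- cl
        queue <- c(queue, fresh)
      }
    }
  }
  # border points: lowest-numbered cluster among core neighbors
  for (i in seq_len(n)) {
    if (core[i]) next
    cand <- labels[nb[[i]][core[nb[[i]]]]]
    if (length(cand) > 0) labels[i] <- min(cand)
  }
  labels
}

#' Cluster-by-group composition table
#'
#' Proportion of each sample group's cells falling in each cluster; noise
#' (label 0) is reported as its own row. Within every group the
#' proportions sum to 1.
#'
#' @param labels per-cell cluster labels (0 = noise).
#' @param groups per-cell sample-group labels, same length.
#' @return tibble with `cluster`, `group`, `n_cells`, `proportion`, and
#'   `percent` (proportion x 100, rounded half away from zero to 2
#'   decimals).
#' @export
composition_table <- function(labels, groups) {
  if (length(labels) != length(groups)) abort("labels and groups must align")
  if (length(labels) == 0) abort("no cells given")
  cluster <- ifelse(labels == 0, "noise", as.character(labels))
  tab <- tibble(cluster = cluster, group = as.character(groups)) |>
    dplyr::count(.data$cluster, .data$group, name = "n_cells") |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(proportion = .data$n_cells / sum(.data$n_cells)) |>
    dplyr::ungroup() |>
    dplyr::mutate(percent = round_half_up(100 * .data$proportion, 2)) |>
    dplyr::arrange(.data$cluster, .data$group)
  tab
}

#' Merge clusters with matching group-composition profiles
#'
#' Repeatedly merges the pair of clusters whose group-composition vectors
#' are mutually nearest under cosine similarity and exceed `threshold`,
#' emulating the manual consolidation of over-split density clusters by
#' their sample-group localization. The merge log is attached as the
#' `"merge_log"` attribute.
#'
#' @param labels per-cell cluster labels (0 = noise, never merged).
#' @param groups per-cell sample-group labels.
#' @param threshold cosine-similarity threshold for merging.
#' @return relabeled integer vector (consecutive labels, 0 preserved).
#' @export
merge_clusters_by_group_profile <- function(labels, groups, threshold = 0.95) {
  if (length(unique(labels[labels != 0])) < 2) {
    abort("need at least 2 clusters to merge")
  }
  labels <- as.integer(labels)
  log <- list()
  repeat {
    ids <- sort(unique(labels[labels != 0]))
    if (length(ids) < 2) break
    comp <- vapply(ids, function(k) {
      tabulate(factor(groups[labels == k], levels = sort(unique(groups))),
               nbins = length(unique(groups)))
    }, numeric(length(unique(groups))))
    comp <- matrix(comp, ncol = length(ids))
    sims <- cosine_sim(comp)
    diag(sims) <- -Inf
    nearest <- apply(sims, 2, which.max)
    merged <- FALSE
    best <- -Inf; pair <- NULL
    for (a in seq_along(ids)) {
      b <- nearest[a]
      if (nearest[b] == a && a < b && sims[a, b] >= threshold &&
          sims[a, b] > best) {
        best <- sims[a, b]; pair <- c(a, b)
      }
    }
    if (!is.null(pair)) {
      keep <- ids[pair[1]]; drop <- ids[pair[2]]
      labels[labels == drop] <- keep
      log[[length(log) + 1]] <- tibble(kept = keep, merged = drop,
                                       similarity = best)
      merged <- TRUE
    }
    if (!merged) break
  }
  ids <- sort(unique(labels[labels != 0]))
  relab <- labels
  for (i in seq_along(ids)) relab[labels == ids[i]] <- i
  attr(relab, "merge_log") <- if (length(log)) dplyr::bind_rows(log) else
    tibble(kept = integer(0), merged = integer(0), similarity = numeric(0))
  relab
}

#' Annotate clusters by marker panels
#'
#' Labels each cluster with the cell-type panel (e.g. cardiomyocyte:
#' ACTC1, MYH7) whose mean scaled expression over the cluster's cells is
#' maximal and exceeds `z_threshold`; clusters where no panel clears the
#' threshold are `"unassigned"`, and an exact tie between top panels is
#' `"ambiguous"` rather than broken arbitrarily.
#'
#' @param norm a `normalized_matrix` with `$scaled` filled
#'   ([scale_regress()]).
#' @param labels per-cell cluster labels (0 = noise, skipped).
#' @param panels named list of gene-id vectors.
#' @param z_threshold minimum mean scaled expression to assign a label.
#' @return tibble with `cluster`, `label`, `score`.
#' @export
annotate_by_markers <- function(norm, labels, panels, z_threshold = 0.5) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (is.null(norm$scaled)) abort("run scale_regress() first")
  missing <- setdiff(unlist(panels), norm$gene_ids)
  if (length(missing) > 0) {
    abort(paste0("panel genes absent from the matrix: ",
                 paste(missing, collapse = ", ")))
  }
  ids <- sort(unique(labels[labels != 0]))
  purrr::map_dfr(ids, function(k) {
    cells <- labels == k
    scores <- vapply(panels, function(genes) {
      mean(norm$scaled[match(genes, norm$gene_ids), cells, drop = FALSE])
    }, numeric(1))
    top <- max(scores)
    hit <- names(scores)[scores == top]
    label <- if (top < z_threshold) "unassigned"
             else if (length(hit) > 1) "ambiguous"
             else hit
    tibble(cluster = k, label = label, score = top)
  })
}
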