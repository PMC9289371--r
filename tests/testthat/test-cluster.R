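test_that("DBSCAN matches a brute-force reference on random instances", {
  skip_if_not_installed("igraph")
  set.seed(20)
  for (i in 1:30) {
    n <- sample(20:200, 1)
    k <- sample(1:3, 1)
    pts <- matrix(rnorm(n * 2, mean = sample(0:4, 1)), ncol = 2) +
      rep(c(0, 5)[sample(1:2, 1)], n)
    if (k > 1) pts[seq_len(n %/% 2), ] <- pts[seq_len(n %/% 2), ] + 4
    eps <- runif(1, 0.2, 1.5)
    minpts <- sample(2:8, 1)
    mine <- density_cluster(pts, cluster_params(minpts = minpts, epsilon = eps))
    ref <- oracle_dbscan(pts, eps, minpts)
    expect_true(same_partition(mine, ref),
                info = sprintf("instance %d (n=%d eps=%.2f minpts=%d)",
                               i, n, eps, minpts))
  }
})

test_that("DBSCAN degenerate regimes behave as defined", {
  set.seed(21)
  pts <- matrix(rnorm(60), ncol = 2)
  expect_true(all(density_cluster(pts, cluster_params(minpts = 3,
                                                      epsilon = 1e-9)) == 0))
  same <- matrix(1, nrow = 40, ncol = 2)
  expect_true(all(density_cluster(same, cluster_params(minpts = 5,
                                                       epsilon = 0.1)) == 1))
  blobs <- rbind(matrix(rnorm(100, 0, 0.2), ncol = 2),
                 matrix(rnorm(100, 10, 0.2), ncol = 2))
  lab <- density_cluster(blobs, cluster_params(minpts = 5, epsilon = 1))
  truth <- rep(1:2, each = 50)
  expect_equal(mclust::adjustedRandIndex(lab, truth), 1)
})

test_that("the k-distance curve is sorted and the elbow separates regimes", {
  set.seed(22)
  # dense cloud plus sparse far outliers: elbow must fall between scales
  pts <- rbind(matrix(rnorm(400, 0, 0.1), ncol = 2),
               matrix(runif(60, -20, 20), ncol = 2))
  kd <- estimate_epsilon(pts, k = 5)
  expect_true(all(diff(kd$curve$kdist) >= 0))
  expect_gt(kd$epsilon, 0.1)
  expect_lt(kd$epsilon, 5)
  expect_false(kd$weak)

  # equally spaced points on a circle: constant k-distance, weak elbow
  theta <- 2 * pi * (0:119) / 120
  ring <- cbind(10 * cos(theta), 10 * sin(theta)) +
    matrix(rnorm(240, 0, 1e-6), ncol = 2)
  kd2 <- estimate_epsilon(ring, k = 4)
  expect_true(kd2$weak)
  expect_lt(diff(range(kd2$curve$kdist)) / kd2$epsilon, 0.05)
  # geometry: the 4th nearest neighbor is two arc steps away
  expect_equal(kd2$epsilon, 2 * 10 * sin(2 * pi / 120), tolerance = 1e-3)

  same <- matrix(1, 40, 2)
  expect_warning(kd3 <- estimate_epsilon(same, k = 5), "degenerate")
  expect_equal(kd3$epsilon, 0)
  expect_error(estimate_epsilon(matrix(rnorm(8), 4, 2), k = 5), "at least")
})

test_that("UMAP projection is seeded and keeps duplicates together", {
  set.seed(23)
  emb <- rbind(matrix(rnorm(800, 0, 1), ncol = 10),
               matrix(rnorm(800, 10, 1), ncol = 10))
  emb[2, ] <- emb[1, ]
  co1 <- project_2d(emb, n_neighbors = 30, seed = 7)
  co2 <- project_2d(emb, n_neighbors = 30, seed = 7)
  expect_equal(unclass(co1)[, ], unclass(co2)[, ])
  rng <- max(apply(co1, 2, function(v) diff(range(v))))
  expect_lt(sqrt(sum((co1[1, ] - co1[2, ])^2)), 1e-3 * rng)
  expect_true(attr(co1, "trustworthiness") > 0.8)
  expect_error(project_2d(emb[1:10, ], n_neighbors = 15), "n_neighbors")

  # well-separated blobs stay separated in 2-D
  truth <- rep(1:2, each = 80)
  sil <- cluster::silhouette(truth, stats::dist(co1))
  expect_gte(mean(sil[, "sil_width"]), 0.8)
})

test_that("composition proportions are exact and label-permutation invariant", {
  labels <- c(rep(1, 63), rep(2, 37))
  groups <- rep("g1", 100)
  comp <- composition_table(labels, groups)
  expect_equal(comp$percent[comp$cluster == "1"], 63)
  expect_equal(sum(comp$proportion), 1, tolerance = 1e-9)

  # planted 62.91% / 37.09% split over 10,000 cells recovers exactly
  labels2 <- c(rep(1, 6291), rep(2, 3709))
  comp2 <- composition_table(labels2, rep("arp1", 10000))
  expect_equal(comp2$percent, c(62.91, 37.09))

  # relabeling clusters permutes rows, not proportions
  relab <- ifelse(labels == 1, 9, 4)
  comp3 <- composition_table(relab, groups)
  expect_equal(sort(comp3$proportion), sort(comp$proportion))

  multi <- composition_table(c(1, 1, 0, 2), c("a", "a", "a", "b"))
  sums <- tapply(multi$proportion, multi$group, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true("noise" %in% multi$cluster)
  expect_error(composition_table(integer(0), character(0)), "no cells")
})

test_that("clusters with matching group profiles merge; mismatched stay", {
  groups <- rep(c("a", "b"), each = 30)
  # clusters 1 and 2: identical composition (all group a); cluster 3: group b
  labels <- c(rep(1, 15), rep(2, 15), rep(3, 30))
  merged <- merge_clusters_by_group_profile(labels, groups, threshold = 0.99)
  expect_equal(length(unique(merged)), 2)
  expect_equal(unique(merged[1:30]), unique(merged[1:15]))
  log <- attr(merged, "merge_log")
  expect_equal(nrow(log), 1)

  none <- merge_clusters_by_group_profile(labels, groups, threshold = 1.01)
  expect_equal(length(unique(none)), 3)
})

test_that("marker panels annotate planted cell types and flag ties", {
  g <- generate_counts(separated_design(2, cells = 50, genes = 150, seed = 30))
  nm <- scale_regress(lognormalize(g$matrix))
  panels <- list(
    cardiomyocyte = g$matrix$gene_ids[1:5],      # cluster 1 markers
    fibroblast = g$matrix$gene_ids[16:20]        # cluster 2 markers
  )
  ann <- annotate_by_markers(nm, g$truth$cluster, panels)
  expect_equal(ann$label[ann$cluster == 1], "cardiomyocyte")
  expect_equal(ann$label[ann$cluster == 2], "fibroblast")

  # no panel expressed -> unassigned
  null_panels <- list(noone = g$matrix$gene_ids[140:145])
  ann2 <- annotate_by_markers(nm, g$truth$cluster, null_panels,
                              z_threshold = 5)
  expect_true(all(ann2$label == "unassigned"))

  # exact tie -> ambiguous
  tie <- list(p1 = g$matrix$gene_ids[1:5], p2 = g$matrix$gene_ids[1:5])
  ann3 <- annotate_by_markers(nm, g$truth$cluster, tie, z_threshold = -10)
  expect_true(all(ann3$label == "ambiguous"))

  expect_error(annotate_by_markers(nm, g$truth$cluster,
                                   list(x = "no_such_gene")), "no_such_gene")
})
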