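# Independent reference implementations used to cross-check the package.
# These deliberately take different computational routes than the exported
# functions.

# Brute-force DBSCAN: core points from the full distance matrix, clusters as
# graph components of the core-core eps-graph (igraph), numbered by their
# minimal core index; border points join the lowest-numbered cluster among
# their core neighbors.
oracle_dbscan <- function(points, eps, minpts) {
  d <- as.matrix(stats::dist(points))
  n <- nrow(points)
  core <- rowSums(d <= eps) >= minpts
  labels <- integer(n)
  if (!any(core)) return(labels)
  adj <- d <= eps
  gr <- igraph::graph_from_adjacency_matrix(
    adj & outer(core, core), mode = "undirected", diag = FALSE
  )
  comp <- igraph::components(gr)$membership
  core_idx <- which(core)
  comp_first <- tapply(core_idx, comp[core_idx], min)
  renumber <- rank(comp_first)
  for (i in core_idx) labels[i] <- renumber[[as.character(comp[i])]]
  for (i in which(!core)) {
    nb <- which(adj[i, ] & core)
    if (length(nb) > 0) labels[i] <- min(labels[nb])
  }
  labels
}

# labels equal up to renaming of cluster ids (noise must match exactly)
same_partition <- function(a, b) {
  if (!identical(a == 0, b == 0)) return(FALSE)
  a <- a[a != 0]; b <- b[b != 0]
  if (length(a) == 0) return(TRUE)
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(paste(a, b))) == length(unique(b))
}

# Two-sided Fisher p by direct enumeration of all tables with the observed
# margins, probabilities from binomial coefficients.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c; n2 <- b + d; k <- a + b
  support <- max(0, k - n2):min(k, m)
  pr <- choose(m, support) * choose(n2, k - support) / choose(m + n2, k)
  min(1, sum(pr[pr <= pr[support == a] * (1 + 1e-7)]))
}

# small well-separated multi-cluster design shared by several suites
separated_design <- function(n_clusters = 3, cells = 80, genes = 300,
                             fold = 4, seed = 101) {
  per <- 300 %/% n_clusters
  marker_plan <- lapply(seq_len(n_clusters), function(k) {
    list(list(genes = ((k - 1) * 15 + 1):(k * 15), fold = fold,
              rate_in = 0.9, rate_out = 0.1))
  })
  synthetic_design(n_clusters, cells, genes, marker_plan = marker_plan,
                   seed = seed)
}

# reorder/subset cells of a count_matrix without touching package internals
subset_cells_for_test <- function(m, idx) {
  count_matrix(m$counts[, idx, drop = FALSE], gene_ids = m$gene_ids,
               barcodes = m$barcodes[idx], group = m$group[idx],
               mito_flags = m$mito_flags)
}
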