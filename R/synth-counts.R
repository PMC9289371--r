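#' Synthetic snRNA-seq study design
#'
#' Describes a multi-group cell population with planted clusters,
#' cluster-specific marker genes at controlled fold-change and detection
#' rates, gene-program activity gradients, log-normal library-size
#' variation, mitochondrial-flagged genes, and negative-binomial count
#' noise. [generate_counts()] realizes a design into a [count_matrix()]
#' plus a ground-truth record, so every downstream stage of the pipeline
#' can be tested against known answers.
#'
#' @param n_clusters number of planted cell clusters.
#' @param cells_per_cluster integer vector of length `n_clusters`.
#' @param n_genes number of genes.
#' @param marker_plan list with one element per cluster; each element a list
#'   of marker specifications `list(genes =, fold =, rate_in =, rate_out =)`
#'   where `genes` are gene indices, `fold >= 1` the mean fold-change in the
#'   cluster, and the rates are in/out-of-cluster detection probabilities.
#'   A gene may serve as marker of up to 5 clusters (mirroring the observed
#'   sharing of cluster markers); beyond that the design is rejected.
#' @param group_map character vector of length `n_clusters` mapping each
#'   cluster to a sample-group label.
#' @param program_plan named list of gene programs, each
#'   `list(genes =, activity =)` with `activity` a length-`n_clusters`
#'   multiplier (>1 = elevated program activity in that cluster, e.g. a
#'   cell-cycle-like gradient).
#' @param library_size_law `c(meanlog =, sdlog =)` of the per-cell total-UMI
#'   log-normal law.
#' @param mito_gene_fraction fraction of genes flagged mitochondrial.
#' @param mito_high_cell_fraction fraction of cells given elevated
#'   mitochondrial content (x8 relative expression), for QC-filter tests.
#' @param mito_baseline_fraction expected share of a normal cell's UMIs
#'   coming from mitochondrial genes (default 2%, a typical healthy-cell
#'   level; mito-high cells land near 8x this).
#' @param dispersion negative-binomial dispersion (1/size); 0 gives the
#'   Poisson limit.
#' @param seed integer seed; identical seeds give identical matrices.
#' @return A `synthetic_design` list, validated.
#' @export
synthetic_design <- function(n_clusters,
                             cells_per_cluster,
                             n_genes,
                             marker_plan = NULL,
                             group_map = paste0("group", seq_len(n_clusters)),
                             program_plan = NULL,
                             library_size_law = c(meanlog = log(5000), sdlog = 0.3),
                             mito_gene_fraction = 0,
                             mito_high_cell_fraction = 0,
                             mito_baseline_fraction = 0.02,
                             dispersion = 0.5,
                             seed = 1L) {
  check_count(n_clusters, "n_clusters", min = 1L)
  check_count(cells_per_cluster, "cells_per_cluster", min = 1L)
  if (length(cells_per_cluster) == 1L) {
    cells_per_cluster <- rep(cells_per_cluster, n_clusters)
  }
  if (length(cells_per_cluster) != n_clusters) {
    stop_field("cells_per_cluster", "length must equal n_clusters")
  }
  check_count(n_genes, "n_genes", min = 1L)
  if (length(group_map) != n_clusters) stop_field("group_map", "length must equal n_clusters")
  check_prob(mito_gene_fraction, "mito_gene_fraction")
  check_prob(mito_high_cell_fraction, "mito_high_cell_fraction")
  check_prob(mito_baseline_fraction, "mito_baseline_fraction")
  if (!is.finite(dispersion) || dispersion < 0) stop_field("dispersion", "must be >= 0")
  if (is.null(marker_plan)) marker_plan <- vector("list", n_clusters)
  if (length(marker_plan) != n_clusters) stop_field("marker_plan", "length must equal n_clusters")
  shared <- integer(n_genes)
  for (k in seq_len(n_clusters)) {
    for (m in marker_plan[[k]]) {
      check_count(m$genes, "marker_plan$genes", min = 1L)
      if (any(m$genes > n_genes)) stop_field("marker_plan$genes", "gene index exceeds n_genes")
      if (!is.finite(m$fold) || m$fold < 1) stop_field("marker_plan$fold", "must be >= 1")
      check_prob(m$rate_in, "marker_plan$rate_in")
      check_prob(m$rate_out, "marker_plan$rate_out")
      shared[m$genes] <- shared[m$genes] + 1L
    }
  }
  if (any(shared > 5L)) {
    stop_field("marker_plan", "a gene may mark at most 5 clusters")
  }
  for (p in program_plan) {
    if (any(p$genes > n_genes)) stop_field("program_plan$genes", "gene index exceeds n_genes")
    if (length(p$activity) != n_clusters) stop_field("program_plan$activity", "length must equal n_clusters")
  }
  if (!all(c("meanlog", "sdlog") %in% names(library_size_law))) {
    stop_field("library_size_law", "needs named meanlog and sdlog")
  }
  structure(
    list(n_clusters = as.integer(n_clusters),
         cells_per_cluster = as.integer(cells_per_cluster),
         n_genes = as.integer(n_genes), marker_plan = marker_plan,
         group_map = as.character(group_map), program_plan = program_plan,
         library_size_law = library_size_law,
         mito_gene_fraction = mito_gene_fraction,
         mito_high_cell_fraction = mito_high_cell_fraction,
         mito_baseline_fraction = mito_baseline_fraction,
         dispersion = dispersion, seed = as.integer(seed)),
    class = "synthetic_design"
  )
}

# run code under a seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate a synthetic count matrix with ground truth
#'
#' Draws a gene x cell UMI matrix from a [synthetic_design()]. Each cluster
#' has a baseline relative-expression profile shared across clusters,
#' modulated by its marker plan and program activities; per-cell totals
#' follow the design's log-normal library-size law; counts are negative
#' binomial (Poisson when `dispersion = 0`). Planted marker genes are
#' switched on/off per cell by the specified detection rates and are
#' guaranteed nonzero when on, so empirical detection rates match the plan
#' up to binomial noise.
#'
#' @param design a [synthetic_design()].
#' @return list with `matrix` (a [count_matrix()]) and `truth`, a list
#'   recording per-cell true cluster and group, per-cluster marker sets,
#'   per-cell program activity, and which cells are mito-high.
#' @export
generate_counts <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  with_local_seed(design$seed, {
    n_cells <- sum(design$cells_per_cluster)
    g <- design$n_genes
    cluster <- rep(seq_len(design$n_clusters), design$cells_per_cluster)
    group <- design$group_map[cluster]

    # baseline relative expression shared by all clusters (gamma-like spread)
    base <- exp(rnorm(g, mean = 0, sd = 1.2))
    rel <- matrix(base, nrow = g, ncol = design$n_clusters)

    marker_sets <- vector("list", design$n_clusters)
    for (k in seq_len(design$n_clusters)) {
      idx <- integer(0)
      for (m in design$marker_plan[[k]]) {
        rel[m$genes, k] <- rel[m$genes, k] * m$fold
        idx <- union(idx, m$genes)
      }
      marker_sets[[k]] <- sort(idx)
    }
    for (p in design$program_plan) {
      rel[p$genes, ] <- rel[p$genes, , drop = FALSE] *
        rep(p$activity, each = length(p$genes))
    }

    mito_flags <- rep(FALSE, g)
    n_mito <- round(design$mito_gene_fraction * g)
    if (n_mito > 0) {
      mito_flags[sample.int(g, n_mito)] <- TRUE
      # rescale mito baseline so a normal cell's expected mito UMI share
      # equals mito_baseline_fraction
      target <- design$mito_baseline_fraction
      s_m <- sum(rel[mito_flags, 1]); s_o <- sum(rel[!mito_flags, 1])
      if (s_m > 0 && target < 1) {
        rel[mito_flags, ] <- rel[mito_flags, , drop = FALSE] *
          (target / (1 - target)) * s_o / s_m
      }
    }
    mito_high <- rep(FALSE, n_cells)
    n_high <- round(design$mito_high_cell_fraction * n_cells)
    if (n_high > 0) mito_high[sample.int(n_cells, n_high)] <- TRUE

    lib <- exp(rnorm(n_cells, design$library_size_law[["meanlog"]],
                     design$library_size_law[["sdlog"]]))

    size <- if (design$dispersion > 0) 1 / design$dispersion else Inf
    counts <- matrix(0L, nrow = g, ncol = n_cells)
    # marker on/off switches per cell, plan order fixed by cluster then spec
    for (c_i in seq_len(n_cells)) {
      k <- cluster[c_i]
      prof <- rel[, k]
      if (mito_high[c_i] && any(mito_flags)) {
        prof[mito_flags] <- prof[mito_flags] * 8
      }
      on <- rep(TRUE, g)
      planted <- rep(FALSE, g)
      for (kk in seq_len(design$n_clusters)) {
        for (m in design$marker_plan[[kk]]) {
          rate <- if (kk == k) m$rate_in else m$rate_out
          on[m$genes] <- runif(length(m$genes)) < rate
          planted[m$genes] <- TRUE
        }
      }
      mu <- prof / sum(prof) * lib[c_i]
      x <- if (is.finite(size)) {
        rnbinom(g, size = size, mu = mu)
      } else {
        rpois(g, lambda = mu)
      }
      # planted markers: detection is exactly the Bernoulli switch
      x[planted] <- ifelse(on[planted], 1L + x[planted], 0L)
      counts[, c_i] <- x
    }

    program_levels <- lapply(design$program_plan, function(p) p$activity[cluster])
    names(program_levels) <- names(design$program_plan)

    mat <- count_matrix(
      counts,
      gene_ids = sprintf("gene%05d", seq_len(g)),
      barcodes = sprintf("cell%05d", seq_len(n_cells)),
      group = group, mito_flags = mito_flags
    )
    truth <- list(
      cluster = cluster, group = group, marker_sets = marker_sets,
      program_levels = program_levels, mito_high = mito_high,
      library_size = lib
    )
    list(matrix = mat, truth = truth)
  })
}

#' Reference synthetic study design
#'
#' The package's standard test-bed: 6 planted cell clusters of 500 cells
#' each across 4 sample groups, 2,000 genes, 20 unique markers per cluster
#' (fold 4, 90% in-cluster / 10% out-of-cluster detection), one
#' cell-cycle-like gene program elevated 3-fold in the fetal-like cluster
#' and absent in the mature-like cluster, and log-normal library sizes
#' around 5,000 UMIs. These are the conditions under which the pipeline's
#' end-to-end recovery properties are stated.
#'
#' @param seed integer seed.
#' @param cells_per_cluster cells per planted cluster (default 500).
#' @param n_genes number of genes (default 2,000).
#' @return a [synthetic_design()].
#' @export
study_design <- function(seed = 1L, cells_per_cluster = 500, n_genes = 2000) {
  n_clusters <- 6
  marker_plan <- lapply(seq_len(n_clusters), function(k) {
    list(list(genes = ((k - 1) * 20 + 1):(k * 20), fold = 4,
              rate_in = 0.9, rate_out = 0.1))
  })
  program_genes <- (n_clusters * 20 + 1):(n_clusters * 20 + 30)
  synthetic_design(
    n_clusters = n_clusters,
    cells_per_cluster = cells_per_cluster,
    n_genes = n_genes,
    marker_plan = marker_plan,
    group_map = c("ctl", "ctl", "injury_p28", "injury_p28", "injury_p56", "fetal"),
    program_plan = list(
      cell_cycle = list(genes = program_genes,
                        activity = c(1, 1, 1.5, 1.5, 1, 3))
    ),
    seed = seed
  )
}
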