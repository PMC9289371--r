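#' Marker-selection configuration
#'
#' The three cluster-marker criteria: Fisher-exact detection enrichment at
#' `p < 1e-6` (strict), expression in at least 50% of the cluster's cells
#' (inclusive), and mean normalized abundance at least 1.3-fold the
#' all-cell mean (inclusive). `genome_size` (25,800 genes for the pig
#' genome) converts marker counts to genome percentages.
#'
#' @param p_threshold Fisher-exact p-value cutoff (strict `<`).
#' @param min_expressing_fraction minimum in-cluster detection fraction.
#' @param min_fold minimum abundance fold-change versus all cells.
#' @param genome_size genes in the genome, for percentage reporting.
#' @param fold_scale `"linear"` (counts-per-10,000 means, default) or
#'   `"log"` (mean of log-normalized values) for the fold criterion.
#' @return a `marker_config` list.
#' @export
marker_config <- function(p_threshold = 1e-6, min_expressing_fraction = 0.5,
                          min_fold = 1.3, genome_size = 25800,
                          fold_scale = c("linear", "log")) {
  fold_scale <- match.arg(fold_scale)
  if (p_threshold <= 0) stop_field("p_threshold", "must be positive")
  if (min_expressing_fraction <= 0 || min_expressing_fraction > 1) {
    stop_field("min_expressing_fraction", "must be in (0, 1]")
  }
  if (min_fold <= 0) stop_field("min_fold", "must be positive")
  structure(list(p_threshold = p_threshold,
                 min_expressing_fraction = min_expressing_fraction,
                 min_fold = min_fold, genome_size = genome_size,
                 fold_scale = fold_scale),
            class = "marker_config")
}

#' Fisher's exact test for a 2x2 table
#'
#' Conditional two-sided test: given the margins, the p-value is the sum
#' of hypergeometric probabilities of all tables at most as probable as
#' the observed one (with the customary `1 + 1e-7` relative tolerance for
#' floating-point ties). The odds ratio is the sample `ad/bc`, with
#' `Inf`/`0` when a single off-diagonal cell is empty and `NaN` flagged
#' undefined when a margin is zero.
#'
#' @param table 2x2 matrix of non-negative integer counts
#'   `rbind(c(a, b), c(c, d))`.
#' @return list with `odds_ratio`, `p_value`, and `undefined` (logical:
#'   a zero margin makes the OR meaningless and forces `p = 1`).
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("need a 2x2 table")
  if (any(table < 0) || any(table != floor(table))) {
    stop_field("table", "must hold non-negative integers")
  }
  a <- table[1, 1]; b <- table[1, 2]; cc <- table[2, 1]; d <- table[2, 2]
  m <- a + cc; n2 <- b + d; k <- a + b
  if (m == 0 || n2 == 0 || k == 0 || cc + d == 0) {
    return(list(odds_ratio = NaN, p_value = 1, undefined = TRUE))
  }
  support <- max(0, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- (a * d) / (b * cc)          # Inf or 0 when one off cell is empty
  list(odds_ratio = or, p_value = p, undefined = FALSE)
}

# per-gene marker evaluation against one cluster: detection fractions,
# fold on the requested scale, Fisher p and OR. Shared by find_markers()
# and criterion_counts().
evaluate_markers <- function(x, norm, labels, cluster, config) {
  in_cells <- labels == cluster
  n_in <- sum(in_cells); n_out <- sum(!in_cells)
  detected <- x$counts > 0
  a <- Matrix::rowSums(detected[, in_cells, drop = FALSE])
  c_ <- Matrix::rowSums(detected[, !in_cells, drop = FALSE])
  frac_in <- a / n_in

  if (config$fold_scale == "linear") {
    cp10k <- sweep_cols_sparse(x$counts, 10000 / Matrix::colSums(x$counts))
    mean_in <- Matrix::rowSums(cp10k[, in_cells, drop = FALSE]) / n_in
    mean_all <- Matrix::rowSums(cp10k) / ncol(cp10k)
  } else {
    mean_in <- Matrix::rowSums(norm$lognorm[, in_cells, drop = FALSE]) / n_in
    mean_all <- Matrix::rowSums(norm$lognorm) / ncol(norm$lognorm)
  }
  fold <- ifelse(mean_all > 0, mean_in / mean_all, NaN)

  fis <- purrr::map(seq_along(a), function(i) {
    fisher_exact(rbind(c(a[i], n_in - a[i]), c(c_[i], n_out - c_[i])))
  })
  tibble(
    gene = x$gene_ids,
    expressing_fraction = unname(frac_in),
    expressing_out = unname(c_) / max(n_out, 1),
    fold = unname(fold),
    odds_ratio = purrr::map_dbl(fis, "odds_ratio"),
    p_value = purrr::map_dbl(fis, "p_value")
  )
}

# multiply each column of a sparse matrix by a scalar
sweep_cols_sparse <- function(m, f) {
  if (length(m@x) > 0) {
    col_of <- rep(seq_len(ncol(m)), diff(m@p))
    m@x <- m@x * f[col_of]
  }
  m
}

#' Find marker genes of a cluster
#'
#' A gene is a marker of a cluster iff all three criteria hold: Fisher
#' exact p (detection in/out of cluster) below `p_threshold`, detection in
#' at least `min_expressing_fraction` of the cluster's cells, and mean
#' normalized abundance at least `min_fold` times the all-cell mean.
#' A cell "expresses" a gene iff its raw count is > 0.
#'
#' @param x the [count_matrix()] (raw counts define detection and the
#'   counts-per-10,000 abundance scale).
#' @param labels per-cell cluster labels.
#' @param cluster the cluster to characterize.
#' @param config a [marker_config()].
#' @param norm optional `normalized_matrix`, needed only for
#'   `fold_scale = "log"`.
#' @return tibble of selected markers with `gene`, `expressing_fraction`,
#'   `fold`, `odds_ratio`, `p_value`, sorted by p. Clusters with fewer
#'   than 3 cells yield an empty table with a warning.
#' @export
find_markers <- function(x, labels, cluster, config = marker_config(),
                         norm = NULL) {
  stopifnot(inherits(x, "count_matrix"), inherits(config, "marker_config"))
  if (sum(labels == cluster) == 0) abort("cluster has no cells")
  if (sum(labels == cluster) < 3) {
    warn("cluster has fewer than 3 cells; no markers reported")
    return(tibble(gene = character(0), expressing_fraction = numeric(0),
                  fold = numeric(0), odds_ratio = numeric(0),
                  p_value = numeric(0)))
  }
  ev <- evaluate_markers(x, norm, labels, cluster, config)
  ev |>
    dplyr::filter(.data$p_value < config$p_threshold,
                  .data$expressing_fraction >= config$min_expressing_fraction,
                  !is.na(.data$fold), .data$fold >= config$min_fold) |>
    dplyr::arrange(.data$p_value, dplyr::desc(.data$fold)) |>
    dplyr::select(!"expressing_out")
}

#' Per-cluster marker-criterion counts and genome percentages
#'
#' For every cluster: the number of genes passing the detection-fraction
#' criterion, the fold criterion, and both, with each count also expressed
#' as a percentage of the genome (`count / genome_size * 100`, rounded
#' half away from zero to 2 decimals) — the summary layout used to argue
#' that joint markers always stay under 2% of the genome.
#'
#' @inheritParams find_markers
#' @return tibble with one row per cluster: `cluster`, `n_criterion1`,
#'   `pct_criterion1`, `n_criterion2`, `pct_criterion2`, `n_joint`,
#'   `pct_joint`.
#' @export
criterion_counts <- function(x, labels, config = marker_config(), norm = NULL) {
  ids <- sort(unique(labels[labels != 0]))
  purrr::map_dfr(ids, function(k) {
    ev <- evaluate_markers(x, norm, labels, k, config)
    c1 <- ev$expressing_fraction >= config$min_expressing_fraction
    c2 <- !is.na(ev$fold) & ev$fold >= config$min_fold
    tibble(
      cluster = k,
      n_criterion1 = sum(c1),
      pct_criterion1 = genome_percent(sum(c1), config$genome_size),
      n_criterion2 = sum(c2),
      pct_criterion2 = genome_percent(sum(c2), config$genome_size),
      n_joint = sum(c1 & c2),
      pct_joint = genome_percent(sum(c1 & c2), config$genome_size)
    )
  })
}

#' Genome percentage of a gene count
#'
#' @param n gene count.
#' @param genome_size genome size (default 25,800).
#' @return `n / genome_size * 100` rounded half away from zero to 2
#'   decimals.
#' @export
genome_percent <- function(n, genome_size = 25800) {
  round_half_up(n / genome_size * 100, 2)
}

#' Marker-sharing histogram across clusters
#'
#' For each gene in the union of the per-cluster marker sets, counts how
#' many clusters it marks; reports the histogram with percentages of the
#' union size (rounded half away from zero to 2 decimals).
#'
#' @param marker_sets list of per-cluster marker gene-id vectors.
#' @return tibble with `n_clusters`, `n_genes`, `percent`.
#' @export
overlap_summary <- function(marker_sets) {
  if (length(marker_sets) == 0) abort("need at least one marker set")
  genes <- unlist(lapply(marker_sets, unique))
  if (length(genes) == 0) {
    return(tibble(n_clusters = integer(0), n_genes = integer(0),
                  percent = numeric(0)))
  }
  counts <- table(table(genes))
  union_size <- length(unique(genes))
  tibble(
    n_clusters = as.integer(names(counts)),
    n_genes = as.integer(counts),
    percent = round_half_up(as.integer(counts) / union_size * 100, 2)
  )
}
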