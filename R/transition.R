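#' Semisupervised self-training scores for an unlabeled cluster
#'
#' Splits an unlabeled cell population between two labeled reference
#' clusters by self-training: a ridge-regularized logistic classifier is
#' fit on the labeled cells, unlabeled cells whose class posterior exceeds
#' the confidence threshold are pseudo-labeled, and the model is refit
#' until no additions remain or `max_iter` is reached. Each unlabeled cell
#' receives a rescaled score in `[0, 1]` — the posterior probability of
#' class 2 — so scores approaching 0 mark class-1-like cells and scores
#' approaching 1 mark class-2-like cells (the CM1a / CM1b reading).
#'
#' @param labeled1,labeled2 cells x genes matrices of the two labeled
#'   reference clusters (class 1 and class 2).
#' @param unlabeled cells x genes matrix of the cells to score.
#' @param confidence posterior threshold for pseudo-labeling (default
#'   0.9).
#' @param max_iter self-training iteration cap (default 10).
#' @param lambda ridge penalty of the base learner.
#' @param seed integer seed (cross-validation-free path is deterministic;
#'   the seed pins any residual randomness).
#' @return numeric scores in `[0, 1]`, one per unlabeled cell, with
#'   attributes `"iterations"` and `"converged"` (`FALSE` triggers a
#'   warning, not an error).
#' @export
fit_semisupervised_scores <- function(labeled1, labeled2, unlabeled,
                                      confidence = 0.9, max_iter = 10,
                                      lambda = 0.01, seed = 1L) {
  labeled1 <- as.matrix(labeled1); labeled2 <- as.matrix(labeled2)
  unlabeled <- as.matrix(unlabeled)
  if (nrow(labeled1) == 0 || nrow(labeled2) == 0) {
    abort("both labeled reference sets must be non-empty")
  }
  check_prob(confidence, "confidence")
  with_local_seed(seed, {
    X <- rbind(labeled1, labeled2)
    y <- c(rep(0, nrow(labeled1)), rep(1, nrow(labeled2)))
    pseudo_idx <- integer(0)
    pseudo_y <- numeric(0)
    converged <- FALSE
    iters <- 0L
    scores <- rep(NA_real_, nrow(unlabeled))
    repeat {
      iters <- iters + 1L
      fit <- glmnet::glmnet(rbind(X, unlabeled[pseudo_idx, , drop = FALSE]),
                            c(y, pseudo_y),
                            family = "binomial", alpha = 0, lambda = lambda,
                            standardize = FALSE)
      scores <- drop(predict(fit, unlabeled, type = "response"))
      remaining <- setdiff(seq_len(nrow(unlabeled)), pseudo_idx)
      conf <- pmax(scores[remaining], 1 - scores[remaining])
      add <- remaining[conf > confidence]
      if (length(add) == 0) { converged <- TRUE; break }
      pseudo_idx <- c(pseudo_idx, add)
      pseudo_y <- c(pseudo_y, as.numeric(scores[add] >= 0.5))
      if (iters >= max_iter) break
    }
    if (!converged) warn("self-training did not converge within max_iter")
    scores <- pmin(pmax(scores, 0), 1)
    attr(scores, "iterations") <- iters
    attr(scores, "converged") <- converged
    scores
  })
}

#' Split scored cells into two reference-like subpopulations
#'
#' @param scores rescaled scores in `[0, 1]`.
#' @param threshold decision boundary; a score exactly at the threshold
#'   goes to class 2 (documented tie rule).
#' @return character vector `"class1-like"` / `"class2-like"`.
#' @export
split_subpops <- function(scores, threshold = 0.5) {
  if (length(scores) == 0) return(character(0))
  check_prob(scores, "scores")
  ifelse(scores < threshold, "class1-like", "class2-like")
}

#' Differential genes between two subpopulations
#'
#' Per gene: two-sided Wilcoxon rank-sum p on the log-normalized values,
#' Benjamini-Hochberg adjustment, fold-change of counts-per-10,000 means,
#' and detection-fraction difference; ranked by p.
#'
#' @param norm a `normalized_matrix`.
#' @param x the matching [count_matrix()] (for detection and abundance).
#' @param cells1,cells2 disjoint cell index/logical vectors (>= 3 cells
#'   each).
#' @return tibble `gene`, `p_value`, `p_adjusted`, `fold`,
#'   `detection_diff`, sorted by p then gene id.
#' @export
diff_genes <- function(norm, x, cells1, cells2) {
  stopifnot(inherits(norm, "normalized_matrix"), inherits(x, "count_matrix"))
  i1 <- seq_len(ncol(x$counts))[cells1]
  i2 <- seq_len(ncol(x$counts))[cells2]
  if (length(i1) < 3 || length(i2) < 3) {
    abort("each subpopulation needs at least 3 cells")
  }
  ln <- as.matrix(norm$lognorm)
  cp10k <- sweep_cols_sparse(x$counts, 10000 / Matrix::colSums(x$counts))
  p <- vapply(seq_len(nrow(ln)), function(g) {
    v1 <- ln[g, i1]; v2 <- ln[g, i2]
    if (all(v1 == v1[1]) && all(v2 == v1[1])) return(1)
    suppressWarnings(wilcox.test(v1, v2)$p.value)
  }, numeric(1))
  m1 <- Matrix::rowSums(cp10k[, i1, drop = FALSE]) / length(i1)
  m2 <- Matrix::rowSums(cp10k[, i2, drop = FALSE]) / length(i2)
  det1 <- Matrix::rowSums(x$counts[, i1, drop = FALSE] > 0) / length(i1)
  det2 <- Matrix::rowSums(x$counts[, i2, drop = FALSE] > 0) / length(i2)
  tibble(
    gene = x$gene_ids, p_value = p,
    p_adjusted = p.adjust(p, method = "BH"),
    fold = ifelse(m2 > 0, m1 / m2, ifelse(m1 > 0, Inf, NaN)),
    detection_diff = det1 - det2
  ) |>
    dplyr::arrange(.data$p_value, .data$gene)
}

#' Fraction of cells co-expressing every gene in a set
#'
#' A cell counts iff its raw count is > 0 for each listed gene (a single
#' zero excludes it).
#'
#' @param x a [count_matrix()].
#' @param genes non-empty gene-id vector.
#' @param cells optional cell index/logical subset (default all).
#' @return percent of qualifying cells, rounded half away from zero to 2
#'   decimals.
#' @export
coexpression_fraction <- function(x, genes, cells = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (length(genes) == 0) abort("gene set must be non-empty")
  gi <- match(genes, x$gene_ids)
  if (anyNA(gi)) {
    abort(paste0("genes absent from the matrix: ",
                 paste(genes[is.na(gi)], collapse = ", ")))
  }
  m <- x$counts[gi, , drop = FALSE]
  if (!is.null(cells)) m <- m[, cells, drop = FALSE]
  if (ncol(m) == 0) abort("no cells selected")
  all_pos <- Matrix::colSums(m > 0) == length(gi)
  round_half_up(100 * mean(all_pos), 2)
}

#' Combine a co-expression percentage with a cluster proportion
#'
#' The share of a whole population attributable to a co-expressing
#' subpopulation of one cluster: the product of the two percentages
#' (e.g. 38.15% co-expressing cells within a cluster that is 62.91% of the
#' population gives 24.00%).
#'
#' @param coexpr_percent,cluster_percent percentages in `[0, 100]`.
#' @return the product expressed as a percent, rounded half away from
#'   zero to 2 decimals.
#' @export
transition_estimate <- function(coexpr_percent, cluster_percent) {
  for (v in c(coexpr_percent, cluster_percent)) {
    if (!is.finite(v) || v < 0 || v > 100) {
      stop_field("percent", "must be in [0, 100]")
    }
  }
  round_half_up(coexpr_percent * cluster_percent / 100, 2)
}
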