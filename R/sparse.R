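#' Gene-program definition
#'
#' A named gene list with positive and negative reference cell groups
#' (e.g. a cell-cycle program with fetal cells as the positive group and
#' adult control cells as the negative group). The margin model is trained
#' on the reference groups restricted to the program's genes and then
#' scores every cell.
#'
#' @param name program name.
#' @param genes non-empty character vector of gene ids.
#' @param positive,negative disjoint, non-empty selectors: values matched
#'   against per-cell group or cluster labels.
#' @return a `gene_program` list.
#' @export
gene_program <- function(name, genes, positive, negative) {
  if (length(genes) == 0) stop_field("genes", "must be non-empty")
  if (length(positive) == 0 || length(negative) == 0) {
    stop_field("positive/negative", "must be non-empty")
  }
  if (length(intersect(positive, negative)) > 0) {
    stop_field("positive/negative", "must be disjoint")
  }
  structure(list(name = name, genes = as.character(genes),
                 positive = positive, negative = negative),
            class = "gene_program")
}

#' Read gene-program definitions from JSON
#'
#' The file holds an array of objects with fields `name`, `genes`,
#' `positive`, `negative` (the layout of the positive/negative reference
#' group table).
#'
#' @param path JSON file.
#' @return list of [gene_program()] objects.
#' @export
read_gene_programs <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  purrr::pmap(raw, function(name, genes, positive, negative, ...) {
    gene_program(name, unlist(genes), unlist(positive), unlist(negative))
  })
}

# smoothed hinge: quadratic on (0, delta), linear above
smooth_hinge <- function(z, delta) {
  ifelse(z <= 0, 0, ifelse(z < delta, z^2 / (2 * delta), z - delta / 2))
}
smooth_hinge_grad <- function(z, delta) {
  ifelse(z <= 0, 0, ifelse(z < delta, z / delta, 1))
}

#' Fit the sparse margin model
#'
#' Minimizes `0.5 * norm(w) + C * sum(eps_i)` subject to
#' `y_i (w x_i + b) + eps_i >= 1`, `eps_i >= 0` — a soft-margin linear
#' model over the program's genes with the slack written as the hinge
#' `eps_i = max(0, 1 - y_i (w x_i + b))`. The default L1 norm drives
#' uninformative gene weights to zero (the "sparse" in sparse modeling);
#' the classic L2-squared norm is available via `norm_type`. The convex
#' objective is solved by BFGS on an annealed smoothed surrogate (smoothed
#' hinge and, for L1, a smoothed absolute value), then the exact slacks
#' and objective are reported at the returned point.
#'
#' @param X cells x genes matrix restricted to the program genes
#'   (training cells only).
#' @param y labels in -1/+1, one per row of `X`.
#' @param C slack cost (default 1).
#' @param norm_type `"l1"` (default) or `"l2"` (squared).
#' @return a `sparse_model`: `w`, `b`, `eps` (exact slacks),
#'   `zero_slack_fraction` (share of training cells with `eps < 1e-6`, the
#'   model-quality diagnostic: a good fit has e.g. >= 90%), `objective`,
#'   `C`, `norm_type`, `genes`.
#' @export
fit_sparse <- function(X, y, C = 1, norm_type = c("l1", "l2")) {
  norm_type <- match.arg(norm_type)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) abort("y must have one label per row of X")
  if (!all(y %in% c(-1, 1))) stop_field("y", "labels must be -1 or +1")
  if (length(unique(y)) < 2) abort("both classes must be present")
  if (!is.finite(C) || C <= 0) stop_field("C", "must be > 0")
  p <- ncol(X)

  obj_grad <- function(theta, delta, mu) {
    w <- theta[seq_len(p)]; b <- theta[p + 1]
    z <- 1 - y * (X %*% w + b)
    reg <- if (norm_type == "l1") 0.5 * sum(sqrt(w^2 + mu^2) - mu)
           else 0.5 * sum(w^2)
    val <- reg + C * sum(smooth_hinge(z, delta))
    g_z <- smooth_hinge_grad(z, delta)
    gw_reg <- if (norm_type == "l1") 0.5 * w / sqrt(w^2 + mu^2) else w
    gw <- gw_reg - C * drop(crossprod(X, y * g_z))
    gb <- -C * sum(y * g_z)
    list(value = val, gradient = c(gw, gb))
  }

  theta <- rep(0, p + 1)
  stages <- cbind(delta = 10^-(0:6) / 2,
                  mu = 10^-(1:7))
  for (s in seq_len(nrow(stages))) {
    delta <- stages[s, "delta"]; mu <- stages[s, "mu"]
    fit <- optim(theta,
                 fn = function(t) obj_grad(t, delta, mu)$value,
                 gr = function(t) obj_grad(t, delta, mu)$gradient,
                 method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14))
    theta <- fit$par
  }
  w <- theta[seq_len(p)]; b <- theta[p + 1]
  if (norm_type == "l1") w[abs(w) < 1e-8] <- 0
  scores <- drop(X %*% w + b)
  eps <- pmax(0, 1 - y * scores)
  reg <- if (norm_type == "l1") 0.5 * sum(abs(w)) else 0.5 * sum(w^2)
  structure(
    list(w = setNames(w, colnames(X)), b = b, eps = eps,
         zero_slack_fraction = mean(eps < 1e-6),
         objective = reg + C * sum(eps), C = C, norm_type = norm_type,
         genes = colnames(X)),
    class = "sparse_model"
  )
}

#' Score cells with a fitted margin model
#'
#' The linear score `y = w x + b` per cell; on separable training data the
#' positives land at or above the `+1` margin and the negatives at or
#' below `-1`.
#'
#' @param model a `sparse_model`.
#' @param X cells x genes matrix over the model's genes (column names, if
#'   present, must match the training genes).
#' @return numeric score per cell.
#' @export
score_cells <- function(model, X) {
  stopifnot(inherits(model, "sparse_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$w)) {
    abort(sprintf("X has %d genes but the model expects %d",
                  ncol(X), length(model$w)))
  }
  if (!is.null(colnames(X)) && !is.null(model$genes) &&
      !identical(colnames(X), model$genes)) {
    abort("gene columns do not match the model's training genes")
  }
  drop(X %*% model$w + model$b)
}

#' Categorize scores into high / middle / low
#'
#' `high` iff the score exceeds the +1 margin, `low` iff it falls below
#' the -1 margin, `middle` on the closed interval between them.
#'
#' @param scores numeric scores from [score_cells()].
#' @param labels optional per-cell cluster/group labels for the count
#'   table.
#' @return a `category_result`: tibble with `score` and `category`
#'   (factor high/middle/low), plus per-label counts in the
#'   `"category_counts"` attribute when `labels` is given.
#' @export
categorize <- function(scores, labels = NULL) {
  if (any(!is.finite(scores))) abort("scores must be finite")
  category <- factor(
    ifelse(scores > 1, "high", ifelse(scores < -1, "low", "middle")),
    levels = c("high", "middle", "low")
  )
  out <- tibble(score = scores, category = category)
  if (!is.null(labels)) {
    out$label <- labels
    attr(out, "category_counts") <- out |>
      dplyr::count(.data$label, .data$category, .drop = FALSE, name = "n")
  }
  class(out) <- c("category_result", class(out))
  out
}

#' Compare the high-score fraction between two clusters
#'
#' Builds the 2x2 table (high / not-high by cluster A / B) and runs
#' [fisher_exact()]; significance is called at `p < 1e-6`.
#'
#' @param categories a `category_result` with a `label` column.
#' @param cluster_a,cluster_b labels to compare.
#' @param p_threshold significance threshold.
#' @return tibble with `odds_ratio`, `p_value`, `significant`, and the
#'   table cells.
#' @export
compare_high_fraction <- function(categories, cluster_a, cluster_b,
                                  p_threshold = 1e-6) {
  stopifnot(inherits(categories, "category_result"))
  if (!"label" %in% names(categories)) abort("categories lack a label column")
  in_a <- categories$label == cluster_a
  in_b <- categories$label == cluster_b
  if (!any(in_a) || !any(in_b)) abort("both clusters must be non-empty")
  high <- categories$category == "high"
  tab <- rbind(c(sum(high & in_a), sum(high & in_b)),
               c(sum(!high & in_a), sum(!high & in_b)))
  fis <- fisher_exact(tab)
  tibble(
    cluster_a = as.character(cluster_a), cluster_b = as.character(cluster_b),
    high_a = tab[1, 1], n_a = sum(in_a),
    high_b = tab[1, 2], n_b = sum(in_b),
    odds_ratio = fis$odds_ratio, p_value = fis$p_value,
    significant = !fis$undefined & fis$p_value < p_threshold
  )
}
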