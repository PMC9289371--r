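#' Quality-control thresholds for cell filtering
#'
#' Defaults follow the protocol this pipeline reproduces: a barcode is
#' dropped if it has fewer than 500 UMIs, more than 30,000 UMIs, or more
#' than 5% mitochondrial UMIs; a nucleus is dropped if it has fewer than
#' 200 detected genes or more than 25% mitochondrial transcripts.
#' Inequalities are strict, so boundary cells (exactly 500 UMIs, exactly
#' 5% mito, ...) are kept. All five thresholds are configurable.
#'
#' @param min_umi minimum UMI count (cells with fewer are removed).
#' @param max_umi maximum UMI count (cells with more are removed).
#' @param max_mito_fraction barcode-level mitochondrial UMI fraction cap.
#' @param min_genes minimum number of detected genes.
#' @param max_mito_nucleus_fraction nucleus-level mitochondrial fraction cap.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_umi = 500, max_umi = 30000,
                          max_mito_fraction = 0.05, min_genes = 200,
                          max_mito_nucleus_fraction = 0.25) {
  if (min_umi >= max_umi) stop_field("min_umi", "must be < max_umi")
  check_prob(max_mito_fraction, "max_mito_fraction")
  check_prob(max_mito_nucleus_fraction, "max_mito_nucleus_fraction")
  structure(list(min_umi = min_umi, max_umi = max_umi,
                 max_mito_fraction = max_mito_fraction,
                 min_genes = min_genes,
                 max_mito_nucleus_fraction = max_mito_nucleus_fraction),
            class = "qc_thresholds")
}

#' Filter cells by QC thresholds
#'
#' Applies the five removal rules of [qc_thresholds()]; a cell is retained
#' only if it violates none of them. Per-rule removal counts (overlaps
#' included, so they may sum to more than the total removed) are attached
#' as the `"qc_log"` attribute, a tibble.
#'
#' @param x a [count_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return the filtered [count_matrix()]; warns (rather than silently
#'   returning) when no cell survives.
#' @export
filter_cells <- function(x, thresholds = qc_thresholds()) {
  stopifnot(inherits(x, "count_matrix"), inherits(thresholds, "qc_thresholds"))
  st <- cell_stats(x)
  fail <- list(
    low_umi = st$n_umi < thresholds$min_umi,
    high_umi = st$n_umi > thresholds$max_umi,
    high_mito = st$mito_fraction > thresholds$max_mito_fraction,
    few_genes = st$n_gene < thresholds$min_genes,
    high_mito_nucleus = st$mito_fraction > thresholds$max_mito_nucleus_fraction
  )
  keep <- !Reduce(`|`, fail)
  log <- tibble(
    rule = names(fail),
    removed = unname(vapply(fail, sum, integer(1))),
    threshold = c(thresholds$min_umi, thresholds$max_umi,
                  thresholds$max_mito_fraction, thresholds$min_genes,
                  thresholds$max_mito_nucleus_fraction)
  )
  if (ncol(x$counts) > 0 && !any(keep)) {
    warn("all cells removed by QC filtering; returning an empty matrix")
  }
  out <- subset_cells(x, keep)
  attr(out, "qc_log") <- log
  out
}

#' Log-normalize a count matrix
#'
#' Per-cell totals are rescaled to a common factor of 10,000 and
#' log-transformed with a pseudocount of 1 (natural log):
#' `log(1 + count * 10000 / total)`. Zero-total cells must be filtered
#' first.
#'
#' @param x a [count_matrix()].
#' @param scale_factor library-size scale factor, default 10,000.
#' @return a `normalized_matrix` with the log-normalized sparse matrix in
#'   `$lognorm` plus the per-cell covariates (`n_umi`, `n_gene`) needed by
#'   [scale_regress()]. `$scaled` is `NULL` until [scale_regress()] runs.
#' @export
lognormalize <- function(x, scale_factor = 10000) {
  stopifnot(inherits(x, "count_matrix"))
  totals <- Matrix::colSums(x$counts)
  if (any(totals == 0)) {
    abort("cells with zero total counts present; run filter_cells() first")
  }
  ln <- x$counts
  if (length(ln@x) > 0) {
    # column index per stored entry of the CsparseMatrix
    col_of <- rep(seq_len(ncol(ln)), diff(ln@p))
    ln@x <- log1p(ln@x * scale_factor / totals[col_of])
  }
  structure(
    list(lognorm = ln, scaled = NULL, scale_factor = scale_factor,
         n_umi = as.numeric(totals),
         n_gene = as.numeric(Matrix::colSums(x$counts > 0)),
         gene_ids = x$gene_ids, barcodes = x$barcodes, group = x$group),
    class = "normalized_matrix"
  )
}

#' Covariate-regressed scaling
#'
#' For each gene, regresses the log-normalized expression on the per-cell
#' total UMIs and detected-gene counts (with intercept), z-scores the
#' residuals, and clips to +/-10 to bound outlier leverage. Genes constant
#' across cells get an all-zero scaled row (recorded in the
#' `"constant_genes"` attribute).
#'
#' @param norm a `normalized_matrix` from [lognormalize()].
#' @param covariates optional data frame with `n_umi` and `n_gene` columns
#'   overriding the ones recorded at normalization.
#' @param clip absolute cap for scaled values.
#' @return `norm` with `$scaled` filled in (dense gene x cell matrix of
#'   residual z-scores).
#' @export
scale_regress <- function(norm, covariates = NULL, clip = 10) {
  stopifnot(inherits(norm, "normalized_matrix"))
  n_umi <- covariates$n_umi %||% norm$n_umi
  n_gene <- covariates$n_gene %||% norm$n_gene
  if (any(!is.finite(n_umi)) || any(!is.finite(n_gene))) {
    stop_field("covariates", "must be finite")
  }
  X <- cbind(1, n_umi, n_gene)
  Y <- t(as.matrix(norm$lognorm))            # cells x genes
  fit <- lm.fit(X, Y)
  res <- t(as.matrix(fit$residuals))         # genes x cells
  sds <- apply(res, 1, sd)
  constant <- sds < .Machine$double.eps^0.5
  sds[constant] <- 1
  scaled <- (res - rowMeans(res)) / sds
  scaled[constant, ] <- 0
  scaled <- pmin(pmax(scaled, -clip), clip)
  dimnames(scaled) <- list(norm$gene_ids, norm$barcodes)
  if (any(constant)) {
    inform(paste0(sum(constant), " constant gene(s) set to scaled 0"))
  }
  norm$scaled <- scaled
  attr(norm, "constant_genes") <- norm$gene_ids[constant]
  norm
}
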