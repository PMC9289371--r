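#' UMI count matrix container
#'
#' Light S3 wrapper around a sparse gene x cell matrix of UMI counts with the
#' per-cell and per-gene annotations the pipeline needs: sample-group labels
#' and mitochondrial-gene flags. All downstream stages (QC, normalization,
#' embedding, marker selection) consume this container.
#'
#' @param counts gene x cell matrix of non-negative integer UMI counts
#'   (dense or `Matrix` sparse; stored as `dgCMatrix`).
#' @param gene_ids character vector of gene identifiers (rows).
#' @param barcodes character vector of unique cell barcodes (columns).
#' @param group per-cell sample-group labels (character or factor).
#' @param mito_flags per-gene logical, `TRUE` for mitochondrial genes.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `gene_ids`, `barcodes`, `group`, `mito_flags`.
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         barcodes = colnames(counts),
                         group = rep("sample", ncol(counts)),
                         mito_flags = rep(FALSE, nrow(counts))) {
  if (is.matrix(counts)) storage.mode(counts) <- "double"
  counts <- Matrix::Matrix(counts, sparse = TRUE) * 1
  counts <- methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%d", seq_len(nrow(counts)))
  if (is.null(barcodes)) barcodes <- sprintf("cell%d", seq_len(ncol(counts)))
  if (length(gene_ids) != nrow(counts)) stop_field("gene_ids", "length must equal nrow(counts)")
  if (length(barcodes) != ncol(counts)) stop_field("barcodes", "length must equal ncol(counts)")
  if (anyDuplicated(barcodes)) stop_field("barcodes", "must be unique")
  if (length(group) != ncol(counts)) stop_field("group", "length must equal ncol(counts)")
  if (length(mito_flags) != nrow(counts)) stop_field("mito_flags", "length must equal nrow(counts)")
  x <- counts@x
  if (any(x < 0) || any(x != floor(x))) stop_field("counts", "must be non-negative integers")
  dimnames(counts) <- list(gene_ids, barcodes)
  structure(
    list(counts = counts, gene_ids = as.character(gene_ids),
         barcodes = as.character(barcodes), group = as.character(group),
         mito_flags = as.logical(mito_flags)),
    class = "count_matrix"
  )
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " genes x ", ncol(x$counts), " cells\n", sep = "")
  cat("  groups: ", paste(names(table(x$group)), collapse = ", "), "\n", sep = "")
  cat("  mito genes: ", sum(x$mito_flags), "\n", sep = "")
  invisible(x)
}

#' Per-cell QC covariates
#'
#' Total UMIs, detected genes, and mitochondrial UMI fraction per cell.
#'
#' @param x a [count_matrix()].
#' @return tibble with columns `barcode`, `group`, `n_umi`, `n_gene`,
#'   `mito_fraction`.
#' @export
cell_stats <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  n_umi <- Matrix::colSums(x$counts)
  n_gene <- Matrix::colSums(x$counts > 0)
  mito <- if (any(x$mito_flags)) {
    Matrix::colSums(x$counts[x$mito_flags, , drop = FALSE])
  } else {
    rep(0, ncol(x$counts))
  }
  tibble(
    barcode = x$barcodes, group = x$group,
    n_umi = as.numeric(n_umi), n_gene = as.numeric(n_gene),
    mito_fraction = ifelse(n_umi > 0, mito / n_umi, 0)
  )
}

# subset cells by logical/integer index, keeping annotations aligned
subset_cells <- function(x, idx) {
  count_matrix(x$counts[, idx, drop = FALSE], x$gene_ids, x$barcodes[idx],
               x$group[idx], x$mito_flags)
}
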