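#' Write a count matrix in the 10x Genomics triplet layout
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate, 1-based indices),
#' `features.tsv` and `barcodes.tsv` into `dir`, plus a `metadata.json`
#' sidecar holding the per-cell group labels and per-gene mitochondrial
#' flags so that [read_10x()] round-trips the full container.
#'
#' @param x a [count_matrix()]; must be non-empty.
#' @param dir output directory; refuses a non-empty existing directory
#'   unless `overwrite = TRUE`.
#' @param overwrite allow writing into a non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_10x <- function(x, dir, overwrite = FALSE) {
  stopifnot(inherits(x, "count_matrix"))
  if (nrow(x$counts) == 0 || ncol(x$counts) == 0) {
    abort("cannot write an empty count matrix")
  }
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    abort(paste0("directory ", dir, " is not empty; use overwrite = TRUE"))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(id = x$gene_ids, name = x$gene_ids, type = "Gene Expression"),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  writeLines(x$barcodes, file.path(dir, "barcodes.tsv"))
  jsonlite::write_json(
    list(group = x$group, mito_flags = x$mito_flags),
    file.path(dir, "metadata.json")
  )
  invisible(dir)
}

#' Read a 10x Genomics triplet directory
#'
#' Inverse of [write_10x()]. The `metadata.json` sidecar is optional; absent
#' it, all cells get one group and no gene is flagged mitochondrial.
#'
#' @param dir directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @return a [count_matrix()].
#' @export
read_10x <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) abort(paste0("no matrix.mtx under ", dir))
  counts <- Matrix::readMM(mtx)
  features <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                                stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  meta_path <- file.path(dir, "metadata.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    group <- meta$group
    mito <- meta$mito_flags
  } else {
    group <- rep("sample", length(barcodes))
    mito <- rep(FALSE, nrow(counts))
  }
  count_matrix(counts, gene_ids = features[[1]], barcodes = barcodes,
               group = group, mito_flags = mito)
}
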