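#' @method tidy ae_model
#' @export
tidy.ae_model <- function(x, ...) x$loss_trace

#' @method glance ae_model
#' @export
glance.ae_model <- function(x, ...) {
  tibble(
    input_dim = x$input_dim, embed_dim = x$config$embed_dim,
    activation = x$config$activation, epochs = x$config$epochs,
    n_cells = x$n_cells,
    final_loss = if (nrow(x$loss_trace)) x$loss_trace$loss[nrow(x$loss_trace)]
                 else NA_real_
  )
}

#' @method tidy sparse_model
#' @export
tidy.sparse_model <- function(x, ...) {
  tibble(gene = x$genes %||% paste0("g", seq_along(x$w)),
         weight = unname(x$w)) |>
    dplyr::arrange(dplyr::desc(abs(.data$weight)))
}

#' @method glance sparse_model
#' @export
glance.sparse_model <- function(x, ...) {
  tibble(
    bias = x$b, C = x$C, norm_type = x$norm_type,
    n_genes = length(x$w), n_nonzero = sum(x$w != 0),
    zero_slack_fraction = x$zero_slack_fraction, objective = x$objective
  )
}

#' @method tidy kdist_curve
#' @export
tidy.kdist_curve <- function(x, ...) x$curve

#' @method glance kdist_curve
#' @export
glance.kdist_curve <- function(x, ...) {
  tibble(k = x$k, epsilon = x$epsilon, weak_elbow = x$weak,
         elbow_rank = x$elbow_rank)
}

#' @export
print.sparse_model <- function(x, ...) {
  cat("<sparse_model> ", x$norm_type, " norm, C = ", x$C, "\n", sep = "")
  cat("  genes: ", length(x$w), " (", sum(x$w != 0), " nonzero)\n", sep = "")
  cat("  zero-slack fraction: ",
      sprintf("%.1f%%", 100 * x$zero_slack_fraction), "\n", sep = "")
  invisible(x)
}

#' @export
print.ae_model <- function(x, ...) {
  cat("<ae_model> ", x$input_dim, " -> ", x$config$embed_dim, " -> ",
      x$input_dim, " (", x$config$activation, ")\n", sep = "")
  invisible(x)
}

#' @export
print.kdist_curve <- function(x, ...) {
  cat("<kdist_curve> k = ", x$k, ", elbow epsilon = ",
      signif(x$epsilon, 4), if (x$weak) " (weak elbow)" else "", "\n", sep = "")
  invisible(x)
}
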