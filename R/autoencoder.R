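#' Select autoencoder input genes by total UMI count
#'
#' The embedding is fit on genes with at least `min_total_umi` summed UMIs
#' across all cells (the rule that yielded the 14,753-gene input space on
#' the original dataset), keeping gene order.
#'
#' @param x a [count_matrix()].
#' @param min_total_umi inclusive threshold on per-gene total UMIs.
#' @return character vector of gene ids.
#' @export
select_input_genes <- function(x, min_total_umi = 1000) {
  stopifnot(inherits(x, "count_matrix"))
  totals <- Matrix::rowSums(x$counts)
  keep <- x$gene_ids[totals >= min_total_umi]
  if (length(keep) == 0) abort("no gene reaches the total-UMI threshold")
  keep
}

#' Autoencoder configuration
#'
#' A three-layer autoencoder (input, 10-dimensional embedded layer, output)
#' trained by full-batch gradient descent on the objective
#' `mean reconstruction error + weight_decay * ||W||^2 + Q`, where `Q` is a
#' KL-divergence sparsity penalty on the mean hidden activation (only
#' meaningful for the sigmoid hidden layer; weight 0 disables it).
#'
#' @param embed_dim embedded-layer width (default 10).
#' @param activation hidden-layer nonlinearity: `"sigmoid"` (default) or
#'   `"linear"` (exactly recoverable against the truncated-SVD optimum).
#' @param weight_decay L2 penalty on all weights (default 0.001).
#' @param sparsity_weight,sparsity_target weight and target rate of the KL
#'   sparsity term `Q`; defaults 0 and 0.05.
#' @param epochs full-batch gradient steps.
#' @param learning_rate step size; `NULL` (default) picks `0.9 / L` with
#'   `L` the curvature scale `2 * ||X||_2^2 / N` estimated by power
#'   iteration.
#' @param momentum heavy-ball momentum coefficient; set 0 for a pure
#'   descent method.
#' @param seed seed for the weight initialization.
#' @return an `ae_config` list.
#' @export
ae_config <- function(embed_dim = 10, activation = c("sigmoid", "linear"),
                      weight_decay = 0.001, sparsity_weight = 0,
                      sparsity_target = 0.05, epochs = 400,
                      learning_rate = NULL, momentum = 0.9, seed = 1L) {
  activation <- match.arg(activation)
  check_count(embed_dim, "embed_dim", min = 1L)
  if (weight_decay < 0) stop_field("weight_decay", "must be >= 0")
  if (sparsity_weight < 0) stop_field("sparsity_weight", "must be >= 0")
  check_prob(sparsity_target, "sparsity_target")
  structure(list(embed_dim = as.integer(embed_dim), activation = activation,
                 weight_decay = weight_decay, sparsity_weight = sparsity_weight,
                 sparsity_target = sparsity_target, epochs = as.integer(epochs),
                 learning_rate = learning_rate, momentum = momentum,
                 seed = as.integer(seed)),
            class = "ae_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Fit a three-layer autoencoder
#'
#' Trains encoder/decoder weights by seeded full-batch gradient descent
#' with momentum, minimizing the mean per-cell squared reconstruction
#' error plus weight decay and the optional sparsity term. The per-epoch
#' loss trace is recorded. Identical seed and data give identical models.
#'
#' @param X gene x cell matrix (typically the scaled matrix restricted to
#'   [select_input_genes()]); cells are the data points.
#' @param config an [ae_config()].
#' @return an `ae_model` with encoder/decoder weights, the config, and the
#'   loss trace (tibble `epoch`, `loss`).
#' @export
fit_autoencoder <- function(X, config = ae_config()) {
  stopifnot(inherits(config, "ae_config"))
  X <- as.matrix(X)
  if (!all(is.finite(X))) abort("X must be finite")
  Xc <- t(X)                                  # cells x genes
  n <- nrow(Xc); p <- ncol(Xc); d <- config$embed_dim
  if (d > p) stop_field("embed_dim", "exceeds the input dimension")

  with_local_seed(config$seed, {
    lim1 <- sqrt(6 / (p + d)); lim2 <- sqrt(6 / (d + p))
    W1 <- matrix(runif(p * d, -lim1, lim1), p, d)
    b1 <- rep(0, d)
    W2 <- matrix(runif(d * p, -lim2, lim2), d, p)
    b2 <- rep(0, p)

    lr <- config$learning_rate
    if (is.null(lr)) {
      # power iteration for ||X||_2^2; curvature of the linear problem
      v <- rnorm(p); v <- v / sqrt(sum(v^2))
      for (i in 1:20) {
        v <- crossprod(Xc, Xc %*% v)
        v <- v / sqrt(sum(v^2))
      }
      L <- 2 * sum((Xc %*% v)^2) / n
      lr <- 0.5 / max(L, .Machine$double.eps)
    }

    lam <- config$weight_decay
    beta <- config$sparsity_weight
    rho <- config$sparsity_target
    mu <- config$momentum
    vW1 <- W1 * 0; vb1 <- b1 * 0; vW2 <- W2 * 0; vb2 <- b2 * 0
    sW1 <- W1; sb1 <- b1; sW2 <- W2; sb2 <- b2
    trace <- numeric(config$epochs)

    for (ep in seq_len(config$epochs)) {
      A <- sweep(Xc %*% W1, 2, b1, "+")
      H <- if (config$activation == "sigmoid") sigmoid(A) else A
      R <- sweep(H %*% W2, 2, b2, "+") - Xc
      loss <- sum(R^2) / n + lam * (sum(W1^2) + sum(W2^2))
      if (beta > 0 && config$activation == "sigmoid") {
        rh <- pmin(pmax(colMeans(H), 1e-8), 1 - 1e-8)
        loss <- loss + beta * sum(rho * log(rho / rh) +
                                  (1 - rho) * log((1 - rho) / (1 - rh)))
      }
      # safeguard against divergence of the heavy-ball iteration: revert
      # the step, halve the rate, and restart the momentum buffers
      if (!is.finite(loss) || (ep > 1 && loss > 4 * min(trace[1:(ep - 1)]))) {
        if (!is.finite(loss) && lr < 1e-12) {
          abort("non-finite training loss; lower the learning rate")
        }
        W1 <- sW1; b1 <- sb1; W2 <- sW2; b2 <- sb2
        vW1 <- W1 * 0; vb1 <- b1 * 0; vW2 <- W2 * 0; vb2 <- b2 * 0
        lr <- lr / 2
        trace[ep] <- if (ep > 1) trace[ep - 1] else loss
        next
      }
      sW1 <- W1; sb1 <- b1; sW2 <- W2; sb2 <- b2
      trace[ep] <- loss

      dY <- 2 * R / n
      gW2 <- crossprod(H, dY) + 2 * lam * W2
      gb2 <- colSums(dY)
      dH <- tcrossprod(dY, W2)
      if (beta > 0 && config$activation == "sigmoid") {
        dH <- sweep(dH, 2, beta * (-rho / rh + (1 - rho) / (1 - rh)) / n, "+")
      }
      dA <- if (config$activation == "sigmoid") dH * H * (1 - H) else dH
      gW1 <- crossprod(Xc, dA) + 2 * lam * W1
      gb1 <- colSums(dA)

      vW1 <- mu * vW1 - lr * gW1; W1 <- W1 + vW1
      vb1 <- mu * vb1 - lr * gb1; b1 <- b1 + vb1
      vW2 <- mu * vW2 - lr * gW2; W2 <- W2 + vW2
      vb2 <- mu * vb2 - lr * gb2; b2 <- b2 + vb2
    }

    structure(
      list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, config = config,
           input_dim = p, n_cells = n,
           loss_trace = tibble(epoch = seq_len(config$epochs), loss = trace),
           gene_ids = rownames(X)),
      class = "ae_model"
    )
  })
}

#' Encode cells into the embedded layer
#'
#' @param model an `ae_model` from [fit_autoencoder()].
#' @param X gene x cell matrix with the model's input dimension.
#' @return cells x embed_dim matrix of embedded coordinates.
#' @export
encode <- function(model, X) {
  stopifnot(inherits(model, "ae_model"))
  X <- as.matrix(X)
  if (nrow(X) != model$input_dim) {
    abort(sprintf("input has %d genes but the model expects %d",
                  nrow(X), model$input_dim))
  }
  A <- sweep(t(X) %*% model$W1, 2, model$b1, "+")
  H <- if (model$config$activation == "sigmoid") sigmoid(A) else A
  rownames(H) <- colnames(X)
  H
}

#' Reconstruct cells through the autoencoder
#'
#' @inheritParams encode
#' @return gene x cell matrix of reconstructions.
#' @export
reconstruct <- function(model, X) {
  H <- encode(model, X)
  t(sweep(H %*% model$W2, 2, model$b2, "+"))
}

#' Serialize / restore an autoencoder model
#'
#' Writes the weights, biases and config to a portable JSON container;
#' [read_ae_model()] restores a model whose [encode()] output matches the
#' original exactly (numbers are serialized at full precision).
#'
#' @param model an `ae_model`.
#' @param path output file.
#' @return `path` (write) or the restored `ae_model` (read).
#' @export
write_ae_model <- function(model, path) {
  stopifnot(inherits(model, "ae_model"))
  obj <- list(
    W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
    config = unclass(model$config), input_dim = model$input_dim,
    n_cells = model$n_cells, gene_ids = model$gene_ids
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_ae_model
#' @export
read_ae_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  config <- ae_config(
    embed_dim = cfg$embed_dim, activation = cfg$activation,
    weight_decay = cfg$weight_decay, sparsity_weight = cfg$sparsity_weight,
    sparsity_target = cfg$sparsity_target, epochs = cfg$epochs,
    learning_rate = cfg$learning_rate, momentum = cfg$momentum, seed = cfg$seed
  )
  structure(
    list(W1 = as.matrix(obj$W1), b1 = as.numeric(obj$b1),
         W2 = as.matrix(obj$W2), b2 = as.numeric(obj$b2),
         config = config, input_dim = obj$input_dim, n_cells = obj$n_cells,
         loss_trace = tibble(epoch = integer(0), loss = numeric(0)),
         gene_ids = obj$gene_ids),
    class = "ae_model"
  )
}
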