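#' Round half away from zero
#'
#' Printed percentages in this package round 0.5 up in magnitude (so
#' 0.485 -> 0.49), not to even as [base::round()] does. Used everywhere a
#' percentage is formatted for a summary table.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(0.485, -0.485, 2.5), 2)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# stop with a message naming the offending argument/field
stop_field <- function(field, msg) {
  abort(paste0("invalid `", field, "`: ", msg), class = "heartscape_validation_error")
}

check_prob <- function(x, field) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_field(field, "must be in [0, 1]")
  }
  invisible(x)
}

check_count <- function(x, field, min = 0L) {
  if (any(!is.finite(x)) || any(x < min) || any(x != floor(x))) {
    stop_field(field, paste0("must be an integer >= ", min))
  }
  invisible(x)
}

# cosine similarity between columns of a matrix
cosine_sim <- function(m) {
  nrm <- sqrt(colSums(m^2))
  nrm[nrm == 0] <- 1
  crossprod(sweep(m, 2, nrm, "/"))
}
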