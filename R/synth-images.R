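#' Generate a synthetic immunofluorescence image with known truth
#'
#' Builds an 8-bit RGB stain image emulating a signal (red) / co-stain
#' (green) / nuclei (blue) immunofluorescence capture. The co-stain channel
#' is 0 on background and well above the segmentation threshold (10) on a
#' planted foreground, so threshold segmentation recovers the true mask
#' exactly. The red channel carries `signal_level` on the foreground plus a
#' background contribution drawn per scenario:
#'
#' * `"zero_inflated"` — background mass concentrated at 0 with sparse
#'   small positives (power-law-like); the correct baseline is 0.
#' * `"homogeneous"` — a single distribution around `background_mean`;
#'   the correct baseline is its mean.
#' * `"multimodal"` — a near-zero mode plus a right mode at
#'   `background_mean`; the correct baseline is the right mode's mean.
#'
#' The same background contribution rides on top of the foreground signal,
#' so subtracting the scenario baseline recovers `signal_level`.
#'
#' @param width,height image size in pixels.
#' @param foreground_fraction fraction of the image area planted as
#'   foreground (the first `round(fraction * height)` pixel rows).
#' @param signal_level planted mean red intensity on the foreground, 0-255.
#' @param background_scenario one of `"zero_inflated"`, `"homogeneous"`,
#'   `"multimodal"`.
#' @param background_mean mean of the (rightmost) background mode; ignored
#'   for the zero-inflated scenario.
#' @param background_sd spread of the homogeneous / rightmost background
#'   mode; 0 gives an exactly constant background.
#' @param seed integer seed.
#' @return list with `image` (a [stain_image()]) and `truth` (mask,
#'   scenario, planted signal, true baseline, and a `degenerate` flag when
#'   the requested foreground is empty).
#' @export
generate_if_image <- function(width = 128, height = 128,
                              foreground_fraction = 0.5,
                              signal_level = 100,
                              background_scenario = c("zero_inflated",
                                                      "homogeneous",
                                                      "multimodal"),
                              background_mean = 50,
                              background_sd = 3,
                              seed = 1L) {
  background_scenario <- match.arg(background_scenario)
  if (signal_level < 0 || signal_level > 255) {
    stop_field("signal_level", "must be in [0, 255]")
  }
  check_prob(foreground_fraction, "foreground_fraction")
  with_local_seed(seed, {
    n <- width * height
    fg_rows <- round(foreground_fraction * height)
    mask <- matrix(FALSE, nrow = height, ncol = width)
    if (fg_rows > 0) mask[seq_len(fg_rows), ] <- TRUE
    degenerate <- fg_rows == 0
    if (degenerate) warn("requested foreground is empty; truth flags the image degenerate")

    bg_draw <- switch(background_scenario,
      zero_inflated = {
        v <- numeric(n)
        pos <- runif(n) < 0.05
        v[pos] <- sample(1:8, sum(pos), replace = TRUE)
        list(values = v, baseline = 0)
      },
      homogeneous = {
        list(values = rnorm(n, background_mean, background_sd),
             baseline = background_mean)
      },
      multimodal = {
        # background mixes true-dark pixels with a haze mode; the haze
        # (rightmost mode) is what also rides on the foreground
        right <- runif(n) < 0.45
        v <- abs(rnorm(n, 0, 1.5))
        v[right] <- rnorm(sum(right), background_mean, background_sd)
        list(values = v, baseline = background_mean,
             fg_extra = rnorm(n, background_mean, background_sd))
      }
    )
    bg <- matrix(bg_draw$values, nrow = height, ncol = width)
    fg_extra <- matrix(bg_draw$fg_extra %||% bg_draw$values,
                       nrow = height, ncol = width)
    red <- bg
    red[mask] <- fg_extra[mask] + signal_level
    red <- pmin(pmax(round(red), 0), 255)

    green <- matrix(0L, height, width)
    green[mask] <- 180L + matrix(sample(0:60, n, replace = TRUE), height, width)[mask]
    green <- pmin(green, 255L)

    blue <- matrix(0L, height, width)
    nuclei <- sample.int(n, max(1, round(0.02 * n)))
    blue[nuclei] <- 200L

    img <- stain_image(red = red, green = green, blue = blue)
    truth <- list(mask = mask, scenario = background_scenario,
                  signal_level = signal_level,
                  baseline = bg_draw$baseline, degenerate = degenerate)
    list(image = img, truth = truth)
  })
}
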