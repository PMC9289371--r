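#' RGB stain image container
#'
#' Three integer channel matrices in `[0, 255]` with fixed roles: red =
#' signal stain, green = co-stain defining the region of interest,
#' blue = nuclei.
#'
#' @param red,green,blue equal-dimension matrices of integers in
#'   `[0, 255]`.
#' @return a `stain_image` list.
#' @export
stain_image <- function(red, green, blue = matrix(0L, nrow(red), ncol(red))) {
  red <- as.matrix(red); green <- as.matrix(green); blue <- as.matrix(blue)
  if (!identical(dim(red), dim(green)) || !identical(dim(red), dim(blue))) {
    stop_field("channels", "must share dimensions")
  }
  for (ch in list(red, green, blue)) {
    if (any(ch < 0) || any(ch > 255) || any(ch != floor(ch))) {
      stop_field("channels", "values must be integers in [0, 255]")
    }
  }
  structure(list(red = red, green = green, blue = blue,
                 roles = c(red = "signal", green = "costain", blue = "nuclei")),
            class = "stain_image")
}

#' Read / write a stain image as 8-bit RGB PNG
#'
#' @param path PNG file.
#' @param image a [stain_image()].
#' @return [read_stain_png()] returns a [stain_image()];
#'   [write_stain_png()] returns `path` invisibly.
#' @export
read_stain_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) abort("package png required")
  arr <- png::readPNG(path)
  if (length(dim(arr)) != 3 || dim(arr)[3] < 3) abort("need an RGB PNG")
  stain_image(round(arr[, , 1] * 255), round(arr[, , 2] * 255),
              round(arr[, , 3] * 255))
}

#' @rdname read_stain_png
#' @export
write_stain_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE)) abort("package png required")
  stopifnot(inherits(image, "stain_image"))
  arr <- array(0, dim = c(nrow(image$red), ncol(image$red), 3))
  arr[, , 1] <- image$red / 255
  arr[, , 2] <- image$green / 255
  arr[, , 3] <- image$blue / 255
  png::writePNG(arr, path)
  invisible(path)
}

#' Segment the co-stain foreground
#'
#' Foreground = pixels whose green (co-stain) channel exceeds the
#' threshold; green exactly at the threshold is background (strict `>`,
#' resolving the boundary the `>10` / `<10` rule leaves open).
#'
#' @param image a [stain_image()].
#' @param threshold green-channel cutoff (default 10).
#' @return logical mask matrix.
#' @export
segment_foreground <- function(image, threshold = 10) {
  stopifnot(inherits(image, "stain_image"))
  image$green > threshold
}

#' Background baseline and scenario of the signal channel
#'
#' Classifies the background red-value distribution into one of three
#' scenarios and returns the matching baseline:
#'
#' 1. zero-concentrated with a sparse tail (power-law-like): baseline 0 —
#'    called when at least `zero_mass` of the pixels are <= 2;
#' 2. a single homogeneous distribution: baseline = its mean;
#' 3. two or more separated modes: baseline = mean of the rightmost mode —
#'    called when the smoothed histogram has >= 2 peaks separated by a
#'    valley below `valley_ratio` of the smaller peak.
#'
#' An ambiguous histogram (multiple candidate readings) is flagged in the
#' result rather than silently resolved; a manual scenario override is
#' accepted.
#'
#' @param background numeric vector of background red values (>= 100
#'   pixels).
#' @param zero_mass scenario-1 trigger: minimum fraction of pixels <= 2.
#' @param valley_ratio scenario-3 trigger: valley depth relative to the
#'   smaller neighboring peak.
#' @param override optional scenario name to force
#'   (`"zero_inflated"`, `"homogeneous"`, `"multimodal"`).
#' @return list with `baseline`, `scenario`, `ambiguous`.
#' @export
background_baseline <- function(background, zero_mass = 0.8,
                                valley_ratio = 0.2, override = NULL) {
  background <- as.numeric(background)
  if (length(background) < 100) abort("need at least 100 background pixels")
  scen <- NULL
  ambiguous <- FALSE

  near_zero <- mean(background <= 2)
  # smoothed histogram over the 0-255 range for mode detection
  h <- density(background, bw = 3, from = 0, to = 255, n = 256)
  yv <- h$y
  peaks <- which(diff(sign(diff(c(-Inf, yv, -Inf)))) == -2)
  peaks <- peaks[yv[peaks] >= 0.01 * max(yv)]  # ignore numerical-noise bumps
  modes_split <- NULL
  if (length(peaks) >= 2) {
    # examine valleys between consecutive retained peaks
    for (i in seq_len(length(peaks) - 1)) {
      lo <- peaks[i]; hi <- peaks[i + 1]
      valley <- which.min(yv[lo:hi]) + lo - 1
      small_peak <- min(yv[lo], yv[hi])
      if (small_peak > 0 && yv[valley] < valley_ratio * small_peak) {
        modes_split <- c(modes_split, h$x[valley])
      }
    }
  }

  if (!is.null(override)) {
    scen <- match.arg(override, c("zero_inflated", "homogeneous", "multimodal"))
  } else if (near_zero >= zero_mass) {
    scen <- "zero_inflated"
    ambiguous <- length(modes_split) > 0
  } else if (length(modes_split) > 0) {
    scen <- "multimodal"
  } else {
    scen <- "homogeneous"
  }

  baseline <- switch(scen,
    zero_inflated = 0,
    homogeneous = mean(background),
    multimodal = {
      cut <- if (length(modes_split) > 0) max(modes_split) else
        stats::median(background)
      mean(background[background > cut])
    }
  )
  list(baseline = baseline, scenario = scen, ambiguous = ambiguous)
}

#' Mean adjusted foreground intensity
#'
#' Mean over the mask of `max(red - baseline, 0)`; negative adjusted
#' values clamp to 0 so the result stays in `[0, 255]`.
#'
#' @param image a [stain_image()].
#' @param mask logical foreground mask (non-empty).
#' @param baseline background baseline to subtract.
#' @return mean adjusted intensity.
#' @export
foreground_intensity <- function(image, mask, baseline = 0) {
  stopifnot(inherits(image, "stain_image"))
  if (!any(mask)) abort("empty foreground mask")
  mean(pmax(image$red[mask] - baseline, 0))
}

#' Quantify one stain image end to end
#'
#' Segmentation (green > threshold), background-scenario baseline from
#' the background red values, and mean adjusted foreground intensity.
#'
#' @param image a [stain_image()].
#' @param green_threshold segmentation threshold.
#' @param override optional scenario override for
#'   [background_baseline()].
#' @return tibble with `scenario`, `baseline`, `intensity`,
#'   `foreground_fraction`, `ambiguous`.
#' @export
quantify_image <- function(image, green_threshold = 10, override = NULL) {
  mask <- segment_foreground(image, green_threshold)
  bg <- background_baseline(image$red[!mask], override = override)
  tibble(
    scenario = bg$scenario, baseline = bg$baseline,
    intensity = foreground_intensity(image, mask, bg$baseline),
    foreground_fraction = mean(mask), ambiguous = bg$ambiguous
  )
}

#' Wilcoxon rank-sum comparison of image-intensity groups
#'
#' Exact two-sided p for small samples (both groups <= 10, no ties);
#' normal approximation with tie correction otherwise. Fully tied input
#' returns p = 1 with a note instead of failing.
#'
#' @param a,b numeric intensity vectors (>= 3 each).
#' @param alpha significance level for the `significant` flag.
#' @return tibble `p_value`, `significant`, `method`, `note`.
#' @export
rank_sum_test <- function(a, b, alpha = 0.05) {
  if (length(a) < 3 || length(b) < 3) abort("each group needs >= 3 images")
  if (length(unique(c(a, b))) == 1) {
    return(tibble(p_value = 1, significant = FALSE, method = "degenerate",
                  note = "all values tied"))
  }
  ties <- anyDuplicated(c(a, b)) > 0
  if (length(a) <= 10 && length(b) <= 10 && !ties) {
    wt <- wilcox.test(a, b, exact = TRUE)
    method <- "exact"
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    method <- "normal approximation (tie-corrected)"
  }
  tibble(p_value = wt$p.value, significant = wt$p.value < alpha,
         method = method, note = NA_character_)
}
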