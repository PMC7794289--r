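#' Wrap a closed-form probability function as a saliency model
#'
#' For testing and analysis, any function mapping a batch of row-major
#' flattened images (matrix, one row per image) to the probability of the
#' explained label can serve as the model under occlusion.
#'
#' @param fun `function(X)` returning a numeric probability per row.
#' @param label the class label the probability refers to.
#' @return an object of class `prob_model`.
#' @export
prob_model <- function(fun, label = "AD") {
  stopifnot(is.function(fun))
  structure(list(fun = fun, label = label), class = "prob_model")
}

# probability of `label` for a batch of flattened maps, for both model kinds
.label_prob <- function(model, X, label) {
  if (inherits(model, "prob_model")) return(model$fun(X))
  if (inherits(model, "ad_classifier")) {
    out <- numeric(nrow(X))
    for (i in seq(1, nrow(X), by = 2048)) {      # chunk large batches
      j <- min(i + 2047, nrow(X))
      out[i:j] <- predict_prob_matrix(model, X[i:j, , drop = FALSE])[, label]
    }
    return(out)
  }
  stop("model must be an ad_classifier or a prob_model")
}

# the class whose probability the scan tracks: the model's predicted class
# for the unoccluded image
.explained_label <- function(model, xrow) {
  if (inherits(model, "prob_model")) return(model$label)
  pr <- predict_prob_matrix(model, matrix(xrow, nrow = 1))
  colnames(pr)[which.max(pr)]
}

#' Single-scale occlusion scan
#'
#' Slides a `window x window` blackout patch (stride 1) over every position
#' fully inside the image, computing the drop in the model's probability for
#' its predicted label, `p(label | original) - p(label | occluded)`, and
#' storing it at the window's central pixel (offset `floor((window - 1) / 2)`
#' from the top-left corner). Occluding an all-zero region is a no-op and
#' yields exactly zero. Border pixels never covered by a window center are
#' `NA` in the raw map.
#'
#' @param model an [fit_ad_classifier()] or [prob_model()].
#' @param v a [vessel_map()] or matrix at the model's input resolution.
#' @param window patch side length, `1 <= window <= image side`.
#' @param label optional label to track; defaults to the model's predicted
#'   class for `v`.
#' @return numeric matrix of raw (signed) saliency with `NA` at uncovered
#'   positions; attributes `window`, `label`, `p_original`.
#' @export
occlusion_scan <- function(model, v, window, label = NULL) {
  px <- map_pixels(v)
  n <- nrow(px); p <- ncol(px)
  if (window < 1 || window > min(n, p))
    stop("window must be between 1 and the image side")
  x0 <- .flatten(px)
  if (is.null(label)) label <- .explained_label(model, x0)
  p0 <- .label_prob(model, matrix(x0, nrow = 1), label)
  npos_r <- n - window + 1L; npos_c <- p - window + 1L
  npos <- npos_r * npos_c
  X <- matrix(rep(x0, each = npos), nrow = npos)
  # flattened (row-major) indices of the occluded patch at each position
  pos <- 0L
  for (i in seq_len(npos_r)) {
    rows <- (i:(i + window - 1L)) - 1L
    base <- rep(rows * p, each = window)
    for (j in seq_len(npos_c)) {
      pos <- pos + 1L
      X[pos, base + (j:(j + window - 1L))] <- 0
    }
  }
  pocc <- .label_prob(model, X, label)
  off <- (window - 1L) %/% 2L
  raw <- matrix(NA_real_, n, p)
  raw[cbind(rep(seq_len(npos_r) + off, each = npos_c),
            rep(seq_len(npos_c) + off, npos_r))] <- p0 - pocc
  attr(raw, "window") <- window
  attr(raw, "label") <- label
  attr(raw, "p_original") <- p0
  raw
}

#' Min-max normalize a raw occlusion map
#'
#' Normalizes the evaluated positions to `[0, 1]`; a constant raw map
#' normalizes to all zeros (convention), and uncovered border positions
#' (`NA`) are filled with 0 so scales can be averaged.
#'
#' @param raw matrix from [occlusion_scan()].
#' @return numeric matrix in `[0, 1]`, no `NA`.
#' @export
normalize_scale <- function(raw) {
  obs <- !is.na(raw)
  stopifnot(all(is.finite(raw[obs])))
  out <- matrix(0, nrow(raw), ncol(raw))
  if (any(obs)) {
    lo <- min(raw[obs]); hi <- max(raw[obs])
    if (hi > lo) out[obs] <- (raw[obs] - lo) / (hi - lo)
  }
  out
}

#' Multi-scale occlusion saliency map
#'
#' Runs [occlusion_scan()] and [normalize_scale()] at each window scale and
#' averages the normalized maps per pixel. The default scales 1, 2, 4, 8
#' probe importance from single pixels up to small neighbourhoods; larger
#' windows (e.g. 32) can be added through `scales`. All scales track the
#' same label: the model's predicted class for the unoccluded map.
#'
#' @param model an [fit_ad_classifier()] or [prob_model()].
#' @param v a [vessel_map()] or matrix.
#' @param scales vector of window sizes (default `c(1, 2, 4, 8)`).
#' @return object of class `saliency_result`: `values` (matrix in `[0, 1]`),
#'   `scales_used`, `label_explained`, `raw_maps` (per-scale raw maps).
#' @export
saliency_map <- function(model, v, scales = c(1, 2, 4, 8)) {
  px <- map_pixels(v)
  if (length(scales) == 0 || any(scales < 1) || any(scales > min(dim(px))))
    stop("invalid scale list")
  label <- .explained_label(model, .flatten(px))
  raws <- lapply(scales, function(k) occlusion_scan(model, px, k, label))
  norm <- lapply(raws, normalize_scale)
  values <- Reduce(`+`, norm) / length(norm)
  structure(list(values = values, scales_used = scales,
                 label_explained = label, raw_maps = raws),
            class = "saliency_result")
}

#' Write a saliency map (and optional green overlay) as PNG
#'
#' @param s a [saliency_map()] result.
#' @param path grayscale PNG path for the saliency values.
#' @param overlay_path optional RGB overlay path; salient pixels are shown
#'   in green over the source map.
#' @param v source vessel map for the overlay.
#' @return `path`, invisibly.
#' @export
write_saliency_png <- function(s, path, overlay_path = NULL, v = NULL) {
  stopifnot(inherits(s, "saliency_result"))
  png::writePNG(s$values, target = path)
  if (!is.null(overlay_path)) {
    stopifnot(!is.null(v))
    base <- map_pixels(v)
    rgb <- array(0, c(dim(base), 3))
    rgb[, , 1] <- base * (1 - s$values)
    rgb[, , 2] <- pmin(1, base + s$values)   # green marks salient pixels
    rgb[, , 3] <- base * (1 - s$values)
    png::writePNG(rgb, target = overlay_path)
  }
  invisible(path)
}
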