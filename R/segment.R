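#' Segmentation configuration
#'
#' @param scales vesselness filter scales (Gaussian sigmas, pixels); the
#'   defaults span the caliber range of the synthetic vascular trees.
#' @param low_threshold,high_threshold hysteresis thresholds on the
#'   max-normalized vesselness response, `low <= high`, both in `[0, 1]`.
#' @param backend `"classical"` (multiscale vesselness, the default) or
#'   `"external"` (delegate to a user-supplied callable, e.g. a trained
#'   deep segmentation model, via the `backend_fun` argument of
#'   [segment_vessels()]).
#' @return an object of class `segmentation_config`.
#' @export
segmentation_config <- function(scales = c(1, 2, 4),
                                low_threshold = 0.08,
                                high_threshold = 0.25,
                                backend = c("classical", "external")) {
  backend <- match.arg(backend)
  stopifnot(length(scales) > 0, all(scales > 0),
            low_threshold >= 0, high_threshold <= 1,
            low_threshold <= high_threshold)
  structure(list(scales = scales, low_threshold = low_threshold,
                 high_threshold = high_threshold, backend = backend),
            class = "segmentation_config")
}

# Replicated-edge shifts for finite differences.
.shift_r <- function(m, d) {
  n <- nrow(m)
  idx <- pmin(pmax(seq_len(n) + d, 1), n)
  m[idx, , drop = FALSE]
}
.shift_c <- function(m, d) {
  p <- ncol(m)
  idx <- pmin(pmax(seq_len(p) + d, 1), p)
  m[, idx, drop = FALSE]
}

# Frangi-style vesselness for dark ridges at one scale (sigma in pixels):
# Hessian of the Gaussian-smoothed image, scale-normalized by sigma^2,
# eigenvalues ordered by magnitude; ridge response gated on lambda2 > 0
# (dark structure on bright background).
.vesselness_scale <- function(img, sigma, beta = 0.5) {
  sm <- EBImage::gblur(img, sigma = sigma)
  ixx <- (.shift_c(sm, 1) - 2 * sm + .shift_c(sm, -1)) * sigma^2
  iyy <- (.shift_r(sm, 1) - 2 * sm + .shift_r(sm, -1)) * sigma^2
  ixy <- (.shift_r(.shift_c(sm, 1), 1) - .shift_r(.shift_c(sm, -1), 1) -
            .shift_r(.shift_c(sm, 1), -1) +
            .shift_r(.shift_c(sm, -1), -1)) / 4 * sigma^2
  tmp <- sqrt(((ixx - iyy) / 2)^2 + ixy^2)
  mu <- (ixx + iyy) / 2
  e1 <- mu - tmp; e2 <- mu + tmp
  swap <- abs(e1) > abs(e2)           # order so |l1| <= |l2|
  l1 <- ifelse(swap, e2, e1)
  l2 <- ifelse(swap, e1, e2)
  s2 <- l1^2 + l2^2
  cmax <- sqrt(max(s2))
  if (cmax < 1e-12) return(matrix(0, nrow(img), ncol(img)))
  rb2 <- (l1 / ifelse(abs(l2) < 1e-12, 1e-12, l2))^2
  v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * (0.5 * cmax)^2)))
  v[l2 <= 0] <- 0                     # keep dark-on-bright ridges only
  v
}

#' Segment retinal vessels from a fundus image
#'
#' Classical backend: a multiscale ridge (vesselness) response over
#' `cfg$scales` is max-combined, normalized, restricted to the interior of
#' the camera disc, and hysteresis-thresholded; connected weak components are
#' kept only if they touch a strong pixel. Accepted pixels carry graded
#' confidence in `[0.5, 1]` (so binarizing at 0.5 recovers the hysteresis
#' mask); rejected pixels are 0. External backend: delegates to
#' `backend_fun(img)`, which must return a matrix of the same dimensions
#' with values in `[0, 1]`.
#'
#' @param img a [fundus_image()] or matrix in `[0, 1]` (dark vessels on a
#'   bright disc).
#' @param cfg a [segmentation_config()].
#' @param backend_fun callable for `backend = "external"`.
#' @return a [vessel_map()] with the same dimensions as `img`.
#' @export
segment_vessels <- function(img, cfg = segmentation_config(),
                            backend_fun = NULL) {
  stopifnot(inherits(cfg, "segmentation_config"))
  m <- map_pixels(img)
  if (cfg$backend == "external") {
    stopifnot(is.function(backend_fun))
    out <- backend_fun(img)
    out <- map_pixels(out)
    if (!identical(dim(out), dim(m)))
      stop("external segmentation backend returned mismatched dimensions")
    if (min(out) < 0 || max(out) > 1)
      stop("external segmentation backend returned values outside [0, 1]")
    return(vessel_map(out))
  }
  v <- matrix(0, nrow(m), ncol(m))
  for (s in cfg$scales) v <- pmax(v, .vesselness_scale(m, s))
  if (max(v) > 0) v <- v / max(v)
  # the ridge response peaks on vessel centerlines; a background-subtraction
  # darkness map recovers the full caliber around accepted centerlines
  bg <- EBImage::gblur(m, sigma = 2 * max(cfg$scales))
  dk <- pmin(pmax(bg - m, 0), 1)
  if (max(dk) > 0) dk <- dk / max(dk)
  # confine to the disc interior: the rim of the camera aperture is itself a
  # strong ridge, so erode the bright-disc mask slightly. The threshold is
  # relative to the intensity range (shift-equivariant) and dark vessel
  # pixels inside the disc are recovered by hole filling.
  rng <- range(m)
  disc <- m > rng[1] + 0.5 * diff(rng)
  if (any(disc) && !all(disc)) {
    disc <- EBImage::fillHull(disc + 0) > 0
    disc <- EBImage::erode(disc + 0, EBImage::makeBrush(7L, "disc")) > 0
  }
  v[!disc] <- 0
  strong <- v >= cfg$high_threshold
  weak <- (v >= cfg$low_threshold | dk >= 0.35) & disc
  out <- matrix(0, nrow(m), ncol(m))
  if (any(strong)) {
    lab <- EBImage::bwlabel(weak + 0)
    keep_ids <- setdiff(unique(lab[strong]), 0)
    keep <- matrix(lab %in% keep_ids, nrow(m), ncol(m))
    conf <- pmax(v, dk)
    if (any(keep)) out[keep] <- 0.5 + 0.5 * conf[keep] / max(conf[keep])
  }
  vessel_map(out)
}
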