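#' Simulation configuration for the synthetic fundus study
#'
#' Bundles the knobs of the synthetic data generator: the raster size of the
#' vessel maps, the cohort layout (cases and matched-control multiplicity),
#' the vascular-tree morphology depth, the planted group effect on small
#' vessels, and additive pixel noise.
#'
#' @param image_size pixels per side of the square raster (>= 32).
#' @param n_ad number of Alzheimer's disease (AD) subjects (>= 2).
#' @param n_controls_per_ad matched normal-control (NC) subjects generated per
#'   AD subject; the default 5 yields five redundant control groups.
#' @param branch_depth recursion depth of the vascular tree; 0 draws only the
#'   major branches.
#' @param small_vessel_effect multiplier in `[0, 1]` applied to small-vessel
#'   caliber and spawn probability in the AD group; 1 means no group
#'   difference (a null cohort), smaller values thin out the AD small-vessel
#'   bed.
#' @param pixel_noise_sd standard deviation of additive Gaussian pixel noise
#'   (intensity units; maps are clipped back to `[0, 1]`).
#' @param seed base RNG seed for the configuration.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(image_size = 128L,
                              n_ad = 20L,
                              n_controls_per_ad = 5L,
                              branch_depth = 3L,
                              small_vessel_effect = 1,
                              pixel_noise_sd = 0.02,
                              seed = 1L) {
  stopifnot(
    image_size >= 32,
    n_ad >= 2,
    n_controls_per_ad >= 1,
    branch_depth >= 0,
    small_vessel_effect >= 0, small_vessel_effect <= 1,
    pixel_noise_sd >= 0
  )
  structure(
    list(
      image_size = as.integer(image_size),
      n_ad = as.integer(n_ad),
      n_controls_per_ad = as.integer(n_controls_per_ad),
      branch_depth = as.integer(branch_depth),
      small_vessel_effect = small_vessel_effect,
      pixel_noise_sd = pixel_noise_sd,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Construct a vessel map
#'
#' A vessel map is a 2-D grid of intensities in `[0, 1]` (row-major, vessels
#' bright on dark background) plus light metadata. Most package functions
#' also accept a bare numeric matrix where a vessel map is expected.
#'
#' @param pixels numeric matrix with values in `[0, 1]`.
#' @param image_id identifier of the source image.
#' @param eye `"left"` or `"right"` (or `NA`).
#' @param meta optional named list of extra metadata.
#' @return an object of class `vessel_map`.
#' @export
vessel_map <- function(pixels, image_id = NA_character_, eye = NA_character_,
                       meta = list()) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)),
            min(pixels) >= 0, max(pixels) <= 1)
  structure(
    list(pixels = pixels, image_id = image_id, eye = eye, meta = meta),
    class = "vessel_map"
  )
}

#' Extract the pixel matrix from a vessel map or matrix
#' @param x a `vessel_map`, `fundus_image`, or numeric matrix.
#' @return numeric matrix.
#' @export
map_pixels <- function(x) {
  if (inherits(x, "vessel_map") || inherits(x, "fundus_image")) x$pixels
  else if (is.matrix(x)) x
  else stop("expected a vessel_map, fundus_image, or matrix")
}

clip01 <- function(x) pmin(pmax(x, 0), 1)  # argument order keeps dim attributes

# Rasterize a branch: walk from (r, c) at `angle`, length `len` steps, with a
# random-walk heading, painting a disc of diameter `caliber` at each step.
# Returns the updated canvas and the list of spawn sites recorded en route.
.draw_branch <- function(canvas, r, c, angle, caliber, len, wiggle,
                         spawn_prob, record_spawns = TRUE) {
  n <- nrow(canvas)
  rad <- max(0.5, caliber / 2)
  irad <- ceiling(rad)
  rmax <- 0.44 * n                    # keep the tree inside the camera disc
  spawns <- list()
  for (step in seq_len(len)) {
    angle <- angle + stats::rnorm(1, 0, wiggle)
    r <- r + sin(angle)
    c <- c + cos(angle)
    if ((r - n / 2)^2 + (c - n / 2)^2 > rmax^2) break
    ri <- round(r); ci <- round(c)
    rr <- max(1, ri - irad):min(n, ri + irad)
    cc <- max(1, ci - irad):min(n, ci + irad)
    d2 <- outer((rr - r)^2, (cc - c)^2, `+`)
    canvas[rr, cc][d2 <= rad^2] <- 1
    if (record_spawns && stats::runif(1) < spawn_prob) {
      side <- if (stats::runif(1) < 0.5) 1 else -1
      spawns[[length(spawns) + 1]] <-
        list(r = r, c = c, angle = angle + side * stats::runif(1, 0.5, 1.1))
    }
  }
  list(canvas = canvas, spawns = spawns)
}

#' Generate a synthetic retinal vascular tree
#'
#' Draws a branching tree raster: a few thick "major" branches radiating from
#' an optic-disc-like origin, plus recursively spawned thin branches whose
#' caliber tapers with depth. For `group = "AD"` the thin-branch caliber and
#' spawn probability are multiplied by `config$small_vessel_effect`, planting
#' a group difference confined to small vessels; major branches are drawn
#' identically in distribution for both groups. With
#' `small_vessel_effect = 1` the two groups are pixel-identical under the
#' same seed.
#'
#' @param config a [simulation_config()].
#' @param group `"AD"` or `"NC"`.
#' @param seed integer RNG seed; identical `(config, group, seed)` gives a
#'   bit-identical map.
#' @return a [vessel_map()] whose `meta` records `n_foreground` and `n_thin`
#'   (pixels contributed by branches of caliber <= 2, before noise).
#' @export
generate_vessel_tree <- function(config, group = c("NC", "AD"), seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  group <- match.arg(group)
  n <- config$image_size
  effect <- if (group == "AD") config$small_vessel_effect else 1
  with_seed(seed, {
    canvas <- matrix(0, n, n)
    thin_canvas <- matrix(0, n, n)
    # optic-disc-like origin on the left third, four major branches arcing out
    r0 <- n / 2 + stats::rnorm(1, 0, n / 40)
    c0 <- n * 0.18 + stats::rnorm(1, 0, n / 50)
    major_angles <- c(-1.1, -0.45, 0.45, 1.1) + stats::rnorm(4, 0, 0.12)
    major_caliber <- 3.2
    # queue of branches: depth 0 = major
    queue <- lapply(major_angles, function(a) {
      list(r = r0, c = c0, angle = a, depth = 0L)
    })
    while (length(queue) > 0) {
      b <- queue[[1]]; queue <- queue[-1]
      is_major <- b$depth == 0L
      caliber <- major_caliber * 0.55^b$depth
      thin <- caliber <= 2
      base_spawn <- if (is_major) 0.10 else 0.06
      spawn_mult <- if (thin || caliber * 0.55 <= 2) effect else 1
      if (thin) caliber <- caliber * effect
      len <- round(if (is_major) n * stats::runif(1, 0.6, 0.9)
                   else n * stats::runif(1, 0.15, 0.4) * 0.8^(b$depth - 1))
      can_spawn <- b$depth < config$branch_depth
      res <- .draw_branch(
        if (thin) thin_canvas else canvas,
        b$r, b$c, b$angle, caliber, len,
        wiggle = if (is_major) 0.10 else 0.16,
        spawn_prob = if (can_spawn) base_spawn * spawn_mult else 0,
        record_spawns = can_spawn
      )
      if (thin) thin_canvas <- res$canvas else canvas <- res$canvas
      for (s in res$spawns) {
        queue[[length(queue) + 1]] <-
          list(r = s$r, c = s$c, angle = s$angle, depth = b$depth + 1L)
      }
    }
    raster <- pmax(canvas, thin_canvas)
    n_fg <- sum(raster > 0)
    n_thin <- sum(thin_canvas > 0 & canvas == 0)
    pixels <- raster
    if (config$pixel_noise_sd > 0) {
      pixels <- clip01(pixels + stats::rnorm(n * n, 0, config$pixel_noise_sd))
    }
    vessel_map(pixels, meta = list(group = group, n_foreground = n_fg,
                                   n_thin = n_thin, seed = seed))
  })
}

#' Construct a fundus image
#'
#' @param pixels numeric matrix in `[0, 1]`.
#' @param quality_label `"sufficient"`, `"insufficient"`, or `"unknown"`.
#' @param fault one of `"none"`, `"exposure"`, `"focus"`, `"composition"`,
#'   `"artifact"`.
#' @param severity fault severity in `[0, 1]`.
#' @return an object of class `fundus_image`.
#' @export
fundus_image <- function(pixels, quality_label = "unknown", fault = "none",
                         severity = 0) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)),
            min(pixels) >= 0, max(pixels) <= 1,
            quality_label %in% c("sufficient", "insufficient", "unknown"),
            fault %in% c("none", "exposure", "focus", "composition",
                         "artifact"))
  structure(list(pixels = pixels, quality_label = quality_label,
                 fault = fault, severity = severity),
            class = "fundus_image")
}

# Render disc + vignette background with dark vessels at the given center.
.render_base <- function(vessels, center_r, center_c) {
  n <- nrow(vessels)
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  d <- sqrt((rr - center_r)^2 + (cc - center_c)^2) / (n * 0.48)
  bg <- ifelse(d <= 1, 0.85 * (1 - 0.35 * d^2), 0.02)
  clip01(bg - 0.55 * vessels * (d <= 1))
}

#' Render a fundus photograph from a vessel map
#'
#' Composites the vessel tree (dark vessels) onto a bright circular disc with
#' radial vignetting, then optionally applies one of four quality-degrading
#' fault operators: `exposure` (global intensity shift with clipping, over- or
#' under-exposed at random), `focus` (Gaussian blur), `composition` (disc
#' translated partly out of frame), `artifact` (random bright blobs and
#' streaks). `fault = "none"` or `severity = 0` returns an undegraded
#' rendering labeled `sufficient`.
#'
#' @param v a [vessel_map()] or matrix.
#' @param fault fault kind.
#' @param severity in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return a [fundus_image()].
#' @export
render_fundus <- function(v, fault = c("none", "exposure", "focus",
                                       "composition", "artifact"),
                          severity = 0, seed = 1L) {
  fault <- match.arg(fault)
  stopifnot(severity >= 0, severity <= 1)
  vessels <- map_pixels(v)
  n <- nrow(vessels)
  if (fault == "none" || severity == 0) {
    img <- .render_base(vessels, n / 2, n / 2)
    return(fundus_image(img, "sufficient", "none", 0))
  }
  with_seed(seed, {
    if (fault == "composition") {
      theta <- stats::runif(1, 0, 2 * pi)
      dr <- severity * 0.6 * n * sin(theta)
      dc <- severity * 0.6 * n * cos(theta)
      sh <- .shift_matrix(vessels, round(dr), round(dc))
      img <- .render_base(sh, n / 2 + dr, n / 2 + dc)
    } else {
      img <- .render_base(vessels, n / 2, n / 2)
      if (fault == "exposure") {
        dir <- if (stats::runif(1) < 0.5) 1 else -1
        img <- clip01(img + dir * 0.9 * severity)
      } else if (fault == "focus") {
        img <- clip01(EBImage::gblur(img, sigma = 0.5 + 4 * severity))
      } else if (fault == "artifact") {
        k <- ceiling(8 * severity)
        rr <- matrix(seq_len(n), n, n)
        cc <- matrix(seq_len(n), n, n, byrow = TRUE)
        for (i in seq_len(k)) {
          br <- stats::runif(1, 1, n); bc <- stats::runif(1, 1, n)
          sr <- stats::runif(1, n / 40, n / 10)
          elong <- stats::runif(1, 1, 6)   # > 1 gives a streak
          theta <- stats::runif(1, 0, pi)
          u <- (rr - br) * cos(theta) + (cc - bc) * sin(theta)
          w <- -(rr - br) * sin(theta) + (cc - bc) * cos(theta)
          blob <- exp(-(u^2 / (elong * sr)^2 + w^2 / sr^2))
          img <- clip01(img + 0.7 * severity * blob)
        }
      }
    }
    fundus_image(img, "insufficient", fault, severity)
  })
}

.shift_matrix <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(0, n, p)
  rs <- intersect(seq_len(n), seq_len(n) + dr)
  cs <- intersect(seq_len(p), seq_len(p) + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Generate a matched synthetic cohort
#'
#' Draws `n_ad` AD subjects with ages uniform on 55–75 (integer years), sex
#' Bernoulli(1/2) and a random eye side, one image per subject; for each AD
#' subject, `n_controls_per_ad` NC subjects with identical age and sex and an
#' image of the same eye side. Every image gets a vessel map from
#' [generate_vessel_tree()] for its group, so the only systematic group
#' difference is the configured small-vessel effect.
#'
#' @param config a [simulation_config()].
#' @param seed integer RNG seed (defaults to `config$seed`).
#' @return a list with `table` (data.frame: subject_id, age, sex, eye,
#'   diagnosis, image_id) and `maps` (named list of [vessel_map()], keyed by
#'   image_id).
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  demo <- with_seed(derive_seed(seed, "demographics"), {
    data.frame(
      age = sample(55:75, config$n_ad, replace = TRUE),
      sex = sample(c("M", "F"), config$n_ad, replace = TRUE),
      eye = sample(c("left", "right"), config$n_ad, replace = TRUE)
    )
  })
  rows <- list(); maps <- list()
  for (i in seq_len(config$n_ad)) {
    ad_id <- sprintf("AD%03d", i)
    ad_img <- sprintf("img_%s", ad_id)
    m <- generate_vessel_tree(config, "AD", derive_seed(seed, "map", ad_img))
    m$image_id <- ad_img; m$eye <- demo$eye[i]
    maps[[ad_img]] <- m
    rows[[length(rows) + 1]] <- data.frame(
      subject_id = ad_id, age = demo$age[i], sex = demo$sex[i],
      eye = demo$eye[i], diagnosis = "AD", image_id = ad_img
    )
    for (j in seq_len(config$n_controls_per_ad)) {
      nc_id <- sprintf("NC%03d_%d", i, j)
      nc_img <- sprintf("img_%s", nc_id)
      m <- generate_vessel_tree(config, "NC", derive_seed(seed, "map", nc_img))
      m$image_id <- nc_img; m$eye <- demo$eye[i]
      maps[[nc_img]] <- m
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = nc_id, age = demo$age[i], sex = demo$sex[i],
        eye = demo$eye[i], diagnosis = "NC", image_id = nc_img
      )
    }
  }
  list(table = do.call(rbind, rows), maps = maps)
}

#' Generate a planted-signal calibration cohort
#'
#' Produces two stacks of i.i.d. Gaussian-noise images in which the case
#' group's mean is shifted by `effect_size` standard deviations inside a
#' known square region covering about `signal_fraction` of the pixels. With
#' `effect_size = 0` this is an exact null (both groups i.i.d. identical),
#' used to calibrate the feature-selection rate and to check that nested
#' cross-validation reports chance-level accuracy.
#'
#' @param n_per_group images per group.
#' @param image_size pixels per side.
#' @param signal_fraction fraction of pixels carrying signal (default 0.05).
#' @param effect_size standardized mean difference inside the region.
#' @param seed integer RNG seed.
#' @return list with `ad` and `nc` (lists of matrices), and `region` (logical
#'   matrix marking the planted pixels).
#' @export
generate_planted_cohort <- function(n_per_group, image_size = 32L,
                                    signal_fraction = 0.05,
                                    effect_size = 0, seed = 1L) {
  stopifnot(n_per_group >= 2, image_size >= 4,
            signal_fraction >= 0, signal_fraction <= 1, effect_size >= 0)
  n <- as.integer(image_size)
  side <- max(1L, round(sqrt(signal_fraction) * n))
  r0 <- (n - side) %/% 2L + 1L
  region <- matrix(FALSE, n, n)
  region[r0:(r0 + side - 1L), r0:(r0 + side - 1L)] <- TRUE
  with_seed(seed, {
    make <- function(shift) {
      lapply(seq_len(n_per_group), function(i) {
        m <- matrix(stats::rnorm(n * n), n, n)
        m[region] <- m[region] + shift
        m
      })
    }
    list(ad = make(effect_size), nc = make(0), region = region)
  })
}
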