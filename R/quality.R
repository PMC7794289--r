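#' Image-quality features
#'
#' Summarises a fundus image by simple quality statistics: intensity mean and
#' spread, clipped-pixel fractions (exposure), log gradient energy (focus),
#' disc coverage and the bright-mass centroid offset from the frame center
#' (composition), and a local-brightness outlier fraction (artifacts). These
#' feed the default trainable member model of the quality ensemble.
#'
#' @param img a [fundus_image()] or matrix in `[0, 1]`.
#' @return named numeric vector of 8 features.
#' @export
quality_features <- function(img) {
  m <- map_pixels(img)
  n <- nrow(m); p <- ncol(m)
  eps <- 1 / 255
  gx <- m[, -1] - m[, -p]
  gy <- m[-1, ] - m[-n, ]
  grad_energy <- mean(gx^2) + mean(gy^2)
  bright <- m > 0.15
  cover <- mean(bright)
  if (any(bright)) {
    rr <- matrix(seq_len(n), n, p); cc <- matrix(seq_len(p), n, p, byrow = TRUE)
    off <- sqrt((mean(rr[bright]) / n - 0.5)^2 + (mean(cc[bright]) / p - 0.5)^2)
  } else off <- 1
  c(
    mean = mean(m),
    sd = stats::sd(as.vector(m)),
    clip_lo = mean(m <= eps),
    clip_hi = mean(m >= 1 - eps),
    log_grad = log1p(1e4 * grad_energy),
    coverage = cover,
    centroid_off = off,
    very_bright = mean(m > 0.95)
  )
}

.quality_feature_matrix <- function(imgs) {
  t(vapply(imgs, quality_features, numeric(8)))
}

#' Train the five-member image-quality ensemble
#'
#' Trains five binary quality classifiers with identical architecture,
#' hyper-parameters and training data, differing only in their random
#' initialization seed — an in-silico "multi-reviewer" panel. The default
#' member model is a small single-hidden-layer neural network over
#' [quality_features()]; the member architecture is pluggable via
#' `member_trainer`, which must return an object usable by `member_predict`.
#'
#' @param sufficient list of [fundus_image()] of acceptable quality.
#' @param insufficient list of [fundus_image()] with quality faults.
#' @param seeds exactly 5 pairwise-distinct integer seeds.
#' @param member_trainer optional `function(X, y01, seed)` returning a fitted
#'   member; `member_predict` a `function(member, X)` returning
#'   probability-of-sufficient. Defaults train a `nnet`.
#' @return an object of class `quality_ensemble` with fields `members`,
#'   `seeds`, `scaling`, and `training_meta`.
#' @export
train_quality_ensemble <- function(sufficient, insufficient,
                                   seeds = 1:5,
                                   member_trainer = NULL,
                                   member_predict = NULL) {
  if (length(sufficient) == 0 || length(insufficient) == 0)
    stop("both quality classes must be non-empty")
  if (length(seeds) != 5) stop("exactly 5 member seeds are required")
  if (anyDuplicated(seeds)) stop("member seeds must be pairwise distinct")
  X <- rbind(.quality_feature_matrix(sufficient),
             .quality_feature_matrix(insufficient))
  y <- c(rep(1, length(sufficient)), rep(0, length(insufficient)))
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")
  if (is.null(member_trainer)) {
    member_trainer <- function(X, y01, seed) {
      with_seed(seed, nnet::nnet(X, y01, size = 4, decay = 1e-3,
                                 maxit = 500, entropy = TRUE, trace = FALSE))
    }
    member_predict <- function(member, X) {
      as.numeric(stats::predict(member, X))
    }
  }
  stopifnot(is.function(member_predict))
  members <- lapply(seeds, function(s) member_trainer(Xs, y, s))
  structure(
    list(members = members, seeds = as.integer(seeds),
         predict_fun = member_predict,
         scaling = list(center = center, scale = scale_),
         training_meta = list(n_sufficient = length(sufficient),
                              n_insufficient = length(insufficient))),
    class = "quality_ensemble"
  )
}

#' Per-member quality votes
#'
#' @param e a trained [train_quality_ensemble()] object.
#' @param imgs a single image or a list of images.
#' @return logical matrix (images x 5 members); `TRUE` = voted sufficient.
#' @export
member_votes <- function(e, imgs) {
  stopifnot(inherits(e, "quality_ensemble"))
  if (!is.list(imgs) || inherits(imgs, "fundus_image")) imgs <- list(imgs)
  X <- .quality_feature_matrix(imgs)
  Xs <- sweep(sweep(X, 2, e$scaling$center), 2, e$scaling$scale, "/")
  votes <- vapply(e$members, function(m) e$predict_fun(m, Xs) > 0.5,
                  logical(length(imgs)))
  matrix(votes, nrow = length(imgs), ncol = length(e$members))
}

#' Classify image quality by unanimous vote
#'
#' An image is `sufficient` only if at least `min_votes` of the five members
#' vote sufficient; the default 5 is the unanimity rule — one dissenting
#' member fails the image, a stricter gate than majority vote.
#'
#' @param e trained ensemble.
#' @param img a [fundus_image()] (or list of them).
#' @param min_votes votes required to pass (default 5 = unanimity).
#' @return `"sufficient"` or `"insufficient"` (vector over a list input).
#' @export
classify_quality <- function(e, img, min_votes = 5L) {
  v <- member_votes(e, img)
  ifelse(rowSums(v) >= min_votes, "sufficient", "insufficient")
}

#' Run the cascaded selection flow
#'
#' Applies the five members as a cascade in seed order, recording how many
#' images enter and survive each stage. The survivor set after the last stage
#' equals the unanimous-pass set: cascading only reorders an intersection.
#'
#' @param e trained ensemble.
#' @param imgs list of [fundus_image()].
#' @param order optional permutation of `1:5` giving the cascade order.
#' @return an object of class `selection_flow`: data.frame `stages` with
#'   columns (stage, member, entering, surviving), `final_pass` count, and
#'   `pass_index` (indices of surviving images in `imgs`).
#' @export
run_selection_flow <- function(e, imgs, order = seq_along(e$members)) {
  stopifnot(inherits(e, "quality_ensemble"),
            length(order) == length(e$members),
            setequal(order, seq_along(e$members)))
  v <- member_votes(e, imgs)
  alive <- rep(TRUE, length(imgs))
  stages <- data.frame(stage = seq_along(order), member = order,
                       entering = NA_integer_, surviving = NA_integer_)
  for (k in seq_along(order)) {
    stages$entering[k] <- sum(alive)
    alive <- alive & v[, order[k]]
    stages$surviving[k] <- sum(alive)
  }
  structure(list(stages = stages, final_pass = sum(alive),
                 pass_index = which(alive)),
            class = "selection_flow")
}

#' @export
print.selection_flow <- function(x, ...) {
  cat("Cascaded quality selection flow\n")
  print(x$stages, row.names = FALSE)
  cat("final unanimous-pass count:", x$final_pass, "\n")
  invisible(x)
}
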