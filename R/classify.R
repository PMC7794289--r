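#' Resize a vessel map by area averaging
#'
#' Reduces a map to `size x size` before pixel-wise statistics. When the
#' input side is an integer multiple of `size`, exact block means are used;
#' otherwise an antialiased resampling is applied.
#'
#' @param v a [vessel_map()] or matrix.
#' @param size target side length.
#' @return matrix `size x size`.
#' @export
resize_map <- function(v, size) {
  m <- map_pixels(v)
  n <- nrow(m)
  if (n == size) return(m)
  if (n %% size == 0) {
    f <- n %/% size
    idx <- rep(seq_len(size), each = f)
    # rowsum collapses rows; the transpose collapses both dimensions
    out <- rowsum(t(rowsum(m, idx)), idx) / f^2
    return(t(out))
  }
  clip01(EBImage::resize(m, w = size, h = size, antialias = TRUE))
}

# row-major flattening (matches the FeatureMask flatten order)
.flatten <- function(m) as.vector(t(m))

# stack a list of maps into an n x npix matrix, row-major per image
.stack_maps <- function(maps, resize_to = NULL) {
  px <- lapply(maps, function(v) {
    m <- map_pixels(v)
    if (!is.null(resize_to)) m <- resize_map(m, resize_to)
    m
  })
  d <- dim(px[[1]])
  if (!all(vapply(px, function(m) identical(dim(m), d), logical(1))))
    stop("vessel maps have mismatched dimensions")
  list(X = do.call(rbind, lapply(px, .flatten)), dims = d)
}

#' Per-pixel group statistics
#'
#' Sample mean and sample variance (divisor n - 1) of the pixel intensity at
#' every location across a stack of images from one diagnostic class.
#'
#' @param images list of [vessel_map()] or matrices with equal dimensions,
#'   at least 2.
#' @param label class label, `"AD"` or `"NC"`.
#' @return object of class `group_pixel_stats` with `mean_map`, `var_map`,
#'   `n`, `label`.
#' @export
group_stats <- function(images, label = c("AD", "NC")) {
  label <- match.arg(label)
  if (length(images) < 2) stop("at least 2 images per group are required")
  st <- .stack_maps(images)
  n <- nrow(st$X)
  mu <- colMeans(st$X)
  v <- colSums(sweep(st$X, 2, mu)^2) / (n - 1)
  shape <- function(x) matrix(x, st$dims[1], st$dims[2], byrow = TRUE)
  structure(list(mean_map = shape(mu), var_map = shape(pmax(v, 0)),
                 n = n, label = label, dims = st$dims),
            class = "group_pixel_stats")
}

# The unequal-variance two-sample t statistic and Welch-Satterthwaite df,
# vectorized over pixels. Degenerate pixels (both variances zero): t = 0 for
# equal means, +/- Inf otherwise; df is NA there.
.welch_t <- function(mean_a, var_a, n_a, mean_c, var_c, n_c) {
  se2 <- var_a / n_a + var_c / n_c
  diff <- mean_a - mean_c
  t <- ifelse(se2 > 0, diff / sqrt(se2),
              ifelse(diff == 0, 0, sign(diff) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((var_a / n_a)^2 / (n_a - 1) +
                          (var_c / n_c)^2 / (n_c - 1)),
               NA_real_)
  list(t = t, df = df)
}

#' Per-pixel Welch t-map between the AD and control groups
#'
#' Implements the unequal-variance two-sample statistic
#' `t = (mean_AD - mean_CN) / sqrt(var_AD / n_AD + var_CN / n_CN)` at every
#' pixel, with Welch–Satterthwaite degrees of freedom. Pixels where both
#' group variances vanish give `t = 0` when the means agree and signed
#' infinity otherwise (such pixels are always selected downstream).
#'
#' @param ad,cn [group_stats()] objects with matching dimensions.
#' @return object of class `t_map` with `t_values`, `df_map`, `dims`.
#' @export
compute_tmap <- function(ad, cn) {
  stopifnot(inherits(ad, "group_pixel_stats"),
            inherits(cn, "group_pixel_stats"))
  if (!identical(dim(ad$mean_map), dim(cn$mean_map)))
    stop("group statistics have mismatched dimensions")
  w <- .welch_t(ad$mean_map, ad$var_map, ad$n, cn$mean_map, cn$var_map, cn$n)
  structure(list(t_values = w$t, df_map = w$df, dims = dim(ad$mean_map),
                 n_ad = ad$n, n_cn = cn$n),
            class = "t_map")
}

#' Threshold a t-map into a feature mask
#'
#' A pixel is selected when its |t| reaches the two-sided critical value of
#' the t distribution at significance `alpha` with that pixel's
#' Welch–Satterthwaite degrees of freedom. Infinite t values (zero variance,
#' unequal means) are always selected. No multiplicity correction is applied:
#' the threshold is a raw per-pixel p-value cut.
#'
#' @param t a [compute_tmap()] result.
#' @param alpha two-sided significance level in (0, 1); default 0.01.
#' @return object of class `feature_mask` with logical matrix `selected`,
#'   `alpha`, `n_selected`, and `flatten_order = "row-major"`.
#' @export
select_features <- function(t, alpha = 0.01) {
  stopifnot(inherits(t, "t_map"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  crit <- stats::qt(1 - alpha / 2, df = t$df_map)
  sel <- abs(t$t_values) >= crit
  sel[is.infinite(t$t_values)] <- TRUE
  sel[is.na(sel)] <- FALSE
  structure(list(selected = sel, alpha = alpha, n_selected = sum(sel),
                 flatten_order = "row-major"),
            class = "feature_mask")
}

#' Vectorize a vessel map through a feature mask
#'
#' Selected pixels in row-major order; the SVM input representation.
#'
#' @param v a [vessel_map()] or matrix.
#' @param m a [select_features()] mask of the same dimensions.
#' @return numeric vector of length `m$n_selected`.
#' @export
vectorize <- function(v, m) {
  px <- map_pixels(v)
  stopifnot(inherits(m, "feature_mask"))
  if (!identical(dim(px), dim(m$selected)))
    stop("map and mask dimensions differ")
  .flatten(px)[.flatten(m$selected)]
}

#' SVM and cross-validation configuration
#'
#' @param c_grid,gamma_grid positive hyper-parameter grids for the RBF
#'   kernel; defaults are log-spaced 6 x 6.
#' @param outer_folds,inner_folds fold counts of the nested cross-validation
#'   (both default 5).
#' @param probability_calibration fit Platt-scaled class probabilities on the
#'   final per-fold models (needed for occlusion saliency).
#' @param seed integer RNG seed controlling fold assignment.
#' @return an object of class `svm_config`.
#' @export
svm_config <- function(c_grid = 10^seq(-2, 3),
                       gamma_grid = 10^seq(-4, 1),
                       outer_folds = 5L, inner_folds = 5L,
                       probability_calibration = FALSE,
                       seed = 1L) {
  stopifnot(length(c_grid) > 0, all(c_grid > 0),
            length(gamma_grid) > 0, all(gamma_grid > 0),
            outer_folds >= 2, inner_folds >= 2)
  structure(list(c_grid = c_grid, gamma_grid = gamma_grid,
                 outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 probability_calibration = isTRUE(probability_calibration),
                 seed = as.integer(seed)),
            class = "svm_config")
}

# Stratified fold assignment: within each class, indices are shuffled and
# dealt round-robin, so every fold holds both classes whenever possible.
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# mask (logical column selector over flattened pixels) fitted on a training
# subset; all-TRUE when selection is off
.fit_mask_cols <- function(X, y, alpha, use_selection, dims) {
  if (!use_selection) return(rep(TRUE, ncol(X)))
  a <- X[y == "AD", , drop = FALSE]
  c_ <- X[y == "NC", , drop = FALSE]
  w <- .welch_t(colMeans(a), apply(a, 2, stats::var), nrow(a),
                colMeans(c_), apply(c_, 2, stats::var), nrow(c_))
  crit <- stats::qt(1 - alpha / 2, df = w$df)
  sel <- abs(w$t) >= crit
  sel[is.infinite(w$t)] <- TRUE
  sel[is.na(sel)] <- FALSE
  sel
}

.fit_svm <- function(X, y, cost, gamma, probability = FALSE) {
  e1071::svm(X, y, type = "C-classification", kernel = "radial",
             cost = cost, gamma = gamma, scale = FALSE,
             probability = probability)
}

#' Nested cross-validated RBF-SVM classification
#'
#' Stratified outer folds estimate performance; within each outer training
#' set an inner cross-validation grid-searches the RBF cost and gamma. The
#' per-pixel t-test feature selection is fitted only on training data: it is
#' refitted inside every inner training split during the grid search, and
#' refitted on the whole outer training set before the final per-fold model,
#' so the held-out fold never influences the selected pixels.
#'
#' @param maps list of [vessel_map()] or matrices (equal dimensions).
#' @param labels vector of `"AD"` / `"NC"`, one per map; `"AD"` is the
#'   positive class.
#' @param cfg an [svm_config()].
#' @param use_selection apply the t-test feature selection (`FALSE` feeds all
#'   pixels to the SVM).
#' @param alpha significance level of the selection (default 0.01).
#' @param resize_to optional side length for area-average downsizing before
#'   statistics.
#' @return an object of class `cv_result`: data.frame `folds` (per-fold
#'   confusion counts, metrics, chosen hyper-parameters, n_selected),
#'   `mean` and `sd` of the six metrics across folds, plus the fold
#'   assignment and configuration echo.
#' @export
nested_cv <- function(maps, labels, cfg = svm_config(),
                      use_selection = TRUE, alpha = 0.01,
                      resize_to = NULL) {
  stopifnot(inherits(cfg, "svm_config"))
  labels <- as.character(labels)
  if (!all(labels %in% c("AD", "NC"))) stop("labels must be 'AD' or 'NC'")
  if (min(table(labels)) < cfg$outer_folds)
    stop("need at least outer_folds images per class")
  st <- .stack_maps(maps, resize_to)
  X <- st$X
  y <- factor(labels, levels = c("AD", "NC"))
  grid <- expand.grid(cost = cfg$c_grid, gamma = cfg$gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  outer <- stratified_folds(labels, cfg$outer_folds,
                            derive_seed(cfg$seed, "outer"))
  fold_rows <- vector("list", cfg$outer_folds)
  for (k in seq_len(cfg$outer_folds)) {
    tr <- which(outer != k); te <- which(outer == k)
    inner <- stratified_folds(labels[tr], cfg$inner_folds,
                              derive_seed(cfg$seed, "inner", k))
    # selection depends only on the inner split, not the grid point:
    # precompute one mask (and feature submatrices) per inner split
    splits <- lapply(seq_len(cfg$inner_folds), function(j) {
      itr <- tr[inner != j]; iva <- tr[inner == j]
      cols <- .fit_mask_cols(X[itr, , drop = FALSE], y[itr], alpha,
                             use_selection, st$dims)
      if (!any(cols))
        stop("empty feature mask in an inner training split; ",
             "increase alpha or the sample size")
      list(Xtr = X[itr, cols, drop = FALSE], ytr = y[itr],
           Xva = X[iva, cols, drop = FALSE], yva = y[iva])
    })
    inner_acc <- vapply(seq_len(nrow(grid)), function(g) {
      mean(vapply(splits, function(s) {
        fit <- .fit_svm(s$Xtr, s$ytr, grid$cost[g], grid$gamma[g])
        mean(predict(fit, s$Xva) == s$yva)
      }, numeric(1)))
    }, numeric(1))
    best <- which.max(inner_acc)   # ties: first grid point (lowest cost)
    cols <- .fit_mask_cols(X[tr, , drop = FALSE], y[tr], alpha,
                           use_selection, st$dims)
    if (!any(cols))
      stop("empty feature mask on an outer training set; ",
           "increase alpha or the sample size")
    fit <- .fit_svm(X[tr, cols, drop = FALSE], y[tr],
                    grid$cost[best], grid$gamma[best],
                    probability = cfg$probability_calibration)
    pred <- predict(fit, X[te, cols, drop = FALSE])
    tp <- sum(pred == "AD" & y[te] == "AD")
    fp <- sum(pred == "AD" & y[te] == "NC")
    tn <- sum(pred == "NC" & y[te] == "NC")
    fn <- sum(pred == "NC" & y[te] == "AD")
    met <- suppressWarnings(compute_metrics(tp, fp, tn, fn))
    fold_rows[[k]] <- data.frame(
      fold = k, TP = tp, FP = fp, TN = tn, FN = fn, t(met),
      cost = grid$cost[best], gamma = grid$gamma[best],
      n_selected = sum(cols))
  }
  folds <- do.call(rbind, fold_rows)
  metric_names <- c("accuracy", "ppv", "npv", "tnr", "tpr", "f1")
  structure(
    list(folds = folds,
         mean = colMeans(folds[, metric_names]),
         sd = apply(folds[, metric_names], 2, stats::sd),
         outer_assignment = outer,
         use_selection = use_selection, alpha = alpha, config = cfg),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Nested cross-validated RBF-SVM (",
      if (x$use_selection) paste0("t-test selection, alpha = ", x$alpha)
      else "no feature selection", ")\n", sep = "")
  cat("mean (sd) over", nrow(x$folds), "outer folds:\n")
  for (m in names(x$mean))
    cat(sprintf("  %-9s %.4f (%.4f)\n", m, x$mean[[m]], x$sd[[m]]))
  invisible(x)
}

#' Binary classification metrics from confusion counts
#'
#' Accuracy, precision (PPV), NPV, specificity (TNR), sensitivity (TPR) and
#' F1. A metric whose denominator is zero is returned as `NaN` with a
#' warning, never silently coerced to 0.
#'
#' @param tp,fp,tn,fn non-negative confusion counts (positive class = AD).
#' @return named numeric vector of the six metrics.
#' @export
compute_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (sum(counts) == 0) stop("confusion counts sum to zero")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as NaN")
      NaN
    } else num / den
  }
  ppv <- ratio(tp, tp + fp, "PPV")
  tpr <- ratio(tp, tp + fn, "TPR")
  f1 <- if (is.nan(ppv) || is.nan(tpr) || ppv + tpr == 0) {
    warning("F1 undefined; reported as NaN")
    NaN
  } else 2 * ppv * tpr / (ppv + tpr)
  c(accuracy = (tp + tn) / sum(counts),
    ppv = ppv,
    npv = ratio(tn, tn + fn, "NPV"),
    tnr = ratio(tn, tn + fp, "TNR"),
    tpr = tpr,
    f1 = f1)
}

#' Fit a single AD-vs-NC classifier (for saliency and deployment)
#'
#' Grid-searches (cost, gamma) by stratified k-fold cross-validation on the
#' supplied training data, fits the t-test feature mask on all of it, and
#' trains a final Platt-calibrated RBF-SVM. The result predicts classes and
#' class probabilities for new maps and is the model object consumed by the
#' occlusion-saliency functions.
#'
#' @inheritParams nested_cv
#' @return object of class `ad_classifier` with fields `fit`, `mask`
#'   (a `feature_mask`), `cost`, `gamma`, `dims`.
#' @export
fit_ad_classifier <- function(maps, labels, cfg = svm_config(),
                              use_selection = TRUE, alpha = 0.01,
                              resize_to = NULL) {
  labels <- as.character(labels)
  st <- .stack_maps(maps, resize_to)
  y <- factor(labels, levels = c("AD", "NC"))
  grid <- expand.grid(cost = cfg$c_grid, gamma = cfg$gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  inner <- stratified_folds(labels, cfg$inner_folds,
                            derive_seed(cfg$seed, "fit"))
  splits <- lapply(seq_len(cfg$inner_folds), function(j) {
    itr <- which(inner != j); iva <- which(inner == j)
    cols <- .fit_mask_cols(st$X[itr, , drop = FALSE], y[itr], alpha,
                           use_selection, st$dims)
    if (!any(cols)) stop("empty feature mask in a training split")
    list(Xtr = st$X[itr, cols, drop = FALSE], ytr = y[itr],
         Xva = st$X[iva, cols, drop = FALSE], yva = y[iva])
  })
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    mean(vapply(splits, function(s) {
      fit <- .fit_svm(s$Xtr, s$ytr, grid$cost[g], grid$gamma[g])
      mean(predict(fit, s$Xva) == s$yva)
    }, numeric(1)))
  }, numeric(1))
  best <- which.max(acc)
  cols <- .fit_mask_cols(st$X, y, alpha, use_selection, st$dims)
  if (!any(cols)) stop("empty feature mask; increase alpha or sample size")
  sel <- matrix(cols, st$dims[1], st$dims[2], byrow = TRUE)
  mask <- structure(list(selected = sel, alpha = alpha,
                         n_selected = sum(sel),
                         flatten_order = "row-major"),
                    class = "feature_mask")
  fit <- .fit_svm(st$X[, cols, drop = FALSE], y, grid$cost[best],
                  grid$gamma[best], probability = TRUE)
  structure(list(fit = fit, mask = mask, cost = grid$cost[best],
                 gamma = grid$gamma[best], dims = st$dims,
                 cv_accuracy = acc[best], resize_to = resize_to),
            class = "ad_classifier")
}

#' Predict class probabilities from a fitted AD classifier
#'
#' @param model an [fit_ad_classifier()] object.
#' @param X matrix of row-major flattened maps (one row per image).
#' @return matrix of class probabilities with columns `AD`, `NC`.
#' @export
predict_prob_matrix <- function(model, X) {
  stopifnot(inherits(model, "ad_classifier"))
  cols <- .flatten(model$mask$selected)
  pr <- attr(predict(model$fit, X[, cols, drop = FALSE], probability = TRUE),
             "probabilities")
  pr[, c("AD", "NC"), drop = FALSE]
}
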