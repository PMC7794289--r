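# closed-form probability model over two pixels of a 6x6 map (row-major)
lin_model <- function() {
  idx <- function(r, c) (r - 1) * 6 + c
  prob_model(function(X) 0.2 + 0.3 * X[, idx(2, 3)] + 0.4 * X[, idx(5, 5)],
             label = "AD")
}

test_that("occlusion raw maps equal the analytic oracle exactly", {
  pm <- lin_model()
  v <- withr::with_seed(8, matrix(runif(36), 6, 6))
  p0 <- 0.2 + 0.3 * v[2, 3] + 0.4 * v[5, 5]
  for (k in c(1, 2, 3)) {
    raw <- occlusion_scan(pm, v, window = k)
    off <- (k - 1) %/% 2
    for (i in seq_len(6 - k + 1)) for (j in seq_len(6 - k + 1)) {
      cov23 <- 2 >= i && 2 <= i + k - 1 && 3 >= j && 3 <= j + k - 1
      cov55 <- 5 >= i && 5 <= i + k - 1 && 5 >= j && 5 <= j + k - 1
      want <- p0 - (0.2 + 0.3 * v[2, 3] * (!cov23) + 0.4 * v[5, 5] * (!cov55))
      expect_equal(raw[i + off, j + off], want)
    }
  }
})

test_that("occluding an already-zero region is exactly a no-op", {
  pm <- lin_model()
  v <- withr::with_seed(9, matrix(runif(36), 6, 6))
  v[1:2, 1:2] <- 0
  raw <- occlusion_scan(pm, v, window = 2)
  expect_identical(raw[1, 1], 0)
})

test_that("a whole-image window compares against the all-zero image", {
  pm <- lin_model()
  v <- withr::with_seed(10, matrix(runif(36), 6, 6))
  raw <- occlusion_scan(pm, v, window = 6)
  p0 <- 0.2 + 0.3 * v[2, 3] + 0.4 * v[5, 5]
  vals <- raw[!is.na(raw)]
  expect_length(vals, 1)
  expect_equal(vals, p0 - 0.2)
  expect_error(occlusion_scan(pm, v, window = 7), "window")
})

test_that("per-scale normalization is min-max with the documented conventions", {
  expect_equal(as.vector(normalize_scale(matrix(c(0.1, 0.5, 0.9), 1))),
               c(0, 0.5, 1))
  expect_true(all(normalize_scale(matrix(0.3, 4, 4)) == 0))
  raw <- matrix(c(NA, 1, 3, NA), 2, 2)
  norm <- normalize_scale(raw)
  expect_equal(norm[is.na(raw)], c(0, 0))      # borders filled with 0
  # affine invariance
  r1 <- matrix(runif(9), 3, 3)
  expect_equal(normalize_scale(r1), normalize_scale(2.5 * r1 + 3))
})

test_that("multi-scale averaging stays in range; constant models give zero maps", {
  v <- withr::with_seed(11, matrix(runif(36), 6, 6))
  s <- saliency_map(lin_model(), v, scales = c(1, 2, 3))
  expect_true(all(s$values >= 0 & s$values <= 1))
  expect_equal(s$values,
               Reduce(`+`, lapply(s$raw_maps, normalize_scale)) / 3)
  s1 <- saliency_map(lin_model(), v, scales = 2)
  expect_equal(s1$values, normalize_scale(s1$raw_maps[[1]]))
  flat <- prob_model(function(X) rep(0.7, nrow(X)), "AD")
  expect_true(all(saliency_map(flat, v, c(1, 2))$values == 0))
  expect_error(saliency_map(lin_model(), v, numeric(0)), "scale")
})

test_that("saliency localizes a planted discriminative region", {
  co <- generate_planted_cohort(40, 24, signal_fraction = 0.05,
                                effect_size = 2, seed = 6)
  model <- fit_ad_classifier(c(co$ad[1:30], co$nc[1:30]),
                             rep(c("AD", "NC"), each = 30),
                             fast_svm_config(seed = 3))
  smaps <- lapply(co$ad[31:40], function(m) saliency_map(model, m)$values)
  avg <- Reduce(`+`, smaps) / length(smaps)
  wt <- wilcox.test(avg[co$region], avg[!co$region], alternative = "greater")
  expect_lt(wt$p.value, 0.01)
  expect_gt(mean(avg[co$region]), mean(avg[!co$region]))
})

test_that("saliency PNGs are written and in range", {
  v <- withr::with_seed(12, matrix(runif(36), 6, 6))
  s <- saliency_map(lin_model(), v, scales = c(1, 2))
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  write_saliency_png(s, p1, p2, v)
  expect_true(file.exists(p1) && file.exists(p2))
  expect_equal(dim(read_image_png(p1)), dim(v))
})
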