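test_that("group statistics match closed forms and a loop oracle", {
  img <- matrix(runif(16), 4, 4)
  same <- group_stats(list(img, img), "AD")
  expect_equal(same$mean_map, img)
  expect_true(all(same$var_map == 0))
  zo <- group_stats(list(matrix(0, 3, 3), matrix(1, 3, 3)), "NC")
  expect_true(all(zo$mean_map == 0.5))
  expect_true(all(zo$var_map == 0.5))
  stack <- random_stack(10, 8, seed = 4)
  st <- group_stats(stack, "AD")
  for (r in 1:8) for (c in 1:8) {
    x <- vapply(stack, function(m) m[r, c], numeric(1))
    expect_lt(abs(st$mean_map[r, c] - mean(x)), 1e-12)
    expect_lt(abs(st$var_map[r, c] - var(x)), 1e-12)
  }
  expect_error(group_stats(stack[1], "AD"), "at least 2")
  expect_error(group_stats(list(matrix(0, 2, 2), matrix(0, 3, 3)), "AD"),
               "dimensions")
})

test_that("the pixel-wise t-map equals the scalar Welch oracle", {
  for (s in 1:10) {
    ad <- random_stack(10, 8, seed = 1000 + s)
    cn <- random_stack(12, 8, seed = 2000 + s)
    tm <- compute_tmap(group_stats(ad, "AD"), group_stats(cn, "NC"))
    o <- oracle_tmap(ad, cn)
    expect_lt(max(abs(tm$t_values - o$t)), 1e-10)
    expect_lt(max(abs(tm$df_map - o$df)), 1e-8)
  }
})

test_that("the t-map is antisymmetric under group swap and handles degeneracy", {
  ad <- random_stack(6, 5, seed = 31)
  cn <- random_stack(7, 5, seed = 32)
  f <- compute_tmap(group_stats(ad, "AD"), group_stats(cn, "NC"))
  b <- compute_tmap(group_stats(cn, "AD"), group_stats(ad, "NC"))
  expect_equal(f$t_values, -b$t_values)
  # equal means everywhere: t is exactly 0
  same <- compute_tmap(group_stats(ad, "AD"), group_stats(ad, "NC"))
  expect_true(all(same$t_values == 0))
  # zero variance in both groups: 0 for equal means, signed Inf otherwise
  z <- compute_tmap(group_stats(list(matrix(1, 2, 2), matrix(1, 2, 2)), "AD"),
                    group_stats(list(matrix(0, 2, 2), matrix(0, 2, 2)), "NC"))
  expect_true(all(z$t_values == Inf))
  expect_true(all(select_features(z, 0.01)$selected))
})

test_that("feature selection thresholds behave at the extremes", {
  ad <- random_stack(10, 6, seed = 41)
  cn <- random_stack(10, 6, seed = 42)
  tm <- compute_tmap(group_stats(ad, "AD"), group_stats(cn, "NC"))
  zero <- tm; zero$t_values <- matrix(0, 6, 6)
  expect_equal(select_features(zero, 0.01)$n_selected, 0L)
  loose <- select_features(tm, 0.9999)
  expect_gte(loose$n_selected, 35)   # nearly all 36 pixels
  expect_error(select_features(tm, 0), "alpha")
  expect_error(select_features(tm, 1), "alpha")
  # two-sided rule: the mask is invariant under group swap
  swapped <- compute_tmap(group_stats(cn, "AD"), group_stats(ad, "NC"))
  expect_equal(select_features(tm, 0.05)$selected,
               select_features(swapped, 0.05)$selected)
})

test_that("null feature selection rate tracks alpha", {
  rates <- vapply(1:5, function(s) {
    co <- generate_planted_cohort(60, 64, effect_size = 0, seed = s)
    tm <- compute_tmap(group_stats(co$ad, "AD"), group_stats(co$nc, "NC"))
    select_features(tm, 0.01)$n_selected / 4096
  }, numeric(1))
  expect_gte(mean(rates), 0.004)
  expect_lte(mean(rates), 0.016)
})

test_that("vectorization follows row-major order through the mask", {
  v <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]] row-major
  mask_all <- structure(list(selected = matrix(TRUE, 2, 2), alpha = 0.5,
                             n_selected = 4L, flatten_order = "row-major"),
                        class = "feature_mask")
  expect_equal(vectorize(v, mask_all), c(1, 2, 3, 4))
  one <- mask_all; one$selected <- matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2)
  one$n_selected <- 1L
  expect_equal(vectorize(v, one), v[2, 1])
  none <- mask_all; none$selected <- matrix(FALSE, 2, 2); none$n_selected <- 0L
  expect_length(vectorize(v, none), 0)
  expect_error(vectorize(matrix(0, 3, 3), mask_all), "dimensions")
})

test_that("metrics reproduce hand-computed values and flag undefined ratios", {
  expect_equal(unname(compute_metrics(10, 0, 10, 0)),
               rep(1, 6))
  sym <- compute_metrics(5, 5, 5, 5)
  expect_true(all(sym == 0.5))
  m <- compute_metrics(3, 1, 4, 2)
  expect_equal(unname(m["accuracy"]), 0.7)
  expect_equal(unname(m["ppv"]), 0.75)
  expect_equal(unname(m["npv"]), 2 / 3)
  expect_equal(unname(m["tnr"]), 0.8)
  expect_equal(unname(m["tpr"]), 0.6)
  expect_equal(unname(m["f1"]), 2 / 3)
  expect_warning(expect_warning(res <- compute_metrics(0, 0, 5, 5), "PPV"),
                 "F1")
  expect_true(is.nan(res[["ppv"]]))
  expect_error(compute_metrics(-1, 0, 1, 0), "non-negative")
})

test_that("nested CV bookkeeping is self-consistent on a separable cohort", {
  co <- generate_planted_cohort(15, 16, signal_fraction = 0.1,
                                effect_size = 5, seed = 9)
  maps <- c(co$ad, co$nc)
  labs <- rep(c("AD", "NC"), each = 15)
  r <- nested_cv(maps, labs, fast_svm_config(seed = 2), use_selection = TRUE)
  # per-fold identity: metrics recompute exactly from stored confusion counts
  for (k in seq_len(nrow(r$folds))) {
    f <- r$folds[k, ]
    expect_equal(f$accuracy, (f$TP + f$TN) / (f$TP + f$TN + f$FP + f$FN))
    expect_equal(f$TP + f$TN + f$FP + f$FN, sum(r$outer_assignment == k))
  }
  expect_gte(r$mean[["accuracy"]], 0.95)
  expect_true(all(r$folds$n_selected > 0))
  few <- c(1:3, 16:18)   # 3 images per class: fewer than the 5 outer folds
  expect_error(nested_cv(maps[few], labs[few], fast_svm_config()),
               "outer_folds")
})

test_that("an unselectable cohort raises the empty-mask error", {
  co <- generate_planted_cohort(6, 8, effect_size = 0, seed = 5)
  expect_error(
    nested_cv(c(co$ad, co$nc), rep(c("AD", "NC"), each = 6),
              fast_svm_config(seed = 1), use_selection = TRUE, alpha = 1e-9),
    "alpha")
})

test_that("area-average resizing preserves block means exactly", {
  m <- matrix(as.numeric(1:16) / 16, 4, 4)
  r <- resize_map(m, 2)
  expect_equal(r[1, 1], mean(m[1:2, 1:2]))
  expect_equal(r[2, 2], mean(m[3:4, 3:4]))
  expect_equal(dim(resize_map(matrix(0.5, 6, 6), 4)), c(4L, 4L))
})
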