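qs <- quality_training_set(n_per_class = 40)
ens <- train_quality_ensemble(qs$good, qs$bad, seeds = 1:5)

test_that("ensemble training validates its inputs", {
  expect_error(train_quality_ensemble(list(), qs$bad, seeds = 1:5),
               "non-empty")
  expect_error(train_quality_ensemble(qs$good, qs$bad, seeds = c(1, 1, 2, 3, 4)),
               "distinct")
  expect_error(train_quality_ensemble(qs$good, qs$bad, seeds = 1:4),
               "exactly 5")
})

test_that("members separate blur-defined classes perfectly and deterministically", {
  votes <- member_votes(ens, c(qs$good, qs$bad))
  truth <- rep(c(TRUE, FALSE), times = c(length(qs$good), length(qs$bad)))
  for (m in 1:5) expect_equal(votes[, m], truth)
  # same image queried twice: identical verdicts
  expect_identical(member_votes(ens, qs$good[[1]]),
                   member_votes(ens, qs$good[[1]]))
})

test_that("unanimity requires all five votes", {
  # synthesize fixed vote patterns through a pluggable member model
  make_fixed <- function(pattern) {
    train_quality_ensemble(
      qs$good[1:2], qs$bad[1:2], seeds = 1:5,
      member_trainer = function(X, y, seed) pattern[seed],
      member_predict = function(member, X) rep(as.numeric(member), nrow(X)))
  }
  img <- qs$good[[1]]
  expect_equal(classify_quality(make_fixed(c(1, 1, 1, 1, 1)), img), "sufficient")
  expect_equal(classify_quality(make_fixed(c(1, 1, 1, 1, 0)), img), "insufficient")
  expect_equal(classify_quality(make_fixed(c(0, 0, 0, 0, 0)), img), "insufficient")
})

test_that("unanimous-pass set is contained in the majority-pass set for every vote pattern", {
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), 5))
  for (i in seq_len(nrow(patterns))) {
    votes <- unlist(patterns[i, ])
    unanimous <- sum(votes) >= 5
    majority <- sum(votes) >= 3
    expect_true(!unanimous || majority)
  }
})

test_that("cascade equals the intersection of individual pass sets, in any order", {
  imgs <- c(qs$good[1:10], qs$bad[1:10])
  votes <- member_votes(ens, imgs)
  individual_pass <- lapply(1:5, function(m) which(votes[, m]))
  flow <- run_selection_flow(ens, imgs)
  expect_equal(flow$pass_index, Reduce(intersect, individual_pass))
  expect_true(all(diff(c(flow$stages$entering[1], flow$stages$surviving)) <= 0))
  # all 120 member orderings give the same survivor count
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  finals <- apply(perms, 1, function(p) run_selection_flow(ens, imgs, p)$final_pass)
  expect_equal(length(unique(finals)), 1)
  expect_equal(finals[[1]], flow$final_pass)
})

test_that("pass probability is non-increasing in fault severity", {
  v <- generate_vessel_tree(small_config(), "NC", seed = 21)
  for (kind in c("focus", "exposure")) {
    rates <- vapply(c(0.2, 0.5, 0.9), function(s) {
      mean(vapply(1:50, function(i) {
        classify_quality(ens, render_fundus(v, kind, s, seed = i)) ==
          "sufficient"
      }, logical(1)))
    }, numeric(1))
    expect_true(all(diff(rates) <= 0.05))  # sampling-error tolerance
  }
})
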