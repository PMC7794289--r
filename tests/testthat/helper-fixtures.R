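# Shared fixtures: small stacks and cheap configurations used across tests.

small_config <- function(...) {
  simulation_config(image_size = 64L, n_ad = 4L, ...)
}

# tiny hyper-parameter grid so cross-validation tests stay fast
fast_svm_config <- function(seed = 1L, ...) {
  svm_config(c_grid = 10^(-1:2), gamma_grid = 10^(-3:0), seed = seed, ...)
}

random_stack <- function(n, side, seed) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    matrix(stats::rnorm(side^2), side, side)
  }))
}

# scalar Welch t oracle: textbook formula applied pixel-by-pixel in a loop
oracle_tmap <- function(ad, cn) {
  side <- nrow(ad[[1]])
  t_o <- df_o <- matrix(NA_real_, side, side)
  for (r in seq_len(side)) for (c in seq_len(side)) {
    x <- vapply(ad, function(m) m[r, c], numeric(1))
    y <- vapply(cn, function(m) m[r, c], numeric(1))
    vx <- stats::var(x); vy <- stats::var(y)
    se2 <- vx / length(x) + vy / length(y)
    t_o[r, c] <- (mean(x) - mean(y)) / sqrt(se2)
    df_o[r, c] <- se2^2 / ((vx / length(x))^2 / (length(x) - 1) +
                             (vy / length(y))^2 / (length(y) - 1))
  }
  list(t = t_o, df = df_o)
}

# gradient energy (sum of squared finite differences)
grad_energy <- function(m) {
  sum((m[, -1] - m[, -ncol(m)])^2) + sum((m[-1, ] - m[-nrow(m), ])^2)
}

# a small quality training set rendered from synthetic trees
quality_training_set <- function(n_per_class = 20, seed = 500) {
  cfg <- small_config()
  good <- lapply(seq_len(n_per_class), function(i) {
    render_fundus(generate_vessel_tree(cfg, "NC", seed + i), "none")
  })
  kinds <- c("exposure", "focus", "composition", "artifact")
  bad <- lapply(seq_len(n_per_class), function(i) {
    render_fundus(generate_vessel_tree(cfg, "NC", seed + 100 + i),
                  kinds[(i - 1) %% 4 + 1], severity = 0.9, seed = seed + i)
  })
  list(good = good, bad = bad)
}
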