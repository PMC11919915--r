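# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately brute-force and share no code with the package
# internals they check.

# Exhaustive modified-k-means oracle: minimal CV over every surjective
# assignment of the n maps to K clusters, with per-cluster optimal template
# (dominant eigenvector <=> largest eigenvalue of the cluster Gram matrix).
exhaustive_cv <- function(V, K) {
  Vc <- sweep(V, 2, colMeans(V))   # average-reference each map
  C <- nrow(Vc)
  n <- ncol(Vc)
  total_ss <- sum(Vc^2)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    a <- grid[r, ]
    if (length(unique(a)) < K) next
    expl <- 0
    for (k in seq_len(K)) {
      Vk <- Vc[, a == k, drop = FALSE]
      G <- crossprod(Vk)
      expl <- expl + max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
    }
    sigma2 <- (total_ss - expl) / (n * (C - 1))
    cv <- sigma2 * ((C - 1) / (C - 1 - K))^2
    if (cv < best) best <- cv
  }
  best
}

# Brute-force Spearman rho: average ranks computed by sorting, then the
# plain Pearson product-moment formula on the ranks.
brute_spearman <- function(x, y) {
  avg_rank <- function(v) {
    s <- sort(v)
    # ties get the mean of the positions they occupy in the sorted order
    vapply(v, function(vi) mean(which(s == vi)), numeric(1))
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Quick synthetic recording for preprocessing tests: smooth multi-source
# signal plus white noise, not average-referenced.
toy_recording <- function(n_channels = 16, fs = 250, dur_s = 8, seed = 1,
                          noise_sd = 1) {
  mont <- make_montage(n_channels)
  maps <- make_topographies(n_channels, 3, 0.5, seed = seed, montage = mont)
  t <- (seq_len(dur_s * fs) - 1) / fs
  src <- rbind(sin(2 * pi * 9 * t), sin(2 * pi * 5 * t + 1), cos(2 * pi * 12 * t))
  data <- 20 * maps %*% src +
    matrix(stats::rnorm(n_channels * length(t), sd = noise_sd), n_channels)
  recording(data, fs, mont, reference = "other")
}

# Planted clustering instance: peak-style maps around K templates at a
# given SNR, with random polarity.
planted_peak_maps <- function(maps, n_per_class, noise_sd, seed) {
  C <- nrow(maps); K <- ncol(maps)
  set.seed(seed)
  lab <- rep(seq_len(K), each = n_per_class)
  signs <- sample(c(-1, 1), length(lab), replace = TRUE)
  V <- maps[, lab, drop = FALSE] * rep(signs, each = C) +
    matrix(stats::rnorm(C * length(lab), sd = noise_sd), C)
  list(V = V, labels = lab)
}
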