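test_that("GFP equals the across-channel population SD", {
  mont <- make_montage(64)
  v <- rnorm(64); v <- v - mean(v)
  rec <- recording(cbind(v, rep(0, 64)), 250, mont, reference = "average")
  g <- gfp(rec)
  expect_equal(g[1], sqrt(sum((v - mean(v))^2) / 64))
  expect_equal(g[2], 0)

  two <- recording(matrix(c(1, -1), 2, 1), 100, NULL, reference = "average")
  expect_equal(as.numeric(gfp(two)), 1)

  bad <- recording(matrix(rnorm(8), 4), 100, NULL, reference = "other")
  expect_error(gfp(bad), "average-referenced")
})

test_that("GFP peak picking respects strictness and minimum distance", {
  expect_identical(find_gfp_peaks(1:50), integer(0))
  # conflict at distance 4: the higher peak wins
  x <- c(0, 5, 0, 0, 0, 3, 0)
  expect_identical(find_gfp_peaks(x, 10), 2L)
  expect_identical(find_gfp_peaks(x, 3), c(2L, 6L))

  env <- abs(sin(2 * pi * 10 * (0:(250 * 10 - 1)) / 250)) + 0.5
  pk <- find_gfp_peaks(env, 10)
  expect_equal(length(pk) / 10, 20, tolerance = 0.05)   # ~20 peaks/s
  expect_gte(min(diff(pk)), 10)
  expect_identical(formals(find_gfp_peaks)$min_distance, 10)
})

test_that("modified k-means recovers noiseless structure exactly", {
  maps <- make_topographies(16, 3, 0, seed = 1)   # orthogonal truth
  set.seed(2)
  lab <- sample(1:3, 60, replace = TRUE)
  V <- maps[, lab] * rep(sample(c(-1, 1), 60, TRUE) * runif(60, 0.5, 2),
                         each = 16)
  fit <- modified_kmeans(V, 3, n_init = 20, seed = 3)
  expect_lt(fit$sigma2, 1e-20)
  expect_lt(fit$cv, 1e-20)
  expect_equal(fit$gev, 1, tolerance = 1e-12)
  m <- match_maps(maps, fit)
  expect_gt(min(m$abs_corr), 1 - 1e-9)

  # polarity invariance with K = 1: a template and its negation are one class
  one <- cbind(maps[, 1], -maps[, 1], maps[, 1] * 2)
  f1 <- modified_kmeans(one, 1, n_init = 5, seed = 4)
  expect_equal(f1$gev, 1, tolerance = 1e-12)

  expect_error(modified_kmeans(V, 15, seed = 1), "K must be <")
  expect_error(modified_kmeans(V[, 1:3], 3, seed = 1), "more maps")
})

test_that("small instances attain the exhaustive-search CV optimum", {
  ok <- 0
  for (i in 1:10) {
    set.seed(i)
    C <- 6; n <- 7; K <- 2 + i %% 2
    maps <- make_topographies(C, K, 0.5, seed = i)
    pl <- planted_peak_maps(maps, ceiling(n / K), noise_sd = 0.25, seed = i + 50)
    V <- pl$V[, 1:n]
    fit <- modified_kmeans(V, K, n_init = 100, seed = i)
    if (fit$cv <= exhaustive_cv(V, K) * (1 + 1e-9)) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("restart selection is monotone in the number of restarts", {
  maps <- make_topographies(16, 4, 0.5, seed = 9)
  pl <- planted_peak_maps(maps, 30, noise_sd = 0.5, seed = 10)
  cvs <- vapply(c(1, 2, 5, 10, 20), function(ni)
    modified_kmeans(pl$V, 4, n_init = ni, seed = 77)$cv, numeric(1))
  expect_true(all(diff(cvs) <= 1e-12))
})

test_that("aggregation is a fixed point on identical sets and recovers planted maps", {
  maps <- make_topographies(32, 7, 0.5, seed = 11)
  set1 <- structure(list(maps = maps, K = 7), class = "microstate_set")
  agg <- aggregate_maps(list(set1, set1, set1), 7, n_iter = 20, seed = 12)
  m <- match_maps(maps, agg)
  expect_gt(min(m$abs_corr), 1 - 1e-9)

  # sign-flipped and permuted copies of one truth still recover it
  p <- c(3, 1, 7, 5, 2, 6, 4)
  flip <- maps[, p] * rep(c(-1, 1, -1, 1, 1, -1, 1), each = 32)
  set2 <- structure(list(maps = flip, K = 7), class = "microstate_set")
  agg2 <- aggregate_maps(list(set1, set2), 7, n_iter = 20, seed = 13)
  expect_gt(min(match_maps(maps, agg2)$abs_corr), 1 - 1e-9)

  expect_error(aggregate_maps(list(set1), 40, n_iter = 5, seed = 1), "fewer pooled")
})

test_that("letter assignment solves the assignment problem optimally", {
  mont <- make_montage(32)
  canon <- canonical_templates(mont)
  set <- structure(list(maps = canon, K = 7), class = "microstate_set")
  out <- assign_letters(set, canon)
  expect_identical(out$letters, LETTERS[1:7])
  expect_equal(out$letter_corr, rep(1, 7), tolerance = 1e-9)

  # permuted and sign-flipped canonical maps recover their letters
  p <- c(4, 2, 7, 1, 6, 3, 5)
  set2 <- structure(list(maps = canon[, p] * rep(c(1, -1), length.out = 7 * 32),
                         K = 7), class = "microstate_set")
  set2$maps <- canon[, p] * rep(sample(c(-1, 1), 7, replace = TRUE), each = 32)
  out2 <- assign_letters(set2, canon)
  expect_identical(out2$letters, LETTERS[p])

  # constructed 3x3 case where greedy assignment is suboptimal
  A <- diag(3)
  corr <- matrix(c(0.9, 0.85, 0.1,
                   0.89, 0.1, 0.1,
                   0.1, 0.1, 0.2), 3, 3, byrow = TRUE)
  sol <- microflight:::best_assignment(corr)
  # greedy would take (1,1)=0.9 then (2,?)... optimal pairs row2->col1, row1->col2
  expect_equal(sol$idx, c(2, 1, 3))
})

test_that("backfitting is polarity-free, unsmoothed, and recovers truth", {
  maps <- make_topographies(32, 7, 0.5, seed = 14)
  set <- structure(list(maps = maps, K = 7), class = "microstate_set")
  mont <- make_montage(32)
  rec <- recording(cbind(maps[, 3] * 5, -maps[, 3] * 2, rep(0, 32)),
                   250, mont, reference = "average")
  bf <- backfit(rec, set)
  expect_equal(bf$labels[1:2], c(3L, 3L))
  expect_equal(bf$abs_corr[1:2], c(1, 1), tolerance = 1e-9)
  expect_equal(bf$labels[3], 1L)           # flat sample: tie rule, corr 0
  expect_equal(bf$abs_corr[3], 0)

  lab <- simulate_labels(30, 250, 80, n_classes = 7, seed = 15)
  recn <- render_eeg(lab, maps, 250, noise_sd = 0, montage = mont, seed = 16)
  bfn <- backfit(recn, set)
  expect_gte(mean(bfn$labels == lab), 0.99)
})

test_that("GEV is 1 on noiseless fits, maximal under argmax labels, and nested in K", {
  maps <- make_topographies(32, 7, 0.5, seed = 17)
  set <- structure(list(maps = maps, K = 7), class = "microstate_set")
  mont <- make_montage(32)
  lab <- simulate_labels(20, 250, 80, n_classes = 7, seed = 18)
  rec0 <- render_eeg(lab, maps, 250, noise_sd = 0, montage = mont, seed = 19)
  bf <- backfit(rec0, set)
  expect_equal(gev(rec0, bf, set), 1, tolerance = 1e-9)

  # adversarial (argmin) labels never beat backfit labels
  noisy <- render_eeg(lab, maps, 250, noise_sd = noise_sd_for_snr(4, 32),
                      montage = mont, seed = 20)
  D <- microflight:::abs_spatial_corr(maps, noisy$data)
  worst <- apply(D, 2, which.min)
  expect_lte(gev(noisy, worst, set), gev(noisy, backfit(noisy, set), set))

  # richer model explains more: K = 7 fit vs K = 4 fit on 7-state data
  pk <- find_gfp_peaks(gfp(noisy), 10)
  V <- noisy$data[, pk]
  f7 <- modified_kmeans(V, 7, n_init = 20, seed = 21)
  f4 <- modified_kmeans(V, 4, n_init = 20, seed = 21)
  peak_rec <- recording(V, 250, mont, reference = "average")
  g7 <- gev(peak_rec, backfit(peak_rec, f7), f7)
  g4 <- gev(peak_rec, backfit(peak_rec, f4), f4)
  expect_gt(g7, g4)

  zero <- recording(matrix(0, 32, 5), 250, mont, reference = "average")
  expect_error(gev(zero, rep(1L, 5), set), "all-zero")
})
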