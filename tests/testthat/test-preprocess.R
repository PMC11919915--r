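test_that("band-pass FIR is zero-phase and has the contracted response", {
  mont <- make_montage(4)
  fs <- 250; n <- 5000
  t <- (seq_len(n) - 1) / fs
  rec <- recording(rbind(sin(2 * pi * 10 * t), rep(1, n),
                         sin(2 * pi * 60 * t), sin(2 * pi * 41.5 * t)),
                   fs, mont, reference = "other")
  f <- bandpass_fir(rec, 1, 40, 1)
  mid <- 1000:4000
  expect_gt(max(abs(f$data[1, mid])), 0.95)           # 10 Hz passes
  expect_lt(max(abs(f$data[1, mid])), 1.05)
  expect_lt(sqrt(mean(f$data[2, mid]^2)), 0.01)       # DC rejected
  expect_lt(max(abs(f$data[3, mid])), 10^(-50 / 20))  # 60 Hz in deep stopband
  expect_lt(max(abs(f$data[4, mid])), 10^(-50 / 20))  # high edge + transition

  # impulse response symmetry = linear phase applied at zero lag
  imp <- matrix(0, 4, 3001); imp[, 1501] <- 1
  fi <- bandpass_fir(recording(imp, fs, mont, reference = "other"))
  v <- fi$data[1, ]
  expect_lt(max(abs(v - rev(v))), 1e-12)

  short <- recording(matrix(rnorm(4 * 100), 4), fs, mont, reference = "other")
  expect_error(bandpass_fir(short), "shorter than")
  expect_error(bandpass_fir(rec, 30, 20), "low < high")
})

test_that("bad-channel rules catch planted faults and spare clean data", {
  rec <- toy_recording(16, 250, 8, seed = 2, noise_sd = 0.5)
  rec$data[5, 1:(6 * 250)] <- 2.5          # flat 6 s
  rec$data[12, ] <- rec$data[12, ] * 20    # gross amplitude
  b <- detect_bad_channels(rec, use_neighbors = FALSE)
  expect_setequal(as.character(b), c("E005", "E012"))
  expect_true("flat" %in% attr(b, "criteria")[["E005"]])
  expect_true("amplitude" %in% attr(b, "criteria")[["E012"]])

  clean <- toy_recording(16, 250, 8, seed = 3, noise_sd = 0.5)
  expect_length(detect_bad_channels(clean, use_neighbors = FALSE), 0)

  # neighbour rule on constructed data: all channels share one source
  # (correlation ~1) except one carrying independent noise
  mont <- make_montage(16)
  s <- sin(2 * pi * 7 * (0:1999) / 250)
  X <- outer(seq(0.5, 2, length.out = 16), s)
  X <- X + matrix(rnorm(length(X), sd = 0.01), 16)
  X[9, ] <- rnorm(2000)
  recn <- recording(X, 250, mont, reference = "other")
  bn <- detect_bad_channels(recn, use_neighbors = TRUE)
  expect_true("E009" %in% as.character(bn))

  recm <- recn; recm$montage <- NULL
  expect_error(detect_bad_channels(recm, use_neighbors = TRUE), "montage")
})

test_that("FASTER-style local-channel repair flags and fixes epoch outliers", {
  rec <- toy_recording(16, 250, 8, seed = 4, noise_sd = 0.5)
  ep <- epoch_recording(rec, 2)
  ep$data[7, , 2] <- ep$data[7, , 2] * 10   # variance inflated x100
  out <- faster_local_channels(ep)
  expect_true("E007" %in% out$interpolated[[2]])

  # identical channels: all z = 0, nothing flagged
  same <- recording(matrix(rep(sin(2 * pi * 5 * (0:999) / 250), each = 8), 8),
                    250, make_montage(8), reference = "other")
  eps <- faster_local_channels(epoch_recording(same, 2))
  expect_true(all(lengths(eps$interpolated) == 0))
})

test_that("spherical splines reproduce constants and smooth harmonics", {
  m <- make_montage(64)
  expect_lt(max(abs(spherical_spline_interpolate(rep(5, 64), m, c(3, 9)) - 5)),
            1e-6)
  # first-degree harmonic held out at one channel
  topo <- m$x
  est <- spherical_spline_interpolate(topo, m, 10)
  expect_lt(abs(est[10] - topo[10]) / stats::sd(topo), 0.05)
  # empty bad set is the identity
  expect_identical(spherical_spline_interpolate(topo, m, integer(0)), topo)
})

test_that("segment rejection obeys the amplitude and probability rules", {
  rec <- toy_recording(16, 250, 20, seed = 5, noise_sd = 0.5)
  ep <- epoch_recording(rec, 2)
  ep$data[3, 100, 4] <- 150                # 150 uV spike
  flags <- reject_segments(ep)
  expect_true(flags[4])

  # all-identical epochs: probability rules stay silent
  one <- rec$data[, 1:500]
  same <- recording(matrix(rep(one, 6), nrow = 16), 250, rec$montage,
                    reference = "other")
  eps <- epoch_recording(same, 2)
  expect_false(any(reject_segments(eps)))

  # a single gross outlier epoch among many is the one flagged
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(rnorm(8 * 250 * 40), 8)
    X[, 250 * 10 + 1:250] <- X[, 250 * 10 + 1:250] * 6
    epo <- epoch_recording(recording(X, 250, make_montage(8),
                                     reference = "other"), 1)
    fl <- reject_segments(epo, amp_uv = 1e6)
    if (fl[11] && sum(fl) == 1) hits <- hits + 1
  }
  expect_gte(hits, 9)

  # monotone in the amplitude threshold
  fl_loose <- reject_segments(ep, amp_uv = 200)
  fl_tight <- reject_segments(ep, amp_uv = 50)
  expect_true(all(fl_tight[fl_loose]))
})

test_that("average reference is idempotent and resampling preserves content", {
  rec <- toy_recording(8, 250, 4, seed = 6)
  a1 <- average_reference(rec)
  a2 <- average_reference(a1)
  expect_equal(a1$data, a2$data, tolerance = 1e-12)
  expect_lt(max(abs(colMeans(a1$data))), 1e-9)

  mont <- make_montage(4)
  fs <- 2048; n <- fs * 10
  t <- (seq_len(n) - 1) / fs
  r <- recording(matrix(rep(sin(2 * pi * 10 * t), 4), 4, byrow = TRUE),
                 fs, mont, reference = "other")
  rr <- resample_recording(r, 250)
  expect_equal(rr$fs, 250)
  expect_lte(abs(ncol(rr$data) - round(n * 250 / 2048)), 1)
  mid <- 200:2200
  expect_lt(abs(max(abs(rr$data[1, mid])) - 1), 0.02)
  expect_error(resample_recording(rr, 500), "upsampling")
})

test_that("the full chain preserves channel count and the reference invariant", {
  rec <- toy_recording(16, 250, 12, seed = 7, noise_sd = 0.5)
  rec$data[5, 1:(6 * 250)] <- 1.0
  out <- preprocess_recording(rec, use_neighbors = FALSE)
  expect_equal(nrow(out$recording$data), 16)
  expect_lt(max(abs(colMeans(out$recording$data))), 1e-9)
  expect_true("E005" %in% out$report$bad_channels)
  # determinism
  out2 <- preprocess_recording(rec, use_neighbors = FALSE)
  expect_identical(out$recording$data, out2$recording$data)
})
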