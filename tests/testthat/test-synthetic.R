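test_that("generated topographies are average-referenced, unit-norm and decorrelated", {
  maps <- make_topographies(8, 7, 0.5, seed = 1)
  expect_equal(dim(maps), c(8, 7))
  expect_lt(max(abs(colSums(maps))), 1e-10)
  expect_lt(max(abs(sqrt(colSums(maps^2)) - 1)), 1e-10)
  cc <- abs(crossprod(maps)); diag(cc) <- 0
  expect_lte(max(cc), 0.5)

  # orthogonal construction
  orth <- make_topographies(64, 2, 0, seed = 2)
  expect_lt(abs(crossprod(orth)[1, 2]), 1e-10)

  # determinism
  expect_identical(make_topographies(16, 4, 0.4, seed = 7),
                   make_topographies(16, 4, 0.4, seed = 7))

  # infeasible requests fail loudly
  expect_error(make_topographies(8, 8, 0.5, seed = 1), "average-referenced")
  expect_error(make_topographies(16, 7, 0.01, seed = 1, max_tries = 20),
               "infeasible")
})

test_that("label dynamics honor the dwell model", {
  expect_error(simulate_labels(10, 250, 80, n_classes = 1), "2 classes")
  expect_error(simulate_labels(10, 250, 2, n_classes = 3), "unresolvable")

  lab <- simulate_labels(60, 250, 80, n_classes = 7, seed = 3)
  expect_length(lab, 60 * 250)
  r <- rle(lab)
  expect_true(all(diff(r$values) != 0))      # no immediate self-transitions

  # empirical mean run length over replicates converges to the 80 ms target
  runs <- unlist(lapply(1:20, function(i)
    rle(simulate_labels(120, 250, 80, n_classes = 7, seed = i))$lengths))
  expect_lt(abs(mean(runs) * 4 - 80) / 80, 0.05)

  # symmetric configuration: coverage ~ 1/7 per class
  cov <- rowMeans(vapply(1:20, function(i)
    ms_coverage(simulate_labels(120, 250, 80, n_classes = 7, seed = 100 + i), 7),
    numeric(7)))
  expect_lt(max(abs(cov - 1 / 7)), 0.02)
})

test_that("rendered EEG matches the forward model", {
  maps <- make_topographies(32, 5, 0.5, seed = 4)
  lab <- simulate_labels(4, 250, 80, n_classes = 5, seed = 5)
  rec <- render_eeg(lab, maps, 250, noise_sd = 0, seed = 6)
  expect_true(microflight:::is_average_referenced(rec, 1e-9))

  # noiseless: every sample correlates +-1 with its true map
  corr <- microflight:::abs_spatial_corr(maps, rec$data)
  expect_lt(max(abs(corr[cbind(lab, seq_along(lab))] - 1)), 1e-9)

  # doubling the envelope doubles GFP everywhere (homogeneity)
  rec2 <- render_eeg(lab, maps, 250, gfp_mean = 20, noise_sd = 0, seed = 6)
  expect_equal(gfp(rec2), 2 * gfp(rec), tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(render_eeg(lab, maps, 250, noise_sd = -1), "non-negative")
})

test_that("evaluation scores hit the planted rank-correlation targets", {
  # synthetic parameter summary with real between-subject spread
  n <- 200
  set.seed(10)
  ps <- data.frame(subject = rep(1:n, each = 1), stage = "S1", class = 1,
                   coverage = runif(n, 0.1, 0.2),
                   duration_ms = rnorm(n, 80, 10),
                   occurrence = rnorm(n, 1.8, 0.2))

  # null dimension stays null
  ev0 <- simulate_evaluations(ps, NULL, seed = 11)
  d2 <- ev0[ev0$dimension == "D2", ]
  expect_lt(abs(cor(d2$score, ps$coverage, method = "spearman")), 0.15)

  # planted rho = 0.6 is calibrated within +-0.1 at n = 200
  pe <- data.frame(class = 1, parameter = "duration", dimension = "D4", rho = 0.6)
  ev <- simulate_evaluations(ps, pe, seed = 12)
  d4 <- ev[ev$dimension == "D4", ]
  expect_lt(abs(cor(d4$score, ps$duration_ms, method = "spearman") - 0.6), 0.1)

  # degenerate target: rho -> 1 with no extra noise gives Spearman exactly 1
  pe1 <- data.frame(class = 1, parameter = "coverage", dimension = "D1",
                    rho = 1 - 1e-12)
  ev1 <- simulate_evaluations(ps, pe1, noise_sd = 0, seed = 13)
  d1 <- ev1[ev1$dimension == "D1", ]
  expect_equal(cor(d1$score, ps$coverage, method = "spearman"), 1)

  expect_error(simulate_evaluations(ps, data.frame(class = 1, parameter = "coverage",
                                                   dimension = "D1", rho = 1)),
               "rho")
})

test_that("cohorts are deterministic and closed under the parameters module", {
  cfg <- cohort_config(n_subjects = 3, n_channels = 16,
                       sessions_per_stage = c(1, 1, 1),
                       session_duration_s = 10, seed = 21)
  coh <- simulate_cohort(cfg)
  coh2 <- simulate_cohort(cfg)
  expect_identical(coh$true_maps, coh2$true_maps)
  expect_identical(coh$true_labels, coh2$true_labels)
  expect_identical(coh$evaluations, coh2$evaluations)

  # true_parameters must be re-derivable from true_labels (generator/
  # estimator closure)
  p <- microstate_parameters(coh$true_labels[[2]][[3]], cfg$fs, cfg$n_classes)
  sub <- coh$true_parameters[coh$true_parameters$subject == 2 &
                               coh$true_parameters$session == 3, ]
  expect_equal(sub$coverage, p$coverage)
  expect_equal(sub$duration_ms, p$duration_ms)
  expect_equal(sub$occurrence, p$occurrence)

  # coverage conservation on every sequence
  covs <- vapply(unlist(coh$true_labels, recursive = FALSE),
                 function(l) sum(ms_coverage(l, cfg$n_classes)), numeric(1))
  expect_equal(covs, rep(1, length(covs)))

  # evaluations: one row per subject x stage x dimension
  expect_equal(nrow(coh$evaluations), 3 * 3 * 5)

  # lazy rendering is order-independent
  r1 <- render_cohort_recording(coh, 2, 2)
  r2 <- render_cohort_recording(coh, 2, 2)
  expect_identical(r1$data, r2$data)
})
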