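make_rm_data <- function(n, a, b, effect_a = 0, sd_subj = 1, sd_noise = 1,
                         seed = 1) {
  set.seed(seed)
  g <- expand.grid(subject = 1:n, A = 1:a, B = 1:b)
  subj_eff <- rnorm(n, sd = sd_subj)
  g$y <- subj_eff[g$subject] + effect_a * g$A + rnorm(nrow(g), sd = sd_noise)
  g
}

test_that("RM-ANOVA partitions the total sum of squares", {
  d <- make_rm_data(12, 4, 3, effect_a = 0.5, seed = 2)
  res <- rm_anova_2way(d, "y", "subject", "A", "B")
  ss_sum <- sum(res$ss) + sum(res$ss_error) + attr(res, "ss_subject")
  expect_equal(ss_sum, attr(res, "ss_total"), tolerance = 1e-9)
  expect_true(all(res$F >= 0))
  expect_true(all(res$gg_epsilon <= 1))
  # GG correction never strengthens an effect in the rejection region
  big <- res$F > 1
  expect_true(all(res$p_gg[big] >= res$p[big] - 1e-12))
})

test_that("a 2-level within factor reproduces the paired t-test", {
  d <- make_rm_data(15, 2, 3, effect_a = 0.4, seed = 3)
  res <- rm_anova_2way(d, "y", "subject", "A", "B")
  # paired t on the per-subject means of the two A levels
  m <- tapply(d$y, list(d$subject, d$A), mean)
  tt <- t.test(m[, 1], m[, 2], paired = TRUE)
  expect_equal(res$F[1], unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res$p[1], tt$p.value, tolerance = 1e-9)
})

test_that("all-equal cells give F = 0 and missing cells fail", {
  g <- expand.grid(subject = 1:6, A = 1:3, B = 1:2)
  g$y <- 5
  res <- rm_anova_2way(g, "y", "subject", "A", "B")
  expect_true(all(is.nan(res$F) | res$F == 0))
  expect_error(rm_anova_2way(g[-1, ], "y", "subject", "A", "B"),
               "one observation per subject")
})

test_that("Greenhouse-Geisser epsilon is near 1 under compound symmetry", {
  set.seed(4)
  n <- 200; a <- 3; b <- 2
  subj <- rnorm(n, sd = 2)
  g <- expand.grid(subject = 1:n, A = 1:a, B = 1:b)
  g$y <- subj[g$subject] + rnorm(nrow(g))      # CS: equal var, equal cov
  res <- rm_anova_2way(g, "y", "subject", "A", "B")
  expect_gt(min(res$gg_epsilon), 0.95)
})

test_that("paired t contrasts follow the closed form and the Bonferroni cap", {
  d <- data.frame(subject = rep(1:10, 2),
                  cond = rep(c("x", "y"), each = 10),
                  v = c(rnorm(10, 1), rnorm(10, 0)))
  res <- paired_t_bonferroni(d, "v", "subject", "cond")
  dd <- d$v[1:10] - d$v[11:20]
  expect_equal(res$t, mean(dd) / (sd(dd) / sqrt(10)), tolerance = 1e-12)
  expect_equal(res$p_adj, min(1, res$p * 1))

  # identical samples: t = 0, p reported as 1
  d2 <- d; d2$v[11:20] <- d2$v[1:10]
  res2 <- paired_t_bonferroni(d2, "v", "subject", "cond")
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)

  # cap at 1 for any family size
  res3 <- paired_t_bonferroni(d, "v", "subject", "cond", family_size = 1e6)
  expect_lte(res3$p_adj, 1)
})

test_that("Spearman machinery matches brute-force ranks and is monotone-invariant", {
  expect_equal(unname(microflight:::spearman_test(1:8, (1:8)^3)["rho"]), 1)
  expect_equal(unname(microflight:::spearman_test(1:8, rev(1:8))["rho"]), -1)
  for (i in 1:10) {
    set.seed(i)
    x <- sample(1:5, 10, replace = TRUE)   # heavy ties
    y <- sample(1:4, 10, replace = TRUE)
    got <- unname(microflight:::spearman_test(x, y)["rho"])
    expect_equal(got, brute_spearman(x, y), tolerance = 1e-12)
    # strictly monotone transforms change nothing
    got2 <- unname(microflight:::spearman_test(exp(x), y^3 + y)["rho"])
    expect_equal(got2, got, tolerance = 1e-12)
  }
})

test_that("the correlation matrix flags planted effects and respects the family", {
  cfg <- cohort_config(n_subjects = 24, n_channels = 16,
                       sessions_per_stage = c(1, 1, 1),
                       session_duration_s = 20, seed = 5)
  coh <- simulate_cohort(cfg)
  sp <- spearman_matrix(coh$parameter_summary, coh$evaluations)
  expect_equal(nrow(sp), 3 * 7 * 5)
  expect_equal(sp$p_adj, pmin(1, sp$p * 35))
  pe <- default_planted_effects()
  hit <- sp[sp$parameter == "coverage" & sp$class == 7 & sp$dimension == "D1", ]
  expect_gt(hit$rho, 0.3)

  tiny <- coh$parameter_summary[coh$parameter_summary$subject <= 1, ]
  ev <- coh$evaluations[coh$evaluations$subject <= 1, ]
  expect_error(spearman_matrix(tiny, ev), "fewer than 4")
})
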