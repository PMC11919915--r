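# Statistics layer: two-way fully within-subject ANOVA with
# Greenhouse-Geisser correction and effect sizes, Bonferroni paired t-tests,
# and Bonferroni-corrected Spearman correlation matrices.

# Orthonormal contrast matrix (p x (p-1)) spanning the deviation space.
orthonormal_contrasts <- function(p) {
  Q <- qr.Q(qr(cbind(rep(1, p), stats::contr.helmert(p))))
  Q[, -1, drop = FALSE]
}

gg_epsilon <- function(S, M) {
  Sc <- crossprod(M, S %*% M)
  q <- ncol(Sc)
  tr <- sum(diag(Sc))
  tr2 <- sum(Sc * Sc)
  if (tr2 <= 0) return(1)
  min(1, tr^2 / (q * tr2))
}

#' Two-way repeated-measures ANOVA
#'
#' Fully within-subject two-factor design with one observation per subject
#' per cell. Sums of squares are partitioned with subject as a random
#' blocking factor; each effect is tested against its own factor-by-subject
#' interaction. Greenhouse-Geisser epsilon is estimated per effect from the
#' covariance of the subject-level cell scores projected onto the effect's
#' orthonormal contrasts, and the corrected p-value uses epsilon-scaled
#' degrees of freedom. Both partial and generalized eta squared are
#' reported. Missing cells are an error (no imputation).
#'
#' @param df data frame in long format.
#' @param value name of the response column.
#' @param subject,factor_a,factor_b names of the id and factor columns.
#' @return data frame of class `rm_anova` with one row per source
#'   (factor A, factor B, A:B): df, SS, F, p, GG epsilon, GG-corrected p,
#'   partial and generalized eta squared.
#' @export
rm_anova_2way <- function(df, value, subject, factor_a, factor_b) {
  s <- factor(df[[subject]])
  A <- factor(df[[factor_a]])
  B <- factor(df[[factor_b]])
  y <- df[[value]]
  if (anyNA(y)) stopf("missing values in response; incomplete designs are not supported")
  n <- nlevels(s); a <- nlevels(A); b <- nlevels(B)
  if (a < 2 || b < 2) stopf("both factors need at least 2 levels")
  cnt <- table(s, A, B)
  if (any(cnt != 1))
    stopf("design must have exactly one observation per subject x cell")
  Y <- array(0, dim = c(n, a, b))
  Y[cbind(as.integer(s), as.integer(A), as.integer(B))] <- y
  m <- mean(Y)
  m_s <- apply(Y, 1, mean); m_a <- apply(Y, 2, mean); m_b <- apply(Y, 3, mean)
  m_sa <- apply(Y, c(1, 2), mean); m_sb <- apply(Y, c(1, 3), mean)
  m_ab <- apply(Y, c(2, 3), mean)
  ss_total <- sum((Y - m)^2)
  ss_s <- a * b * sum((m_s - m)^2)
  ss_a <- n * b * sum((m_a - m)^2)
  ss_b <- n * a * sum((m_b - m)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) - outer(rep(1, a), m_b) + m)^2)
  ss_sa <- b * sum((m_sa - outer(m_s, rep(1, a)) - outer(rep(1, n), m_a) + m)^2)
  ss_sb <- a * sum((m_sb - outer(m_s, rep(1, b)) - outer(rep(1, n), m_b) + m)^2)
  ss_sab <- ss_total - ss_s - ss_a - ss_b - ss_ab - ss_sa - ss_sb
  # epsilon estimates from the subject x cell covariance
  Ca <- orthonormal_contrasts(a); Cb <- orthonormal_contrasts(b)
  S_a <- stats::cov(m_sa)
  S_b <- stats::cov(m_sb)
  X_full <- matrix(Y, n, a * b)            # cells ordered (A fastest)
  S_full <- stats::cov(X_full)
  M_ab <- kronecker(Cb, Ca)                # contrasts matching cell order
  eps <- c(gg_epsilon(S_a, Ca), gg_epsilon(S_b, Cb), gg_epsilon(S_full, M_ab))
  df1 <- c(a - 1, b - 1, (a - 1) * (b - 1))
  df2 <- df1 * (n - 1)
  ss_eff <- c(ss_a, ss_b, ss_ab)
  ss_err <- c(ss_sa, ss_sb, ss_sab)
  Fv <- (ss_eff / df1) / (ss_err / df2)
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  p_gg <- stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE)
  ss_all_err <- ss_s + ss_sa + ss_sb + ss_sab
  out <- data.frame(
    source = c(factor_a, factor_b, paste0(factor_a, ":", factor_b)),
    df_num = df1, df_den = df2, ss = ss_eff, ss_error = ss_err,
    F = Fv, p = p, gg_epsilon = eps, p_gg = p_gg,
    eta2_partial = ss_eff / (ss_eff + ss_err),
    eta2_generalized = ss_eff / (ss_eff + ss_all_err),
    stringsAsFactors = FALSE)
  attr(out, "ss_subject") <- ss_s
  attr(out, "ss_total") <- ss_total
  class(out) <- c("rm_anova", "data.frame")
  out
}

#' Bonferroni-corrected paired t-tests
#'
#' Classical paired t-test for each requested contrast between
#' within-subject conditions, with Bonferroni adjustment over the declared
#' family. Zero-variance differences are handled explicitly: t = 0 and
#' p = 1 when the mean difference is also zero.
#'
#' @param df long data frame.
#' @param value,subject,condition column names.
#' @param contrasts list of length-2 character vectors of condition levels;
#'   defaults to all pairs.
#' @param family_size Bonferroni family size; defaults to the number of
#'   contrasts.
#' @return data frame (level1, level2, mean_diff, t, df, p, p_adj).
#' @export
paired_t_bonferroni <- function(df, value, subject, condition,
                                contrasts = NULL, family_size = NULL) {
  cond <- as.character(df[[condition]])
  lev <- unique(cond)
  if (is.null(contrasts)) {
    cmb <- utils::combn(lev, 2)
    contrasts <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  if (is.null(family_size)) family_size <- length(contrasts)
  rows <- lapply(contrasts, function(ct) {
    x1 <- df[cond == ct[1], ]
    x2 <- df[cond == ct[2], ]
    ix <- match(x1[[subject]], x2[[subject]])
    if (anyNA(ix)) stopf("subjects are not paired across %s and %s", ct[1], ct[2])
    d <- x1[[value]] - x2[[value]][ix]
    nn <- length(d)
    if (nn < 2) stopf("paired t-test needs at least 2 subjects")
    sd_d <- stats::sd(d)
    if (sd_d == 0) {
      tt <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      pp <- if (mean(d) == 0) 1 else 0
    } else {
      tt <- mean(d) / (sd_d / sqrt(nn))
      pp <- 2 * stats::pt(-abs(tt), nn - 1)
    }
    data.frame(level1 = ct[1], level2 = ct[2], mean_diff = mean(d),
               t = tt, df = nn - 1, p = pp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * family_size)
  out
}

# Spearman rho and its t-approximation p-value for paired vectors.
spearman_test <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 4) return(c(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(x[ok], y[ok], method = "spearman")
  if (is.na(rho)) return(c(rho = NA_real_, p = NA_real_, n = n))
  if (abs(rho) >= 1) return(c(rho = rho, p = 0, n = n))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho = rho, p = 2 * stats::pt(-abs(tt), n - 2), n = n)
}

#' Spearman correlation matrix between microstate parameters and scores
#'
#' For each parameter type, correlates the subject-by-stage class parameter
#' values with each evaluation dimension's scores, pairing observations by
#' (subject, stage) (n = subjects x stages; set `unit = "subject"` to
#' average over stages first). P-values use the t approximation; Bonferroni
#' correction is applied within each parameter type's class x dimension
#' family.
#'
#' @param parameter_summary output of [summarize_parameters()].
#' @param evaluations evaluation table (subject, stage, dimension, score).
#' @param parameters which parameter types to correlate.
#' @param alpha significance level applied to adjusted p-values.
#' @param unit observation unit: "subject_stage" (default) or "subject".
#' @return data frame of class `spearman_matrix` (parameter, class,
#'   dimension, rho, n, p, p_adj, significant).
#' @export
spearman_matrix <- function(parameter_summary, evaluations,
                            parameters = c("coverage", "duration", "occurrence"),
                            alpha = 0.05,
                            unit = c("subject_stage", "subject")) {
  unit <- match.arg(unit)
  ps <- parameter_summary
  ev <- evaluations
  pcol <- c(coverage = "coverage", duration = "duration_ms",
            occurrence = "occurrence")
  if (unit == "subject") {
    ps <- stats::aggregate(ps[, unname(pcol)],
                           by = list(subject = ps$subject, class = ps$class),
                           FUN = mean, na.rm = TRUE)
    ps$stage <- "all"
    ev <- stats::aggregate(list(score = ev$score),
                           by = list(subject = ev$subject, dimension = ev$dimension),
                           FUN = mean)
    ev$stage <- "all"
  }
  classes <- sort(unique(ps$class))
  dims <- sort(unique(ev$dimension))
  fam <- length(classes) * length(dims)
  rows <- list()
  for (par in parameters) {
    col <- pcol[[par]]
    for (k in classes) {
      sub <- ps[ps$class == k, c("subject", "stage", col)]
      for (dim in dims) {
        es <- ev[ev$dimension == dim, c("subject", "stage", "score")]
        ix <- match(paste(sub$subject, sub$stage), paste(es$subject, es$stage))
        st <- spearman_test(sub[[col]], es$score[ix])
        rows[[length(rows) + 1L]] <-
          data.frame(parameter = par, class = k, dimension = dim,
                     rho = st[["rho"]], n = st[["n"]], p = st[["p"]],
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (all(is.na(out$p))) stopf("fewer than 4 paired observations everywhere")
  out$p_adj <- pmin(1, out$p * fam)
  out$significant <- !is.na(out$p_adj) & out$p_adj <= alpha
  class(out) <- c("spearman_matrix", "data.frame")
  out
}
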