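# Core microstate machinery: GFP, peak picking, polarity-invariant modified
# k-means with cross-validation model selection, hierarchical group-level
# aggregation, canonical letter assignment and template backfitting.

#' Global field power
#'
#' Spatial standard deviation of the scalp potential across channels at each
#' sample (population convention, divisor C). Requires an average-referenced
#' recording so the GFP equals the column norm over sqrt(C).
#'
#' @param rec an average-referenced `eeg_recording`.
#' @return numeric vector, one non-negative value per sample, with attribute
#'   `fs`.
#' @export
gfp <- function(rec) {
  assert_average_reference(rec, "GFP")
  g <- unname(sqrt(colSums(rec$data^2) / nrow(rec$data)))
  attr(g, "fs") <- rec$fs
  g
}

#' Find GFP peaks with a minimum separation
#'
#' Strict local maxima of the GFP series, thinned greedily by descending
#' height so that any two retained peaks are at least `min_distance` samples
#' apart (ties in height keep the earlier peak).
#'
#' @param g numeric GFP series.
#' @param min_distance minimum separation in samples (>= 1).
#' @return integer vector of sample indices, in increasing order.
#' @export
find_gfp_peaks <- function(g, min_distance = 10) {
  if (min_distance < 1) stopf("min_distance must be >= 1")
  n <- length(g)
  if (n < 3) return(integer(0))
  core <- g[2:(n - 1)]
  cand <- which(core > g[1:(n - 2)] & core > g[3:n]) + 1L
  if (length(cand) == 0) return(integer(0))
  ord <- cand[order(-g[cand], cand)]
  keep <- logical(0)
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0 || min(abs(kept - i)) >= min_distance)
      kept <- c(kept, i)
  }
  sort(kept)
}

# Absolute spatial correlation between unit-norm average-referenced
# templates A (C x K) and arbitrary maps V (C x n): K x n matrix.
# Zero-variance maps get correlation 0 against every template.
abs_spatial_corr <- function(A, V) {
  Vc <- center_cols(as.matrix(V))
  nv <- col_norms(Vc)
  D <- abs(crossprod(A, Vc))
  nz <- nv > 0
  D[, nz] <- sweep(D[, nz, drop = FALSE], 2, nv[nz], "/")
  D[, !nz] <- 0
  D
}

# --- modified k-means internals -------------------------------------------

# Dominant eigenvector of V %*% t(V) by warm-started power iteration; avoids
# forming the C x C matrix.
dominant_direction <- function(V, start, max_iter = 60, tol = 1e-12) {
  a <- start
  for (i in seq_len(max_iter)) {
    b <- V %*% crossprod(V, a)
    nb <- sqrt(sum(b^2))
    if (nb == 0) return(a)
    b <- b / nb
    if (sum((b - a)^2) < tol || sum((b + a)^2) < tol) {
      a <- b
      break
    }
    a <- b
  }
  a
}

# Fix template sign for determinism: largest-magnitude entry positive.
canonical_sign <- function(A) {
  for (k in seq_len(ncol(A))) {
    j <- which.max(abs(A[, k]))
    if (A[j, k] < 0) A[, k] <- -A[, k]
  }
  A
}

# One modified k-means run from given initial templates, on pre-centered
# maps Vc with column norms nv. Returns templates, assignment, sigma2.
mk_refine <- function(Vc, nv, A, max_iter = 300, tol = 1e-6) {
  C <- nrow(Vc)
  n <- ncol(Vc)
  K <- ncol(A)
  total_ss <- sum(nv^2)
  sigma2_prev <- Inf
  assign <- integer(n)
  for (iter in seq_len(max_iter)) {
    D <- crossprod(A, Vc)            # K x n signed dot products
    D2 <- D * D
    assign <- max.col(t(D2), ties.method = "first")
    best <- D2[cbind(assign, seq_len(n))]
    sigma2 <- (total_ss - sum(best)) / (n * (C - 1))
    # template update: dominant direction of each cluster's maps
    for (k in seq_len(K)) {
      idx <- which(assign == k)
      if (length(idx) == 0) {
        # re-seed empty cluster from the worst-fit map
        resid <- nv^2 - best
        j <- which.max(resid)
        a <- Vc[, j]
        na <- sqrt(sum(a^2))
        A[, k] <- if (na > 0) a / na else A[, k]
        next
      }
      A[, k] <- dominant_direction(Vc[, idx, drop = FALSE], A[, k, drop = FALSE])
    }
    if (is.finite(sigma2_prev) &&
        abs(sigma2_prev - sigma2) <= tol * max(sigma2_prev, .Machine$double.eps))
      break
    sigma2_prev <- sigma2
  }
  # final assignment consistent with returned templates
  D <- crossprod(A, Vc)
  D2 <- D * D
  assign <- max.col(t(D2), ties.method = "first")
  best <- D2[cbind(assign, seq_len(n))]
  sigma2 <- (total_ss - sum(best)) / (n * (C - 1))
  list(templates = A, assign = assign, sigma2 = sigma2,
       explained = sum(best), total_ss = total_ss)
}

mk_cv <- function(sigma2, C, K) sigma2 * ((C - 1) / (C - 1 - K))^2

mk_result <- function(fit, C, K, provenance) {
  A <- canonical_sign(fit$templates)
  structure(list(maps = A, K = K, letters = rep(NA_character_, K),
                 cv = mk_cv(fit$sigma2, C, K), sigma2 = fit$sigma2,
                 gev = fit$explained / fit$total_ss,
                 n_maps = length(fit$assign), assign = fit$assign,
                 provenance = provenance),
            class = "microstate_set")
}

#' Polarity-invariant modified k-means clustering of topographies
#'
#' Clusters average-referenced scalp maps (typically maps at GFP peaks) into
#' K template topographies, ignoring polarity: maps are assigned to the
#' template with the largest squared spatial correlation, and each template
#' is updated as the dominant eigenvector of its cluster's outer-product
#' sum. The procedure is restarted `n_init` times from random map subsets
#' and the solution minimizing the cross-validation criterion
#' `CV = sigma2 * ((C-1)/(C-1-K))^2` (sigma2 the mean orthogonal residual
#' variance) is returned.
#'
#' @param V channels x n matrix of maps (n > K), average-referenced.
#' @param K number of template classes.
#' @param n_init number of random restarts.
#' @param max_iter iteration cap per restart.
#' @param tol relative residual-variance change declaring convergence.
#' @param seed integer seed; results are deterministic given it.
#' @return a `microstate_set`: unit-norm templates (channels x K), the CV
#'   value, the global explained variance (GEV) over the input maps, the
#'   residual variance, and the final assignment.
#' @export
modified_kmeans <- function(V, K, n_init = 100, max_iter = 300, tol = 1e-6,
                            seed = NULL) {
  V <- as.matrix(V)
  C <- nrow(V)
  n <- ncol(V)
  if (K >= C - 1) stopf("K must be < C - 1 for the CV criterion (C = %d)", C)
  if (n <= K) stopf("need more maps (%d) than clusters (%d)", n, K)
  Vc <- center_cols(V)
  nv <- col_norms(Vc)
  if (all(nv == 0)) stopf("all maps are flat")
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_init)) {
      idx <- sample.int(n, K)
      A <- Vc[, idx, drop = FALSE]
      na <- col_norms(A)
      na[na == 0] <- 1
      A <- sweep(A, 2, na, "/")
      fit <- mk_refine(Vc, nv, A, max_iter, tol)
      if (is.null(best) || fit$sigma2 < best$sigma2) best <- fit
    }
    mk_result(best, C, K, provenance = "session")
  })
}

#' Hierarchical aggregation of lower-level microstate sets
#'
#' Pools the template maps of the lower-level sets as observations and
#' repeatedly (`n_iter` times) draws K pooled maps as initial templates,
#' refines them with the modified k-means update on the pooled maps, and
#' keeps the solution with the best (lowest) CV. Applied session -> subject
#' -> condition -> global. With `refine = FALSE` the drawn candidate sets
#' are only scored, never refined (the literal random-subset reading).
#'
#' @param lower_sets list of `microstate_set` objects (or a channels x m
#'   matrix of pooled maps).
#' @param K number of output classes.
#' @param n_iter number of random draws.
#' @param seed integer seed.
#' @param refine refine drawn candidate sets by modified k-means.
#' @param provenance provenance tag for the returned set.
#' @return a `microstate_set`.
#' @export
aggregate_maps <- function(lower_sets, K, n_iter = 100, seed = NULL,
                           refine = TRUE, provenance = "group") {
  P <- if (is.matrix(lower_sets)) lower_sets
  else do.call(cbind, lapply(lower_sets, function(s) s$maps))
  C <- nrow(P)
  if (ncol(P) < K) stopf("fewer pooled maps (%d) than K (%d)", ncol(P), K)
  if (K >= C - 1) stopf("K must be < C - 1 (C = %d)", C)
  Vc <- center_cols(P)
  nv <- col_norms(Vc)
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_iter)) {
      idx <- sample.int(ncol(P), K)
      A <- Vc[, idx, drop = FALSE]
      na <- col_norms(A)
      na[na == 0] <- 1
      A <- sweep(A, 2, na, "/")
      fit <- if (refine) mk_refine(Vc, nv, A)
      else mk_refine(Vc, nv, A, max_iter = 1, tol = Inf)
      if (is.null(best) || fit$sigma2 < best$sigma2) best <- fit
    }
    mk_result(best, C, K, provenance = provenance)
  })
}

#' @export
print.microstate_set <- function(x, ...) {
  lab <- if (all(is.na(x$letters))) "" else
    sprintf(" [%s]", paste(x$letters, collapse = ""))
  cat(sprintf("<microstate_set> K = %d%s, %d channels, CV = %.4g, GEV = %.3f (%s)\n",
              x$K, lab, nrow(x$maps), x$cv, x$gev, x$provenance))
  invisible(x)
}

#' Synthetic canonical template library
#'
#' Seven smooth reference topographies on a montage, ordered A-G, built from
#' fixed low-degree harmonic patterns (diagonal left/right gradients,
#' anterior-posterior and fronto-central patterns, and central/parietal
#' foci). These are synthetic approximations used to attach conventional
#' letters to fitted maps; they are cosmetic metadata and never enter any
#' numeric computation.
#'
#' @param montage an `eeg_montage`.
#' @return channels x 7 matrix with columns named A-G (average-referenced,
#'   unit norm).
#' @export
canonical_templates <- function(montage) {
  x <- montage$x; y <- montage$y; z <- montage$z
  pats <- cbind(A = -x + y,
                B = x + y,
                C = -y + 0.3 * z,
                D = z + 0.7 * y,
                E = 2 * z^2 - x^2 - y^2,
                F = x * y,
                G = z - 0.7 * y)
  pats <- center_cols(pats)
  sweep(pats, 2, col_norms(pats), "/")
}

# Best injective assignment of the K set maps to library columns maximizing
# total |corr|; exhaustive over permutations (library sizes here are small).
best_assignment <- function(corr) {
  L <- nrow(corr)
  K <- ncol(corr)
  if (L < K) stopf("canonical library must have at least K entries")
  if (L > 9) stopf("canonical library too large for exhaustive assignment")
  perm_best <- NULL
  score_best <- -Inf
  rec <- function(chosen, used, score) {
    k <- length(chosen) + 1
    if (k > K) {
      if (score > score_best) {
        score_best <<- score
        perm_best <<- chosen
      }
      return()
    }
    for (l in seq_len(L)) {
      if (!used[l]) {
        used[l] <- TRUE
        rec(c(chosen, l), used, score + corr[l, k])
        used[l] <- FALSE
      }
    }
  }
  rec(integer(0), logical(L), 0)
  list(idx = perm_best, score = score_best)
}

#' Attach canonical letters to a microstate set
#'
#' Solves the assignment problem maximizing the total absolute spatial
#' correlation between the set's templates and a canonical template library
#' (columns named by letter), and attaches the winning letters together with
#' the achieved per-class |correlation|.
#'
#' @param set a `microstate_set`.
#' @param canonical channels x L template library with column names, e.g.
#'   from [canonical_templates()]; L >= K, same montage/channel order.
#' @return the set with `letters` and `letter_corr` filled in.
#' @export
assign_letters <- function(set, canonical) {
  canonical <- as.matrix(canonical)
  if (nrow(canonical) != nrow(set$maps))
    stopf("canonical library channel count does not match the set")
  Cc <- center_cols(canonical)
  Cc <- sweep(Cc, 2, col_norms(Cc), "/")
  corr <- abs_spatial_corr(Cc, set$maps)   # L x K
  sol <- best_assignment(corr)
  set$letters <- colnames(canonical)[sol$idx]
  set$letter_corr <- corr[cbind(sol$idx, seq_len(set$K))]
  set
}

#' Match fitted maps to reference maps
#'
#' Optimal one-to-one assignment (maximum total absolute spatial
#' correlation) between the columns of `maps` and the columns of
#' `reference`; used to compare recovered templates with planted ground
#' truth or another solution, up to polarity and permutation.
#'
#' @param reference channels x L reference maps (L >= K).
#' @param maps channels x K fitted maps, or a `microstate_set`.
#' @return data frame (map, ref, abs_corr), one row per fitted map.
#' @export
match_maps <- function(reference, maps) {
  if (inherits(maps, "microstate_set")) maps <- maps$maps
  R <- center_cols(as.matrix(reference))
  R <- sweep(R, 2, col_norms(R), "/")
  corr <- abs_spatial_corr(R, maps)
  sol <- best_assignment(corr)
  data.frame(map = seq_len(ncol(maps)), ref = sol$idx,
             abs_corr = corr[cbind(sol$idx, seq_len(ncol(maps)))])
}

#' Backfit global templates onto a recording
#'
#' Labels every sample with the template of maximal absolute spatial
#' (Pearson) correlation, disregarding polarity and applying no temporal
#' smoothing. Ties break to the lowest class index; a flat (zero-variance)
#' sample gets class 1 with correlation recorded as 0.
#'
#' @param rec an average-referenced `eeg_recording`.
#' @param set a `microstate_set` with templates on the same channels.
#' @return a `label_sequence`: list with integer `labels`, per-sample
#'   absolute correlation `abs_corr`, and `fs`.
#' @export
backfit <- function(rec, set) {
  assert_average_reference(rec, "backfitting")
  if (nrow(set$maps) != nrow(rec$data))
    stopf("template channel count does not match the recording")
  D <- abs_spatial_corr(set$maps, rec$data)    # K x n
  labels <- max.col(t(D), ties.method = "first")
  structure(list(labels = labels,
                 abs_corr = D[cbind(labels, seq_along(labels))],
                 fs = rec$fs, K = set$K),
            class = "label_sequence")
}

#' Global explained variance of a labeled recording
#'
#' GEV = sum_t (GFP_t * corr_t)^2 / sum_t GFP_t^2, where corr_t is the
#' spatial correlation between sample t and its assigned template.
#'
#' @param rec an average-referenced `eeg_recording`.
#' @param labels a `label_sequence` from [backfit()] (or an integer vector).
#' @param set the `microstate_set` used for labeling.
#' @return GEV fraction in [0, 1].
#' @export
gev <- function(rec, labels, set) {
  assert_average_reference(rec, "GEV")
  lab <- if (inherits(labels, "label_sequence")) labels$labels else as.integer(labels)
  if (length(lab) != ncol(rec$data)) stopf("label length does not match recording")
  Vc <- center_cols(rec$data)
  nv2 <- colSums(Vc^2)
  if (all(nv2 == 0)) stopf("all-zero recording: GEV undefined")
  dots <- colSums(set$maps[, lab, drop = FALSE] * Vc)
  # (GFP_t * corr_t)^2 = dots^2 / C ; GFP_t^2 = nv2 / C
  sum(dots^2) / sum(nv2)
}
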