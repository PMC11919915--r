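# Spherical-spline scalp interpolation (Perrin-style Legendre-series
# g function). Used both for repairing bad channels on whole recordings and
# for FASTER-style within-epoch channel repair.

# Legendre polynomials P_1..P_n evaluated at x (vector); returns a
# length(x) x n matrix built by the three-term recurrence.
legendre_table <- function(x, n) {
  out <- matrix(0, length(x), n)
  p_prev <- rep(1, length(x))     # P_0
  p_cur <- x                      # P_1
  out[, 1] <- p_cur
  if (n >= 2) {
    for (k in 2:n) {
      p_next <- ((2 * k - 1) * x * p_cur - (k - 1) * p_prev) / k
      out[, k] <- p_next
      p_prev <- p_cur
      p_cur <- p_next
    }
  }
  out
}

# g(cos theta) kernel of the spherical spline of a given order, truncated at
# n_legendre terms.
spline_g <- function(cosang, order = 4, n_legendre = 50) {
  n <- seq_len(n_legendre)
  coef <- (2 * n + 1) / (n * (n + 1))^order
  P <- legendre_table(pmin(1, pmax(-1, as.vector(cosang))), n_legendre)
  g <- as.vector(P %*% coef) / (4 * pi)
  if (is.matrix(cosang)) matrix(g, nrow(cosang), ncol(cosang)) else g
}

# Linear operator mapping values at `good` channel indices to interpolated
# values at `bad` indices (rows = bads, cols = goods). Solving once and
# reusing the operator makes sample-wise interpolation of whole epochs cheap.
spherical_spline_operator <- function(montage, good, bad,
                                      order = 4, n_legendre = 50,
                                      lambda = 1e-5) {
  pos <- as.matrix(montage[, c("x", "y", "z")])
  cos_gg <- tcrossprod(pos[good, , drop = FALSE])
  cos_bg <- tcrossprod(pos[bad, , drop = FALSE], pos[good, , drop = FALSE])
  G <- spline_g(cos_gg, order, n_legendre)
  Gb <- spline_g(cos_bg, order, n_legendre)
  ng <- length(good)
  A <- rbind(cbind(G + diag(lambda, ng), rep(1, ng)),
             c(rep(1, ng), 0))
  cn <- kappa(A, exact = FALSE)
  sol <- tryCatch(solve(A, rbind(diag(ng), matrix(0, 1, ng))),
                  error = function(e)
                    stopf("spherical-spline system is singular (condition number %.3e)", cn))
  Cmat <- sol[seq_len(ng), , drop = FALSE]   # spline coefficients per unit input
  dvec <- sol[ng + 1, ]                      # constant term per unit input
  # interpolated = Gb %*% C %*% v + 1 * d %*% v
  Gb %*% Cmat + matrix(dvec, nrow = length(bad), ncol = ng, byrow = TRUE)
}

#' Spherical-spline interpolation of scalp topographies
#'
#' Replaces the entries of `bad_set` channels with a spherical-spline
#' estimate computed from the remaining channels. Accepts a single
#' topography (vector) or a channels x samples matrix, in which case every
#' sample is interpolated with the same operator.
#'
#' @param values numeric vector (one topography) or channels x samples matrix.
#' @param montage an `eeg_montage` matching the rows of `values`.
#' @param bad_set channel names or integer indices to replace.
#' @param order spline order m (flexibility of the interpolant); 4 is the
#'   standard choice for EEG.
#' @param n_legendre number of terms kept in the Legendre series of g.
#' @param lambda Tikhonov regularization added to the spline system.
#' @return `values` with the bad rows replaced; good rows untouched.
#' @export
spherical_spline_interpolate <- function(values, montage, bad_set,
                                         order = 4, n_legendre = 50,
                                         lambda = 1e-5) {
  vec_in <- is.null(dim(values))
  V <- if (vec_in) matrix(values, ncol = 1) else as.matrix(values)
  if (nrow(V) != nrow(montage)) stopf("values rows must match montage channels")
  bad <- if (is.character(bad_set)) match(bad_set, montage$name) else as.integer(bad_set)
  if (anyNA(bad) || any(bad < 1 | bad > nrow(V)))
    stopf("bad_set must name channels present in the montage")
  bad <- sort(unique(bad))
  if (length(bad) == 0) return(values)
  good <- setdiff(seq_len(nrow(V)), bad)
  if (length(good) < 4) stopf("need at least 4 good channels to interpolate")
  W <- spherical_spline_operator(montage, good, bad, order, n_legendre, lambda)
  V[bad, ] <- W %*% V[good, , drop = FALSE]
  if (vec_in) drop(V) else V
}
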