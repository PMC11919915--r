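# Rule-based preprocessing chain: zero-phase FIR band-pass, bad-channel
# rules, 2-s epoching with FASTER-style local-channel repair, segment
# rejection, spherical-spline repair of global bads, average reference and
# anti-aliased downsampling. Every operator is deterministic.

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Hamming windowed-sinc band-pass kernel. Transition width sets the kernel
# length (Hamming normalized transition ~ 3.3/N); 6 dB cutoffs are placed
# half a transition band outside [low, high].
fir_bandpass_kernel <- function(fs, low, high, transition) {
  if (low - transition / 2 <= 0)
    stopf("transition band extends below DC; reduce transition or raise low")
  if (high + transition / 2 >= fs / 2)
    stopf("transition band extends beyond Nyquist")
  N <- ceiling(3.3 * fs / transition)
  if (N %% 2 == 0) N <- N + 1
  M <- (N - 1) / 2
  k <- -M:M
  lp <- function(fc) 2 * fc / fs * sinc(2 * fc * k / fs)
  h <- lp(high + transition / 2) - lp(low - transition / 2)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(N - 1)) / (N - 1))
  h * w
}

# Zero-phase application of a symmetric odd-length kernel: reflect-pad by
# the group delay, FFT-convolve, take the centered segment.
apply_fir <- function(x, h) {
  N <- length(h)
  M <- (N - 1) / 2
  n <- length(x)
  if (n <= N) stopf("signal (%d samples) shorter than filter kernel (%d)", n, N)
  xp <- c(x[(M + 1):2], x, x[(n - 1):(n - M)])
  z <- stats::convolve(xp, rev(h), type = "open")
  z[(2 * M + 1):(2 * M + n)]
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming windowed-sinc linear-phase kernel applied with group-delay
#' compensation (zero net phase). The kernel length follows from the
#' transition bandwidth; Hamming sidelobes give > 50 dB stopband
#' attenuation beyond one transition width outside the passband.
#'
#' @param rec an `eeg_recording`.
#' @param low_hz,high_hz passband edges in Hz (0 < low < high < fs/2).
#' @param transition_hz transition bandwidth in Hz.
#' @return the filtered `eeg_recording`.
#' @export
bandpass_fir <- function(rec, low_hz = 1, high_hz = 40, transition_hz = 1) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < rec$fs / 2))
    stopf("need 0 < low < high < fs/2")
  h <- fir_bandpass_kernel(rec$fs, low_hz, high_hz, transition_hz)
  rec$data <- t(apply(rec$data, 1, apply_fir, h = h))
  rec
}

#' Detect bad channels
#'
#' Union of three rules: (1) flat for more than `flat_s` seconds (absolute
#' first difference under `flat_floor` microvolts/sample); (2) mean absolute
#' Pearson correlation with the `k_neighbors` nearest montage neighbours
#' below `neighbor_corr`; (3) log-RMS amplitude z-scored across channels
#' beyond `amp_sd`.
#'
#' @param rec an `eeg_recording` (montage required unless
#'   `use_neighbors = FALSE`).
#' @param flat_s flatness duration threshold in seconds.
#' @param neighbor_corr neighbour-correlation floor.
#' @param amp_sd amplitude z-score threshold.
#' @param k_neighbors neighbours used by rule 2.
#' @param flat_floor derivative floor defining "flat", microvolts/sample.
#' @param use_neighbors disable rule 2 when no montage is available.
#' @return character vector of bad channel names (or indices without a
#'   montage), with a `criteria` attribute naming the triggering rule(s).
#' @export
detect_bad_channels <- function(rec, flat_s = 5, neighbor_corr = 0.8,
                                amp_sd = 3, k_neighbors = 4,
                                flat_floor = 1e-8, use_neighbors = TRUE) {
  X <- rec$data
  C <- nrow(X)
  flagged <- list()
  # (1) flat runs
  flat <- vapply(seq_len(C), function(c) {
    small <- abs(diff(X[c, ])) < flat_floor
    if (!any(small)) return(FALSE)
    r <- rle(small)
    max(r$lengths[r$values]) + 1 > flat_s * rec$fs
  }, logical(1))
  # (2) neighbour correlation
  if (use_neighbors) {
    if (is.null(rec$montage))
      stopf("neighbour-correlation rule needs a montage (or set use_neighbors = FALSE)")
    nb <- montage_neighbors(rec$montage, k_neighbors)
    cc <- suppressWarnings(stats::cor(t(X)))
    cc[is.na(cc)] <- 0
    lowcorr <- vapply(seq_len(C), function(c)
      mean(abs(cc[c, nb[[c]]])) < neighbor_corr, logical(1))
  } else {
    lowcorr <- rep(FALSE, C)
  }
  # (3) amplitude outliers (log-RMS z-score across channels)
  lrms <- log(sqrt(rowMeans(X^2)) + .Machine$double.eps)
  s <- stats::sd(lrms)
  zz <- if (s > 0) (lrms - mean(lrms)) / s else rep(0, C)
  amp <- abs(zz) > amp_sd
  bad <- which(flat | lowcorr | amp)
  nm <- if (!is.null(rec$montage)) rec$montage$name[bad] else as.character(bad)
  crit <- lapply(bad, function(c)
    c("flat", "neighbor_corr", "amplitude")[c(flat[c], lowcorr[c], amp[c])])
  names(crit) <- nm
  structure(nm, criteria = crit)
}

#' Split a recording into fixed-length epochs
#'
#' @param rec an `eeg_recording`.
#' @param epoch_s epoch length in seconds; `epoch_s * fs` must be a whole
#'   number of samples. Trailing samples that do not fill an epoch are
#'   dropped.
#' @return an `eeg_epochs` object (data array channels x samples x epochs,
#'   rejection flags, per-epoch interpolated-channel sets).
#' @export
epoch_recording <- function(rec, epoch_s = 2) {
  n_per <- epoch_s * rec$fs
  if (abs(n_per - round(n_per)) > 1e-9)
    stopf("epoch length times sampling rate must be an integer sample count")
  n_per <- as.integer(round(n_per))
  n_ep <- floor(ncol(rec$data) / n_per)
  if (n_ep < 1) stopf("recording shorter than one epoch")
  data <- array(rec$data[, seq_len(n_ep * n_per)],
                dim = c(nrow(rec$data), n_per, n_ep))
  structure(list(data = data, fs = rec$fs, montage = rec$montage,
                 epoch_s = epoch_s, rejected = rep(FALSE, n_ep),
                 flagged = rep(FALSE, n_ep),
                 interpolated = vector("list", n_ep)),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples (%g s @ %g Hz), %d rejected\n",
              dim(x$data)[3], dim(x$data)[1], dim(x$data)[2], x$epoch_s, x$fs,
              sum(x$rejected)))
  invisible(x)
}

# z-score a vector across its entries; all-equal input gives all-zero z.
safe_z <- function(v) {
  s <- stats::sd(v)
  if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
}

#' FASTER-style local-channel repair within epochs
#'
#' Within each epoch, computes four per-channel statistics (variance,
#' median absolute gradient, amplitude range, deviation from the mean
#' amplitude), z-scores each across channels, and spherical-spline
#' interpolates any channel with any |z| above `z_thresh`. If more than
#' `cap` of the channels are implicated the epoch is flagged instead of
#' repaired.
#'
#' @param ep an `eeg_epochs` object (montage required).
#' @param z_thresh z-score threshold.
#' @param cap maximal fraction of channels repaired per epoch.
#' @return the updated `eeg_epochs` with `interpolated` and `flagged` filled.
#' @export
faster_local_channels <- function(ep, z_thresh = 3, cap = 0.25) {
  if (is.null(ep$montage)) stopf("local-channel repair needs a montage")
  C <- dim(ep$data)[1]
  for (e in seq_len(dim(ep$data)[3])) {
    X <- ep$data[, , e]
    stats4 <- cbind(
      variance = apply(X, 1, stats::var),
      med_gradient = apply(X, 1, function(v) stats::median(abs(diff(v)))),
      range = apply(X, 1, function(v) diff(range(v))),
      mean_dev = abs(rowMeans(X) - mean(X)))
    z <- apply(stats4, 2, safe_z)
    bad <- which(apply(abs(z) > z_thresh, 1, any))
    if (length(bad) == 0) next
    if (length(bad) > cap * C) {
      ep$flagged[e] <- TRUE
      next
    }
    ep$data[, , e] <- spherical_spline_interpolate(X, ep$montage, bad)
    ep$interpolated[[e]] <- if (!is.null(ep$montage)) ep$montage$name[bad] else bad
  }
  ep
}

# Negative mean log kernel-density of `v` under the density estimate `f`.
nll_stat <- function(v, f) -mean(log(pmax(f(v), 1e-300)))

density_fun <- function(values, max_points = 50000) {
  if (length(values) > max_points)
    values <- values[seq(1, length(values), length.out = max_points)]
  if (stats::sd(values) == 0) return(NULL)
  d <- stats::density(values, n = 512)
  stats::approxfun(d$x, pmax(d$y, 1e-12), rule = 2)
}

#' Reject bad epochs
#'
#' An epoch is rejected when (a) any channel sample exceeds `amp_uv`
#' microvolts in magnitude, (b) any channel's negative log kernel-density
#' statistic (computed under that channel's across-epoch value
#' distribution) is more than `prob_sd` SDs from its across-epoch mean, or
#' (c) the pooled electrode-group statistic of the epoch is.
#'
#' @param ep an `eeg_epochs` object.
#' @param amp_uv absolute amplitude threshold in microvolts.
#' @param prob_sd z-score threshold for the probability statistics.
#' @return logical rejection flags (also stored in the returned object via
#'   attribute; use [drop_rejected()] to apply them). Fails if every epoch
#'   would be rejected.
#' @export
reject_segments <- function(ep, amp_uv = 100, prob_sd = 3) {
  C <- dim(ep$data)[1]
  n_ep <- dim(ep$data)[3]
  amp_bad <- vapply(seq_len(n_ep), function(e)
    max(abs(ep$data[, , e])) > amp_uv, logical(1))
  # single-electrode probability
  prob_bad <- rep(FALSE, n_ep)
  for (c in seq_len(C)) {
    f <- density_fun(as.vector(ep$data[c, , ]))
    if (is.null(f)) next
    stat <- vapply(seq_len(n_ep), function(e) nll_stat(ep$data[c, , e], f),
                   numeric(1))
    prob_bad <- prob_bad | abs(safe_z(stat)) > prob_sd
  }
  # electrode-group probability
  fg <- density_fun(as.vector(ep$data))
  if (!is.null(fg)) {
    statg <- vapply(seq_len(n_ep), function(e) nll_stat(as.vector(ep$data[, , e]), fg),
                    numeric(1))
    prob_bad <- prob_bad | abs(safe_z(statg)) > prob_sd
  }
  flags <- amp_bad | prob_bad | ep$flagged
  if (all(flags))
    stopf("all %d epochs rejected (amplitude rule hit %d, probability rules %d)",
          n_ep, sum(amp_bad), sum(prob_bad))
  flags
}

#' Concatenate retained epochs back into a recording
#'
#' @param ep an `eeg_epochs` object.
#' @param flags logical rejection flags (from [reject_segments()]).
#' @return an `eeg_recording` of the kept epochs in temporal order.
#' @export
drop_rejected <- function(ep, flags = ep$rejected) {
  keep <- which(!flags)
  if (length(keep) == 0) stopf("no epochs retained")
  data <- matrix(ep$data[, , keep], nrow = dim(ep$data)[1])
  recording(data, ep$fs, ep$montage, reference = "other")
}

#' Downsample a recording
#'
#' Applies a windowed-sinc anti-alias low-pass at 0.45 times the target rate
#' and evaluates the band-limited signal on the new sampling grid by cubic
#' spline interpolation (the source signal is heavily oversampled after
#' anti-aliasing, so the interpolation error is negligible). Upsampling is
#' refused.
#'
#' @param rec an `eeg_recording`.
#' @param target_hz new sampling rate (<= fs).
#' @return the resampled `eeg_recording`; sample count is
#'   `round(n * target_hz / fs)` within one sample.
#' @export
resample_recording <- function(rec, target_hz = 250) {
  if (target_hz > rec$fs) stopf("no upsampling: target %g Hz > fs %g Hz", target_hz, rec$fs)
  if (target_hz == rec$fs) return(rec)
  n <- ncol(rec$data)
  cutoff <- 0.45 * target_hz
  transition <- 0.1 * target_hz
  N <- ceiling(3.3 * rec$fs / transition)
  if (N %% 2 == 0) N <- N + 1
  M <- (N - 1) / 2
  k <- -M:M
  h <- 2 * cutoff / rec$fs * sinc(2 * cutoff * k / rec$fs)
  h <- h * (0.54 - 0.46 * cos(2 * pi * (0:(N - 1)) / (N - 1)))
  t_old <- (seq_len(n) - 1) / rec$fs
  n_new <- round(n * target_hz / rec$fs)
  t_new <- pmin((seq_len(n_new) - 1) / target_hz, t_old[n])
  rec$data <- t(apply(rec$data, 1, function(x) {
    xf <- apply_fir(x, h)
    stats::spline(t_old, xf, xout = t_new)$y
  }))
  rec$fs <- target_hz
  rec
}

#' Full preprocessing chain
#'
#' Band-pass filter, whole-recording bad-channel detection, pluggable
#' artifact-removal hook (identity by default; stands in for ICA-based
#' component rejection), 2-s epoching, FASTER-style local-channel repair,
#' segment rejection, spherical-spline repair of the global bad channels,
#' average referencing, and downsampling. Channel count is preserved
#' end-to-end (bad channels are interpolated, never dropped), and identical
#' input yields identical output.
#'
#' @param rec an `eeg_recording`.
#' @param low_hz,high_hz,transition_hz band-pass settings.
#' @param flat_s,neighbor_corr,amp_sd bad-channel rule thresholds.
#' @param epoch_s epoch length in seconds.
#' @param faster_z local-channel z threshold.
#' @param amp_uv,prob_sd segment-rejection thresholds.
#' @param target_hz output sampling rate.
#' @param bandpass,detect_bads,segment logical switches for the respective
#'   stages (all on by default).
#' @param use_neighbors apply the neighbour-correlation bad-channel rule.
#'   It presumes a spatially correlated background (volume conduction) and
#'   misfires on data whose noise is spatially white, so simulation-driven
#'   callers may turn it off.
#' @param artifact_hook optional `function(recording) -> recording` applied
#'   after filtering.
#' @return list with elements `recording` (cleaned, average-referenced) and
#'   `report` (bad channels, epoch counts, thresholds used).
#' @export
preprocess_recording <- function(rec, low_hz = 1, high_hz = 40,
                                 transition_hz = 1,
                                 flat_s = 5, neighbor_corr = 0.8, amp_sd = 3,
                                 epoch_s = 2, faster_z = 3,
                                 amp_uv = 100, prob_sd = 3,
                                 target_hz = 250,
                                 bandpass = TRUE, detect_bads = TRUE,
                                 use_neighbors = TRUE, segment = TRUE,
                                 artifact_hook = NULL) {
  report <- list(thresholds = list(low_hz = low_hz, high_hz = high_hz,
                                   flat_s = flat_s, neighbor_corr = neighbor_corr,
                                   amp_sd = amp_sd, epoch_s = epoch_s,
                                   faster_z = faster_z, amp_uv = amp_uv,
                                   prob_sd = prob_sd, target_hz = target_hz))
  if (bandpass) rec <- bandpass_fir(rec, low_hz, high_hz, transition_hz)
  bads <- character()
  if (detect_bads)
    bads <- as.character(detect_bad_channels(
      rec, flat_s, neighbor_corr, amp_sd,
      use_neighbors = use_neighbors && !is.null(rec$montage)))
  report$bad_channels <- bads
  if (!is.null(artifact_hook)) rec <- artifact_hook(rec)
  if (segment) {
    ep <- epoch_recording(rec, epoch_s)
    ep <- faster_local_channels(ep, faster_z)
    flags <- reject_segments(ep, amp_uv, prob_sd)
    report$n_epochs <- length(flags)
    report$n_rejected <- sum(flags)
    report$interpolated <- ep$interpolated
    rec <- drop_rejected(ep, flags)
  }
  if (length(bads) && !is.null(rec$montage))
    rec$data <- spherical_spline_interpolate(rec$data, rec$montage, bads)
  rec$bads <- bads
  rec <- average_reference(rec)
  if (rec$fs > target_hz) rec <- resample_recording(rec, target_hz)
  rec <- average_reference(rec)
  list(recording = rec, report = report)
}
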