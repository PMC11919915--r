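# Synthetic ground-truth cohort generator: template topographies, semi-Markov
# label dynamics, forward EEG rendering, and instructor-style evaluation
# scores with planted monotone brain-behavior associations. Everything is
# deterministic given its seed, so downstream recovery can be audited
# exactly.

# Smooth spatial basis (real spherical harmonics of degree 1-2 evaluated at
# the sensor positions) used to draw realistic-looking template maps.
smooth_basis <- function(montage) {
  x <- montage$x; y <- montage$y; z <- montage$z
  cbind(x, y, z, x * y, x * z, y * z, x^2 - y^2, 2 * z^2 - x^2 - y^2)
}

#' Generate ground-truth microstate template topographies
#'
#' Draws `n_classes` average-referenced, unit-norm template maps on a scalp
#' montage. Maps are smooth (random mixtures of low-degree spherical
#' harmonics plus a small rough component) and mutually decorrelated:
#' pairwise absolute spatial correlation is at most `max_abs_corr`
#' (rejection sampling), or exactly 0 when `max_abs_corr = 0`
#' (Gram-Schmidt orthogonalization).
#'
#' @param n_channels number of channels; montage is generated with
#'   [make_montage()] unless `montage` is supplied.
#' @param n_classes number of template maps K; must be <= n_channels - 1.
#' @param max_abs_corr maximum tolerated pairwise absolute spatial
#'   correlation, in [0, 1).
#' @param seed integer seed; same seed gives bit-identical maps.
#' @param montage optional `eeg_montage` to use instead of the synthetic one.
#' @param roughness standard deviation of the white spatial component mixed
#'   into the smooth basis draw (relative scale).
#' @param max_tries rejection-sampling budget per map before failing.
#' @return channels x n_classes matrix; columns sum to ~0 and have unit norm.
#' @export
make_topographies <- function(n_channels, n_classes, max_abs_corr = 0.5,
                              seed = NULL, montage = NULL,
                              roughness = 0.15, max_tries = 2000) {
  if (is.null(montage)) montage <- make_montage(n_channels)
  if (nrow(montage) != n_channels) stopf("montage size does not match n_channels")
  if (n_classes > n_channels - 1)
    stopf("cannot place %d average-referenced maps in %d channels", n_classes, n_channels)
  if (max_abs_corr < 0 || max_abs_corr >= 1) stopf("max_abs_corr must be in [0, 1)")
  B <- smooth_basis(montage)
  draw_map <- function() {
    v <- B %*% stats::rnorm(ncol(B)) + roughness * stats::rnorm(n_channels)
    v <- v - mean(v)
    v / sqrt(sum(v^2))
  }
  with_seed(seed, {
    if (max_abs_corr == 0) {
      maps <- matrix(0, n_channels, n_classes)
      k <- 0
      tries <- 0
      while (k < n_classes) {
        v <- draw_map()
        if (k > 0) {
          v <- v - maps[, seq_len(k), drop = FALSE] %*%
            crossprod(maps[, seq_len(k), drop = FALSE], v)
          v <- v - mean(v)
        }
        nv <- sqrt(sum(v^2))
        tries <- tries + 1
        if (nv > 1e-8) {
          k <- k + 1
          maps[, k] <- v / nv
        } else if (tries > max_tries) {
          stopf("could not orthogonalize %d maps in %d channels", n_classes, n_channels)
        }
      }
      maps
    } else {
      maps <- matrix(0, n_channels, n_classes)
      k <- 0
      for (i in seq_len(n_classes)) {
        ok <- FALSE
        for (t in seq_len(max_tries)) {
          v <- draw_map()
          if (k == 0 ||
              max(abs(crossprod(maps[, seq_len(k), drop = FALSE], v))) <= max_abs_corr) {
            ok <- TRUE
            break
          }
        }
        if (!ok)
          stopf("infeasible decorrelation: could not draw map %d with |corr| <= %g after %d tries",
                i, max_abs_corr, max_tries)
        k <- k + 1
        maps[, k] <- v
      }
      maps
    }
  })
}

#' Simulate a quasi-stable microstate label sequence
#'
#' Semi-Markov dynamics: class dwell times are gamma-distributed with a
#' per-class mean (shape `shape`, so dwell histograms are peaked rather than
#' geometric), successive runs never repeat the same class, and transitions
#' are uniform over the other classes.
#'
#' @param duration_s sequence length in seconds.
#' @param fs sampling rate in Hz.
#' @param dwell_mean_ms per-class mean dwell time in ms (scalar recycled, or
#'   one value per class).
#' @param n_classes number of classes (>= 2).
#' @param shape gamma shape of the dwell distribution.
#' @param seed integer seed.
#' @return integer vector of class labels (1..n_classes), length
#'   `round(duration_s * fs)`.
#' @export
simulate_labels <- function(duration_s, fs, dwell_mean_ms = 80,
                            n_classes = max(2L, length(dwell_mean_ms)),
                            shape = 2, seed = NULL) {
  if (duration_s <= 0) stopf("duration must be positive")
  if (n_classes < 2) stopf("need at least 2 classes (no valid transition otherwise)")
  dwell <- rep_len(dwell_mean_ms, n_classes)
  if (any(dwell <= 0)) stopf("dwell means must be positive")
  if (fs * min(dwell) / 1000 < 2)
    stopf("shortest dwell mean (%.1f ms) is under 2 samples at %g Hz: states unresolvable",
          min(dwell), fs)
  n_total <- round(duration_s * fs)
  with_seed(seed, {
    labels <- integer(0)
    cur <- sample.int(n_classes, 1)
    # generate runs in chunks until the sequence is full
    while (length(labels) < n_total) {
      n_chunk <- max(16L, ceiling((n_total - length(labels)) /
                                    (min(dwell) * fs / 1000)) + 8L)
      cls <- integer(n_chunk)
      for (i in seq_len(n_chunk)) {
        cls[i] <- cur
        step <- sample.int(n_classes - 1, 1)
        cur <- ((cur - 1 + step) %% n_classes) + 1
      }
      d_ms <- stats::rgamma(n_chunk, shape = shape, rate = shape / dwell[cls])
      d_smp <- pmax(1L, as.integer(round(d_ms * fs / 1000)))
      labels <- c(labels, rep(cls, d_smp))
    }
    labels[seq_len(n_total)]
  })
}

# Rectified-sinusoid GFP envelope with an additive floor so every sample
# carries some signal. Scaled so the time-mean GFP of the clean signal is
# `gfp_mean` microvolts for unit-norm maps on C channels (GFP_t = env_t /
# sqrt(C)), which keeps per-channel amplitudes channel-count-invariant and
# in the physiological range.
gfp_envelope <- function(n, fs, n_channels, gfp_mean = 10, freq = 10,
                         floor_frac = 0.5) {
  t <- (seq_len(n) - 1) / fs
  unit <- abs(sin(2 * pi * freq * t)) + floor_frac
  gfp_mean * sqrt(n_channels) / (2 / pi + floor_frac) * unit
}

#' Noise level for a target signal-to-noise ratio
#'
#' SNR is defined as the ratio of mean signal power per channel entry to the
#' noise variance: `snr = mean(env^2)/C / noise_sd^2` for unit-norm maps on
#' C channels, with the default rectified-sinusoid envelope scaled to a
#' time-mean GFP of `gfp_mean` microvolts.
#'
#' @param snr target power ratio.
#' @param n_channels channel count C.
#' @param gfp_mean,floor_frac envelope parameters (see [render_eeg()]).
#' @return noise standard deviation in microvolts.
#' @export
noise_sd_for_snr <- function(snr, n_channels, gfp_mean = 10, floor_frac = 0.5) {
  m1 <- 2 / pi + floor_frac
  m2 <- 0.5 + 2 * floor_frac * 2 / pi + floor_frac^2
  gfp_mean * sqrt(m2 / m1^2 / snr)
}

#' Render an EEG recording from a label sequence and template maps
#'
#' Forward model: at each sample the scalp map is the active template scaled
#' by a strictly positive oscillatory envelope, with a random sign per run
#' (so downstream analysis must be polarity-invariant), plus spatially white
#' Gaussian sensor noise projected onto the average-reference subspace.
#'
#' @param labels integer label sequence from [simulate_labels()].
#' @param maps channels x K template matrix from [make_topographies()].
#' @param fs sampling rate in Hz.
#' @param gfp_mean time-mean GFP of the clean signal, microvolts.
#' @param env_freq envelope oscillation frequency in Hz.
#' @param floor_frac envelope floor relative to the rectified sinusoid's
#'   unit peak; 0.5 keeps GFP troughs at about a third of the peaks, as in
#'   broadband scalp EEG.
#' @param noise_sd sensor-noise SD in microvolts (>= 0).
#' @param montage optional montage; generated to match `maps` otherwise.
#' @param seed integer seed (run signs and noise).
#' @return an average-referenced `eeg_recording`.
#' @export
render_eeg <- function(labels, maps, fs, gfp_mean = 10, env_freq = 10,
                       floor_frac = 0.5, noise_sd = 0, montage = NULL,
                       seed = NULL) {
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  maps <- as.matrix(maps)
  if (max(labels) > ncol(maps)) stopf("labels refer to classes without a template")
  C <- nrow(maps)
  n <- length(labels)
  env <- gfp_envelope(n, fs, C, gfp_mean, env_freq, floor_frac)
  runs <- rle(labels)
  with_seed(seed, {
    signs <- sample(c(-1, 1), length(runs$lengths), replace = TRUE)
    amp <- env * rep(signs, runs$lengths)
    data <- maps[, labels, drop = FALSE] * rep(amp, each = C)
    if (noise_sd > 0) {
      noise <- matrix(stats::rnorm(C * n, sd = noise_sd), C, n)
      data <- data + center_cols(noise)
    }
    if (is.null(montage)) montage <- make_montage(C)
    recording(data, fs, montage, reference = "average")
  })
}

#' Simulate instructor evaluation scores with planted associations
#'
#' For each evaluation dimension with a planted effect, the score is a
#' strictly monotone transform of the named subject-by-stage parameter value
#' plus independent noise calibrated (via the Gaussian-copula relation
#' `r = 2*sin(pi*rho/6)`) so the population Spearman correlation between
#' parameter and score approximates the target. Dimensions without a
#' planted effect are pure noise.
#'
#' @param parameter_summary data frame with columns subject, stage, class,
#'   coverage, duration_ms, occurrence (one row per subject x stage x class),
#'   as returned by [summarize_parameters()].
#' @param planted_effects data frame with columns class, parameter
#'   ("coverage", "duration" or "occurrence"), dimension, rho (|rho| < 1);
#'   at most one effect per dimension.
#' @param noise_sd extra score noise on top of the calibrated latent (0 keeps
#'   the calibration exact; with a target of +-1 and `noise_sd = 0` the
#'   sample Spearman is exactly +-1).
#' @param score_range numeric length-2 grading scale, default 1-5.
#' @param dimensions dimension labels to emit.
#' @param seed integer seed.
#' @return data frame (subject, stage, dimension, score): the evaluation
#'   table, one row per subject x stage x dimension.
#' @export
simulate_evaluations <- function(parameter_summary, planted_effects = NULL,
                                 noise_sd = 0, score_range = c(1, 5),
                                 dimensions = paste0("D", 1:5), seed = NULL) {
  ps <- parameter_summary
  key <- unique(ps[, c("subject", "stage")])
  key <- key[order(key$subject, key$stage), , drop = FALSE]
  n <- nrow(key)
  if (!is.null(planted_effects) && nrow(planted_effects) > 0) {
    if (any(abs(planted_effects$rho) >= 1))
      stopf("target |rho| must be < 1")
    if (anyDuplicated(planted_effects$dimension))
      stopf("at most one planted effect per dimension")
    if (!all(planted_effects$dimension %in% dimensions))
      stopf("planted dimension not among emitted dimensions")
  }
  pcol <- c(coverage = "coverage", duration = "duration_ms",
            occurrence = "occurrence")
  with_seed(seed, {
    out <- lapply(dimensions, function(dim) {
      eff <- if (!is.null(planted_effects))
        planted_effects[planted_effects$dimension == dim, , drop = FALSE]
      else NULL
      if (!is.null(eff) && nrow(eff) == 1) {
        col <- pcol[[as.character(eff$parameter)]]
        if (is.null(col)) stopf("unknown parameter '%s'", eff$parameter)
        sub <- ps[ps$class == eff$class, c("subject", "stage", col)]
        idx <- match(paste(key$subject, key$stage),
                     paste(sub$subject, sub$stage))
        if (anyNA(idx)) stopf("planted effect names a class missing from the summary")
        x <- sub[[col]][idx]
        if (anyNA(x)) stopf("planted parameter has missing values")
        z <- stats::qnorm(rank(x, ties.method = "average") / (n + 1))
        z <- z / stats::sd(z)
        a <- 2 * sin(pi * eff$rho / 6)
        latent <- a * z + sqrt(1 - a^2) * stats::rnorm(n)
      } else {
        latent <- stats::rnorm(n)
      }
      score <- score_range[1] + diff(score_range) * stats::pnorm(latent)
      if (noise_sd > 0) score <- score + stats::rnorm(n, sd = noise_sd)
      data.frame(subject = key$subject, stage = key$stage,
                 dimension = dim, score = score, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Default cohort configuration
#'
#' Mirrors the study design the generator emulates: 24 subjects, 64-channel
#' cap, 250 Hz, 7 microstate classes, 22 task sessions split 7/8/7 over the
#' Training / PracticeA / PracticeB stages (session durations kept at 30 s
#' for desk-scale work), 80 ms mean dwell, sensor noise at SNR 4, and
#' planted rank-correlations between selected class parameters and
#' evaluation dimensions echoing the positive class-E/G and negative class-C
#' association structure.
#'
#' @param n_subjects,n_channels,fs,n_classes cohort dimensions.
#' @param sessions_per_stage integer vector (one per stage) of task sessions.
#' @param stage_names stage labels in curriculum order.
#' @param session_duration_s duration of each task session.
#' @param dwell_mean_ms per-class mean dwell (recycled).
#' @param subject_sd log-normal sigma of the per-subject, per-class dwell
#'   multipliers: subjects genuinely differ in their microstate dynamics
#'   (about a 15 percent coefficient of variation by default, in the range
#'   reported for temporal microstate parameters), which is what gives the
#'   temporal parameters a between-subject rank structure that evaluation
#'   scores can be planted against.
#' @param snr signal-to-noise power ratio (see [noise_sd_for_snr()]).
#' @param gfp_mean time-mean clean-signal GFP, microvolts.
#' @param max_abs_corr decorrelation bound for the planted maps.
#' @param planted_effects data frame (class, parameter, dimension, rho).
#' @param score_noise_sd extra evaluation-score noise.
#' @param seed global integer seed for the cohort.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 24, n_channels = 64, fs = 250,
                          n_classes = 7,
                          sessions_per_stage = c(7, 8, 7),
                          stage_names = c("Training", "PracticeA", "PracticeB"),
                          session_duration_s = 30,
                          dwell_mean_ms = 80,
                          subject_sd = 0.15,
                          snr = 4,
                          gfp_mean = 10,
                          max_abs_corr = 0.5,
                          planted_effects = default_planted_effects(),
                          score_noise_sd = 0,
                          seed = 1) {
  if (length(sessions_per_stage) != length(stage_names))
    stopf("sessions_per_stage must match stage_names")
  if (n_classes > n_channels - 1) stopf("n_classes must be <= n_channels - 1")
  cfg <- list(n_subjects = n_subjects, n_channels = n_channels, fs = fs,
              n_classes = n_classes, sessions_per_stage = sessions_per_stage,
              stage_names = stage_names,
              session_duration_s = session_duration_s,
              dwell_mean_ms = dwell_mean_ms, subject_sd = subject_sd,
              snr = snr,
              gfp_mean = gfp_mean, max_abs_corr = max_abs_corr,
              planted_effects = planted_effects,
              score_noise_sd = score_noise_sd, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

#' Default planted brain-behavior effects
#'
#' Positive rank-correlations for late-alphabet classes (coverage of class 7
#' with D1, coverage of class 5 with D4, duration of class 4 with D3) and a
#' negative one for class-3 occurrence with D5; D2 carries no effect.
#' @return data frame (class, parameter, dimension, rho).
#' @export
default_planted_effects <- function() {
  data.frame(class = c(7L, 5L, 4L, 3L),
             parameter = c("coverage", "coverage", "duration", "occurrence"),
             dimension = c("D1", "D4", "D3", "D5"),
             rho = c(0.6, 0.6, 0.5, -0.6),
             stringsAsFactors = FALSE)
}

# Session bookkeeping table for a config.
session_plan <- function(cfg) {
  data.frame(stage = rep(cfg$stage_names, cfg$sessions_per_stage),
             session = seq_len(sum(cfg$sessions_per_stage)),
             duration_s = cfg$session_duration_s,
             stringsAsFactors = FALSE)
}

# Deterministic per-(subject, session) seed.
session_seed <- function(cfg, subject, session, what) {
  derive_seed(cfg$seed, what, subject * 1000L + session)
}

#' Simulate a ground-truth cohort
#'
#' Generates planted template maps, per subject x session label sequences,
#' the implied true temporal parameters (computed from the labels, not from
#' the configuration targets), and an evaluation table with the configured
#' planted associations. EEG is not materialized here (a full cohort would
#' be large); render any single session on demand with
#' [render_cohort_recording()], which is deterministic given the cohort.
#'
#' @param cfg a [cohort_config()].
#' @return a list of class `simulated_cohort` with elements `true_maps`,
#'   `montage`, `true_labels` (list indexed `[[subject]][[session]]`),
#'   `true_parameters` (tidy data frame), `parameter_summary`,
#'   `evaluations`, `plan`, and `config`.
#' @export
simulate_cohort <- function(cfg) {
  mont <- make_montage(cfg$n_channels)
  maps <- make_topographies(cfg$n_channels, cfg$n_classes,
                            max_abs_corr = cfg$max_abs_corr,
                            seed = derive_seed(cfg$seed, "maps"),
                            montage = mont)
  plan <- session_plan(cfg)
  # per-subject, per-class dwell means: shared base times log-normal
  # subject multipliers (the planted between-subject dynamics)
  base_dwell <- rep_len(cfg$dwell_mean_ms, cfg$n_classes)
  mult <- with_seed(derive_seed(cfg$seed, "subject_dwell"), {
    matrix(exp(stats::rnorm(cfg$n_subjects * cfg$n_classes,
                            sd = cfg$subject_sd %||% 0)),
           cfg$n_subjects, cfg$n_classes)
  })
  subject_dwell <- sweep(mult, 2, base_dwell, "*")
  true_labels <- lapply(seq_len(cfg$n_subjects), function(s) {
    lapply(seq_len(nrow(plan)), function(i) {
      simulate_labels(plan$duration_s[i], cfg$fs, subject_dwell[s, ],
                      n_classes = cfg$n_classes,
                      seed = session_seed(cfg, s, i, "labels"))
    })
  })
  rows <- list()
  for (s in seq_len(cfg$n_subjects)) {
    for (i in seq_len(nrow(plan))) {
      p <- microstate_parameters(true_labels[[s]][[i]], cfg$fs, cfg$n_classes)
      p$subject <- s
      p$stage <- plan$stage[i]
      p$session <- plan$session[i]
      rows[[length(rows) + 1L]] <- p
    }
  }
  pt <- do.call(rbind, rows)
  pt <- pt[, c("subject", "stage", "session", "class",
               "coverage", "duration_ms", "occurrence")]
  summ <- summarize_parameters(pt)
  evals <- simulate_evaluations(summ, cfg$planted_effects,
                                noise_sd = cfg$score_noise_sd,
                                seed = derive_seed(cfg$seed, "evals"))
  structure(list(true_maps = maps, montage = mont,
                 subject_dwell_ms = subject_dwell, true_labels = true_labels,
                 true_parameters = pt, parameter_summary = summ,
                 evaluations = evals, plan = plan, config = cfg),
            class = "simulated_cohort")
}

#' Render the EEG of one cohort session
#'
#' Deterministic given the cohort: the rendering seed is derived from the
#' cohort seed and the (subject, session) pair, so a session can be rendered
#' lazily, in any order, with identical results.
#'
#' @param cohort a `simulated_cohort`.
#' @param subject,session indices into the cohort plan.
#' @return an `eeg_recording`.
#' @export
render_cohort_recording <- function(cohort, subject, session) {
  cfg <- cohort$config
  noise_sd <- noise_sd_for_snr(cfg$snr, cfg$n_channels, cfg$gfp_mean)
  render_eeg(cohort$true_labels[[subject]][[session]], cohort$true_maps,
             cfg$fs, gfp_mean = cfg$gfp_mean, noise_sd = noise_sd,
             montage = cohort$montage,
             seed = session_seed(cfg, subject, session, "render"))
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<simulated_cohort> %d subjects x %d sessions (%s), %d ch @ %g Hz, K = %d\n",
              cfg$n_subjects, nrow(x$plan),
              paste(cfg$sessions_per_stage, collapse = "/"),
              cfg$n_channels, cfg$fs, cfg$n_classes))
  invisible(x)
}
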