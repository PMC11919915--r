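# Temporal microstate parameters: coverage, mean duration, occurrence.
# Truncated boundary runs are counted in full by default, which makes the
# identity coverage = occurrence * duration / 1000 exact.

label_runs <- function(labels, count_truncated = TRUE) {
  r <- rle(as.integer(labels))
  if (!count_truncated && length(r$lengths) > 2) {
    keep <- seq(2, length(r$lengths) - 1)
    r$lengths <- r$lengths[keep]
    r$values <- r$values[keep]
  }
  r
}

#' Per-class coverage of a label sequence
#'
#' Fraction of the total analysis time spent in each class.
#'
#' @param labels integer label sequence (classes 1..n_classes).
#' @param n_classes number of classes (defaults to the maximum label seen).
#' @return named numeric vector of fractions summing to 1.
#' @export
ms_coverage <- function(labels, n_classes = max(labels)) {
  if (length(labels) == 0) stopf("empty label sequence")
  tabulate(labels, n_classes) / length(labels)
}

#' Per-class mean duration of a label sequence
#'
#' Mean contiguous-run length of each class, in milliseconds. Boundary
#' (possibly truncated) runs are included unless `count_truncated = FALSE`.
#' A class that never occurs gets `NA` (not zero, which would bias means).
#'
#' @param labels integer label sequence.
#' @param fs sampling rate in Hz.
#' @param n_classes number of classes.
#' @param count_truncated include the first and last run.
#' @return numeric vector of mean durations in ms (NA where absent).
#' @export
ms_duration <- function(labels, fs, n_classes = max(labels),
                        count_truncated = TRUE) {
  if (fs <= 0) stopf("fs must be positive")
  r <- label_runs(labels, count_truncated)
  out <- rep(NA_real_, n_classes)
  if (length(r$values)) {
    m <- tapply(r$lengths, factor(r$values, levels = seq_len(n_classes)), mean)
    out <- as.numeric(m) * 1000 / fs
  }
  out
}

#' Per-class occurrence rate of a label sequence
#'
#' Number of contiguous runs of each class per second of analysis time.
#'
#' @inheritParams ms_duration
#' @return numeric vector of rates in events/s (0 where absent).
#' @export
ms_occurrence <- function(labels, fs, n_classes = max(labels),
                          count_truncated = TRUE) {
  if (fs <= 0) stopf("fs must be positive")
  r <- label_runs(labels, count_truncated)
  counts <- tabulate(r$values, n_classes)
  counts / (length(labels) / fs)
}

#' All three temporal parameters of one label sequence
#'
#' @inheritParams ms_duration
#' @return data frame (class, coverage, duration_ms, occurrence), one row
#'   per class.
#' @export
microstate_parameters <- function(labels, fs, n_classes = max(labels),
                                  count_truncated = TRUE) {
  data.frame(class = seq_len(n_classes),
             coverage = ms_coverage(labels, n_classes),
             duration_ms = ms_duration(labels, fs, n_classes, count_truncated),
             occurrence = ms_occurrence(labels, fs, n_classes, count_truncated))
}

#' Aggregate a parameter table to subject x stage x class means
#'
#' Unweighted mean across sessions within each subject x stage cell.
#' Missing durations (class absent in a session) are excluded pairwise; the
#' number of sessions contributing to the duration mean is reported.
#'
#' @param parameter_table data frame with columns subject, stage, session,
#'   class, coverage, duration_ms, occurrence.
#' @return data frame (subject, stage, class, coverage, duration_ms,
#'   occurrence, n_sessions, n_duration).
#' @export
summarize_parameters <- function(parameter_table) {
  pt <- parameter_table
  need <- c("subject", "stage", "session", "class",
            "coverage", "duration_ms", "occurrence")
  if (!all(need %in% names(pt))) stopf("parameter table is missing columns")
  cells <- unique(pt[, c("subject", "stage")])
  if (nrow(cells) == 0) stopf("empty parameter table")
  key <- interaction(pt$subject, pt$stage, pt$class, drop = TRUE)
  agg <- function(x, f) as.numeric(tapply(x, key, f))
  first <- function(x) tapply(x, key, function(v) v[1])
  out <- data.frame(
    subject = as.vector(first(pt$subject)),
    stage = as.vector(first(as.character(pt$stage))),
    class = as.vector(first(pt$class)),
    coverage = agg(pt$coverage, mean),
    duration_ms = agg(pt$duration_ms, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) mean(v) else NA_real_
    }),
    occurrence = agg(pt$occurrence, mean),
    n_sessions = agg(pt$coverage, length),
    n_duration = agg(pt$duration_ms, function(v) sum(!is.na(v))),
    stringsAsFactors = FALSE)
  if (any(out$n_sessions == 0)) stopf("a subject x stage cell has no sessions")
  out[order(out$subject, out$stage, out$class), , drop = FALSE]
}
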