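#' Construct an EEG recording
#'
#' The carrier object for all signal-processing stages: a channels x samples
#' voltage matrix in microvolts plus sampling rate, montage, reference state
#' and the set of channels marked bad.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param montage an `eeg_montage` with one row per data row, or NULL.
#' @param reference one of "average", "mastoid", "other".
#' @param bads character vector of bad channel names.
#' @return an object of class `eeg_recording`.
#' @export
recording <- function(data, fs, montage = NULL,
                      reference = c("average", "mastoid", "other"),
                      bads = character()) {
  data <- as.matrix(data)
  reference <- match.arg(reference)
  if (!is.numeric(data)) stopf("recording data must be numeric")
  if (fs <= 0) stopf("sampling rate must be positive")
  if (!is.null(montage)) {
    if (nrow(montage) != nrow(data))
      stopf("montage has %d channels but data has %d rows",
            nrow(montage), nrow(data))
    rownames(data) <- montage$name
    if (length(bads) && !all(bads %in% montage$name))
      stopf("bad-channel names not present in montage")
  }
  structure(list(data = data, fs = fs, montage = montage,
                 reference = reference, bads = as.character(bads)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %s reference",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$reference))
  if (length(x$bads)) cat(sprintf(", %d bad channel(s)", length(x$bads)))
  cat("\n")
  invisible(x)
}

n_channels <- function(rec) nrow(rec$data)
n_samples <- function(rec) ncol(rec$data)

#' Re-reference a recording to the common average
#'
#' Subtracts the instantaneous mean across channels from every sample, so
#' the channel mean is zero at each time point. Idempotent.
#'
#' @param rec an `eeg_recording`.
#' @return the re-referenced `eeg_recording` with reference = "average".
#' @export
average_reference <- function(rec) {
  rec$data <- center_cols(rec$data)
  rec$reference <- "average"
  rec
}

is_average_referenced <- function(rec, tol = 1e-6) {
  max(abs(colMeans(rec$data))) <= tol
}

assert_average_reference <- function(rec, what = "operation") {
  if (rec$reference != "average" || !is_average_referenced(rec, 1e-6))
    stopf("%s requires an average-referenced recording; call average_reference() first",
          what)
  invisible(rec)
}
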