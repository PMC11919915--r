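# Plain-text on-disk formats. Recordings use a two-file layout: a JSON
# header (sampling rate, reference, bad channels, montage) next to a
# whitespace-delimited numeric matrix written at full double precision, so
# a write/read round trip is bit-lossless. Tables are CSV.

#' Write a recording to the documented text layout
#'
#' Writes `<prefix>.json` (header: fs, reference, bads, montage) and
#' `<prefix>.dat` (channels x samples matrix, one channel per row, `%.17g`
#' formatted so the round trip is lossless).
#'
#' @param rec an `eeg_recording`.
#' @param prefix path prefix (no extension).
#' @return `prefix`, invisibly.
#' @export
write_recording <- function(rec, prefix) {
  hdr <- list(fs = rec$fs, reference = rec$reference, bads = rec$bads,
              n_channels = nrow(rec$data), n_samples = ncol(rec$data),
              montage = if (!is.null(rec$montage)) as.data.frame(rec$montage))
  jsonlite::write_json(hdr, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(paste0(prefix, ".dat"), "w")
  on.exit(close(con))
  for (c in seq_len(nrow(rec$data)))
    writeLines(paste(sprintf("%.17g", rec$data[c, ]), collapse = " "), con)
  invisible(prefix)
}

#' Read a recording from the text layout
#'
#' Counterpart of [write_recording()]. If `montage` is supplied, channels on
#' disk are matched and reordered by name against it; a name mismatch is an
#' error naming the offending channels.
#'
#' @param prefix path prefix used at write time.
#' @param montage optional `eeg_montage` dictating channel order.
#' @return an `eeg_recording`.
#' @export
read_recording <- function(prefix, montage = NULL) {
  hpath <- paste0(prefix, ".json")
  dpath <- paste0(prefix, ".dat")
  if (!file.exists(hpath) || !file.exists(dpath))
    stopf("recording files not found at prefix %s", prefix)
  hdr <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  data <- matrix(scan(dpath, quiet = TRUE), nrow = hdr$n_channels,
                 ncol = hdr$n_samples, byrow = TRUE)
  mont_file <- if (!is.null(hdr$montage))
    montage(hdr$montage$name, as.matrix(hdr$montage[, c("x", "y", "z")]))
  use_mont <- mont_file
  if (!is.null(montage)) {
    if (is.null(mont_file)) stopf("file %s carries no montage to match against", hpath)
    ix <- match(montage$name, mont_file$name)
    if (anyNA(ix))
      stopf("channels missing on disk: %s",
            paste(montage$name[is.na(ix)], collapse = ", "))
    data <- data[ix, , drop = FALSE]
    use_mont <- montage
  }
  recording(data, hdr$fs, use_mont,
            reference = hdr$reference %||% "other",
            bads = unlist(hdr$bads) %||% character())
}

#' Serialize a microstate set to JSON
#' @param set a `microstate_set`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_microstate_set <- function(set, path) {
  jsonlite::write_json(
    list(K = set$K, letters = set$letters, cv = set$cv, gev = set$gev,
         sigma2 = set$sigma2, provenance = set$provenance,
         maps = t(set$maps)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a microstate set from JSON
#' @param path file written by [write_microstate_set()].
#' @return a `microstate_set`.
#' @export
read_microstate_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(maps = t(x$maps), K = x$K,
                 letters = as.character(x$letters), cv = x$cv, gev = x$gev,
                 sigma2 = x$sigma2, provenance = x$provenance),
            class = "microstate_set")
}

#' Write a label sequence as compact CSV
#' @param labels a `label_sequence` from [backfit()].
#' @param path destination CSV (columns sample, label, abs_corr).
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(data.frame(sample = seq_along(labels$labels),
                              label = labels$labels,
                              abs_corr = labels$abs_corr),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Fills unspecified fields with package defaults; see
#' [default_pipeline_config()].
#'
#' @param path YAML file.
#' @return a nested configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  merge_config(default_pipeline_config(), user)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) && !is.data.frame(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Default pipeline configuration
#'
#' The nested list consumed by [run_pipeline()]: a `cohort` block (arguments
#' of [cohort_config()] minus the seed), a `preprocess` block (stage
#' switches and thresholds), a `microstates` block (K, restarts, peak
#' distance, aggregation draws) and a `stats` block, plus the global `seed`
#' every stage derives its sub-stream from.
#'
#' @return a nested list.
#' @export
default_pipeline_config <- function() {
  list(seed = 1,
       cohort = list(n_subjects = 24, n_channels = 64, fs = 250,
                     n_classes = 7, sessions_per_stage = c(7, 8, 7),
                     session_duration_s = 30, dwell_mean_ms = 80,
                     snr = 4, gfp_mean = 10),
       preprocess = list(enabled = TRUE, bandpass = TRUE, low_hz = 1,
                         high_hz = 40, transition_hz = 1, epoch_s = 2,
                         amp_uv = 100, prob_sd = 3, faster_z = 3,
                         detect_bads = TRUE, use_neighbors = FALSE,
                         target_hz = 250),
       microstates = list(k = 7, n_init = 100, min_peak_distance = 10,
                          aggregate_n_iter = 100),
       stats = list(alpha = 0.05, unit = "subject_stage"))
}
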