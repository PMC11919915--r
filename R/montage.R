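#' Construct a scalp montage
#'
#' A montage is a data frame with one row per channel holding the channel
#' name and a unit-norm 3D position on the scalp sphere (x = right,
#' y = anterior, z = superior).
#'
#' @param names character vector of unique channel names.
#' @param positions numeric matrix (channels x 3) of sensor positions;
#'   rows are normalized to unit length and must be within 1e-6 of it.
#' @return an object of class `eeg_montage` (a data frame with columns
#'   `name`, `x`, `y`, `z`).
#' @export
montage <- function(names, positions) {
  positions <- as.matrix(positions)
  if (anyDuplicated(names)) stopf("montage channel names must be unique")
  if (nrow(positions) != length(names) || ncol(positions) != 3)
    stopf("positions must be a %d x 3 matrix", length(names))
  nrm <- sqrt(rowSums(positions^2))
  if (any(abs(nrm - 1) > 1e-6))
    stopf("montage positions must lie on the unit sphere (max |norm-1| = %.2e)",
          max(abs(nrm - 1)))
  out <- data.frame(name = as.character(names),
                    x = positions[, 1], y = positions[, 2], z = positions[, 3],
                    stringsAsFactors = FALSE)
  class(out) <- c("eeg_montage", "data.frame")
  out
}

#' Generate a synthetic scalp layout
#'
#' Places `n_channels` sensors quasi-uniformly on the upper spherical cap
#' (down to z = -0.25, roughly the coverage of a high-density EEG cap) using
#' a Fibonacci lattice. Deterministic; intended for simulation and testing
#' when no measured electrode layout is available.
#'
#' @param n_channels number of channels (>= 4).
#' @return an `eeg_montage`.
#' @export
make_montage <- function(n_channels) {
  if (n_channels < 4) stopf("need at least 4 channels")
  i <- seq_len(n_channels)
  z_top <- 1
  z_bot <- -0.25
  z <- z_top - (i - 0.5) * (z_top - z_bot) / n_channels
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (i - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(r * cos(phi), r * sin(phi), z)
  pos <- pos / sqrt(rowSums(pos^2))
  montage(sprintf("E%03d", i), pos)
}

#' Read a montage from a CSV file
#'
#' Expects columns `name`, `x`, `y`, `z`; positions are renormalized to unit
#' length (tolerating small rounding in the file).
#'
#' @param path CSV file path.
#' @return an `eeg_montage`.
#' @export
read_montage <- function(path) {
  if (!file.exists(path)) stopf("montage file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stopf("montage file %s must have columns name,x,y,z", path)
  pos <- as.matrix(df[, c("x", "y", "z")])
  nrm <- sqrt(rowSums(pos^2))
  if (any(nrm == 0)) stopf("montage file %s has a zero position", path)
  if (any(abs(nrm - 1) > 1e-3))
    stopf("montage file %s positions are not close to unit norm", path)
  montage(df$name, pos / nrm)
}

#' Write a montage to CSV
#' @param m an `eeg_montage`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_montage <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

# k nearest neighbours of every channel by great-circle distance.
# Returns a list of integer index vectors.
montage_neighbors <- function(m, k = 4) {
  pos <- as.matrix(m[, c("x", "y", "z")])
  cosang <- tcrossprod(pos)
  cosang <- pmin(pmax(cosang, -1), 1)
  d <- acos(cosang)
  diag(d) <- Inf
  lapply(seq_len(nrow(pos)), function(i) order(d[i, ])[seq_len(min(k, nrow(pos) - 1))])
}
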