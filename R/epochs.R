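#' Epoched EEG container
#'
#' Bundles a trials x channels x samples amplitude array with its sampling
#' metadata and a per-trial label table.  Epoch time is half-open
#' `[t0, t0 + samples/rate)`; sample `i` covers time `t0 + (i-1)/rate`.
#'
#' @param data numeric array, trials x channels x samples.
#' @param sampling_rate sampling rate in Hz.
#' @param t0 epoch start in seconds relative to the locking event.
#' @param channel_ids character vector of unique channel identifiers.
#' @param labels `data.frame` with one row per trial (task, phase, category,
#'   block, group, subject, ... as available).
#' @return An `epoch_set` object.
#' @export
epoch_set <- function(data, sampling_rate, t0 = 0, channel_ids = NULL,
                      labels = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(dim(data)[2]))
  if (is.null(labels)) labels <- data.frame(row.names = seq_len(dim(data)[1]))
  x <- structure(list(data = data, sampling_rate = sampling_rate, t0 = t0,
                      channel_ids = as.character(channel_ids),
                      labels = labels),
                 class = "epoch_set")
  validate_epoch_set(x)
  x
}

validate_epoch_set <- function(x) {
  d <- dim(x$data)
  if (length(x$channel_ids) != d[2])
    stop("channel count mismatch between data and channel_ids")
  if (anyDuplicated(x$channel_ids)) stop("channel_ids must be unique")
  if (nrow(x$labels) != d[1])
    stop("labels row count must equal the number of trials")
  if (!is.numeric(x$sampling_rate) || x$sampling_rate <= 0)
    stop("sampling_rate must be positive")
  if (!all(is.finite(x$data))) stop("epoch data must be finite")
  invisible(x)
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("epoch_set: %d trials x %d channels x %d samples @ %g Hz, t0 = %g s\n",
              d[1], d[2], d[3], x$sampling_rate, x$t0))
  if (ncol(x$labels)) {
    cat("labels:", paste(names(x$labels), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

n_trials <- function(x) dim(x$data)[1]

#' Subset trials of an epoch set
#'
#' @param x an `epoch_set`.
#' @param i trial index vector (integer or logical).
#' @param ... ignored.
#' @return An `epoch_set` with the selected trials.
#' @export
`[.epoch_set` <- function(x, i, ...) {
  epoch_set(x$data[i, , , drop = FALSE], x$sampling_rate, x$t0,
            x$channel_ids, x$labels[i, , drop = FALSE])
}

#' Epoch sample times
#'
#' @param x an `epoch_set`.
#' @return Numeric vector of sample onset times in seconds.
#' @export
epoch_times <- function(x) x$t0 + (seq_len(dim(x$data)[3]) - 1) / x$sampling_rate

#' Crop an epoch set to a time interval
#'
#' Keeps samples whose onset time lies in the half-open interval
#' `[tmin, tmax)`.
#'
#' @param x an `epoch_set`.
#' @param tmin,tmax interval bounds in seconds.
#' @return Cropped `epoch_set` with `t0` updated.
#' @export
crop_epochs <- function(x, tmin, tmax) {
  t <- epoch_times(x)
  keep <- which(t >= tmin - 1e-9 & t < tmax - 1e-9)
  if (!length(keep)) stop("crop window contains no samples")
  epoch_set(x$data[, , keep, drop = FALSE], x$sampling_rate, t[keep[1]],
            x$channel_ids, x$labels)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude over `window` so the
#' window mean becomes zero.
#'
#' @param epochs an `epoch_set`.
#' @param window length-2 numeric, half-open baseline interval in seconds
#'   (e.g. `c(-0.2, 0)` for a 200 ms prestimulus baseline).
#' @return The corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window = c(-0.2, 0)) {
  t <- epoch_times(epochs)
  idx <- which(t >= window[1] - 1e-9 & t < window[2] - 1e-9)
  if (!length(idx))
    stop("baseline window lies outside the epoch")
  bl <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - array(bl, dim(epochs$data))
  epochs
}

#' Resample epochs to a lower sampling rate
#'
#' Polyphase anti-aliased resampling (via \code{signal::resample}) of every
#' trial and channel.  Only downsampling (or the identity) is supported.
#'
#' @param epochs an `epoch_set`.
#' @param target_rate new sampling rate in Hz, `<= sampling_rate`.
#' @return An `epoch_set` at `target_rate`.
#' @export
resample_epochs <- function(epochs, target_rate) {
  if (target_rate > epochs$sampling_rate)
    stop("upsampling is not supported")
  if (target_rate == epochs$sampling_rate) return(epochs)
  ratio <- epochs$sampling_rate / target_rate
  d <- dim(epochs$data)
  if (abs(ratio - round(ratio)) < 1e-9) {
    # integer decimation: zero-phase IIR anti-alias filter then pick
    q <- as.integer(round(ratio))
    n_out <- ceiling(d[3] / q)
    out <- array(0, c(d[1], d[2], n_out))
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
      out[i, j, ] <- signal::decimate(epochs$data[i, j, ], q)
  } else {
    frac <- .as_fraction(target_rate / epochs$sampling_rate)
    n_out <- ceiling(d[3] * frac[1] / frac[2])
    out <- array(0, c(d[1], d[2], n_out))
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
      out[i, j, ] <- signal::resample(epochs$data[i, j, ], frac[1], frac[2])
  }
  epoch_set(out, target_rate, epochs$t0, epochs$channel_ids, epochs$labels)
}

.as_fraction <- function(x, max_den = 10000L) {
  for (q in seq_len(max_den)) {
    p <- x * q
    if (abs(p - round(p)) < 1e-9) return(c(as.integer(round(p)), q))
  }
  stop("rate ratio is not a manageable rational number")
}

#' Optional zero-phase band-pass filter
#'
#' Convenience hook for real recordings (synthetic epochs are generated
#' band-limited and clean): forward-backward Butterworth filtering per trial
#' and channel.
#'
#' @param epochs an `epoch_set`.
#' @param low,high band edges in Hz (`NULL` to skip one side).
#' @param order filter order.
#' @return Filtered `epoch_set`.
#' @export
bandpass_epochs <- function(epochs, low = NULL, high = NULL, order = 4L) {
  ny <- epochs$sampling_rate / 2
  filt <- if (!is.null(low) && !is.null(high)) {
    signal::butter(order, c(low, high) / ny, type = "pass")
  } else if (!is.null(high)) {
    signal::butter(order, high / ny, type = "low")
  } else if (!is.null(low)) {
    signal::butter(order, low / ny, type = "high")
  } else return(epochs)
  d <- dim(epochs$data)
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    epochs$data[i, j, ] <- signal::filtfilt(filt, epochs$data[i, j, ])
  epochs
}

#' Save epochs to an HDF5 container
#'
#' Writes the amplitude tensor as float32 dataset `epochs` plus metadata:
#' scalar datasets `sampling_rate_hz` and `t0_s`, a `channel_ids` vector, and
#' the label table serialized as JSON under `labels_json`.
#'
#' @param epochs an `epoch_set`.
#' @param path output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
save_epochs <- function(epochs, path) {
  validate_epoch_set(epochs)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  d <- dim(epochs$data)
  rhdf5::h5createDataset(path, "epochs", dims = d, H5type = "H5T_IEEE_F32LE",
                         chunk = c(min(d[1], 16L), d[2], d[3]))
  rhdf5::h5write(epochs$data, path, "epochs")
  rhdf5::h5write(epochs$sampling_rate, path, "sampling_rate_hz")
  rhdf5::h5write(epochs$t0, path, "t0_s")
  rhdf5::h5write(epochs$channel_ids, path, "channel_ids")
  rhdf5::h5write(as.character(jsonlite::toJSON(epochs$labels, digits = NA)),
                 path, "labels_json")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Load epochs from an HDF5 container
#'
#' @param path file written by [save_epochs()].
#' @return An `epoch_set` (data in float32 precision).
#' @export
load_epochs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  have <- rhdf5::h5ls(path, recursive = FALSE)$name
  needed <- c("epochs", "sampling_rate_hz", "t0_s", "channel_ids", "labels_json")
  missing <- setdiff(needed, have)
  if (length(missing))
    stop("malformed epoch container, missing field(s): ",
         paste(missing, collapse = ", "))
  data <- rhdf5::h5read(path, "epochs")
  labels <- as.data.frame(jsonlite::fromJSON(rhdf5::h5read(path, "labels_json")))
  if (nrow(labels) == 0 && ncol(labels) == 0)
    labels <- data.frame(row.names = seq_len(dim(data)[1]))
  out <- epoch_set(data,
                   as.numeric(rhdf5::h5read(path, "sampling_rate_hz")),
                   as.numeric(rhdf5::h5read(path, "t0_s")),
                   as.character(rhdf5::h5read(path, "channel_ids")),
                   labels)
  rhdf5::h5closeAll()
  out
}

#' Summarize an epoch container file
#'
#' @param path epoch HDF5 file.
#' @return The `epoch_set`, invisibly; prints shape and label summary.
#' @export
epochs_info <- function(path) {
  x <- load_epochs(path)
  print(x)
  for (col in names(x$labels)) {
    v <- x$labels[[col]]
    if (is.character(v) || is.factor(v)) {
      tab <- table(v)
      cat(sprintf("  %s: %s\n", col,
                  paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
    }
  }
  invisible(x)
}
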