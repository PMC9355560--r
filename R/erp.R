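#' Condition-average ERP waveforms
#'
#' Averages epochs within each combination of the given label columns into
#' per-condition channel x time waveforms.
#'
#' @param epochs an [epoch_set()], typically baseline-corrected
#'   stimulus-locked learning-task epochs.
#' @param by label columns defining the conditions.
#' @return An `erp_set`: conditions x channels x samples array, the
#'   condition table, sample times and channel ids.
#' @export
compute_erp <- function(epochs, by = c("block_type", "stimulus")) {
  miss <- setdiff(by, names(epochs$labels))
  if (length(miss)) stop("missing label column(s): ", paste(miss, collapse = ", "))
  key <- interaction(epochs$labels[by], drop = TRUE, sep = "|")
  conds <- levels(key)
  d <- dim(epochs$data)
  data <- array(0, c(length(conds), d[2], d[3]))
  for (i in seq_along(conds))
    data[i, , ] <- colMeans(epochs$data[key == conds[i], , , drop = FALSE], dims = 1)
  cond_tab <- unique(epochs$labels[by])
  cond_tab <- cond_tab[match(conds, do.call(paste, c(unname(cond_tab), sep = "|"))), ,
                       drop = FALSE]
  rownames(cond_tab) <- NULL
  structure(list(data = data, conditions = cond_tab,
                 times = epoch_times(epochs), channel_ids = epochs$channel_ids),
            class = "erp_set")
}

#' @export
print.erp_set <- function(x, ...) {
  cat(sprintf("erp_set: %d conditions x %d channels x %d samples, t = [%.3g, %.3g] s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times), max(x$times)))
  invisible(x)
}

.erp_channel <- function(erp, channel) {
  j <- match(channel, erp$channel_ids)
  if (is.na(j)) stop("channel not present: ", channel)
  j
}

# grand average across conditions at one channel
.erp_grand_channel <- function(erp, channel) {
  j <- .erp_channel(erp, channel)
  m <- erp$data[, j, , drop = FALSE]
  colMeans(matrix(m, nrow = dim(m)[1]))
}

#' Find the P1 peak at an occipital channel
#'
#' Locates the largest positive deflection of the condition grand average
#' within the search window (default 75-200 ms, the canonical occipital P1
#' range).  Peak-finding on the grand average (rather than per condition)
#' mirrors the two-step procedure in which a fixed window around the common
#' peak is then used to quantify each condition.
#'
#' @param erp an `erp_set`.
#' @param channel channel id (default `"Oz"`).
#' @param search length-2 search window in seconds.
#' @return List with `latency_s` and `amplitude`.
#' @export
find_p1_peak <- function(erp, channel = "Oz", search = c(0.075, 0.200)) {
  wave <- .erp_grand_channel(erp, channel)
  idx <- which(erp$times >= search[1] - 1e-9 & erp$times <= search[2] + 1e-9)
  if (!length(idx)) stop("search window lies outside the time axis")
  k <- idx[which.max(wave[idx])]
  if (wave[k] <= 0) stop("no positive deflection in the search window")
  list(latency_s = erp$times[k], amplitude = wave[k])
}

#' Mean amplitude over a time window
#'
#' Arithmetic mean of one channel's samples whose onset times fall in the
#' half-open window (default 80-150 ms, the fixed P1 quantification window).
#'
#' @param erp an `erp_set`.
#' @param channel channel id.
#' @param window length-2 window in seconds.
#' @param condition condition row index; `NULL` (default) returns one value
#'   per condition.
#' @return Named numeric vector of window means (one per condition), or a
#'   scalar if `condition` is given.
#' @export
window_mean <- function(erp, channel = "Oz", window = c(0.080, 0.150),
                        condition = NULL) {
  j <- .erp_channel(erp, channel)
  idx <- which(erp$times >= window[1] - 1e-9 & erp$times < window[2] - 1e-9)
  if (!length(idx)) stop("window lies outside the time axis")
  vals <- rowMeans(erp$data[, j, idx, drop = FALSE][, 1, , drop = FALSE])
  names(vals) <- do.call(paste, c(unname(erp$conditions), sep = "|"))
  if (!is.null(condition)) vals[[condition]] else vals
}

#' Late centroparietal time-bin means
#'
#' Subdivides the late span (default 400-700 ms) into consecutive
#' non-overlapping bins (default 50 ms, giving six bins) and returns the
#' mean amplitude over the given channel set per condition and bin.
#'
#' @param erp an `erp_set`.
#' @param channels channel ids to average over (default: the CPz
#'   neighbourhood of the packaged montage).
#' @param span length-2 span in seconds; must be divisible by `bin`.
#' @param bin bin width in seconds.
#' @return A conditions x bins matrix with bin-labelled columns.
#' @export
late_bins <- function(erp, channels = c("CPz", "CP1", "CP2", "Cz", "Pz"),
                      span = c(0.400, 0.700), bin = 0.050) {
  n_bins <- (span[2] - span[1]) / bin
  if (abs(n_bins - round(n_bins)) > 1e-9)
    stop_config("span is not divisible by the bin width")
  n_bins <- round(n_bins)
  channels <- intersect(channels, erp$channel_ids)
  if (!length(channels)) stop("none of the requested channels are present")
  js <- match(channels, erp$channel_ids)
  chan_mean <- apply(erp$data[, js, , drop = FALSE], c(1, 3), mean)
  out <- matrix(0, nrow = dim(erp$data)[1], ncol = n_bins)
  for (b in seq_len(n_bins)) {
    lo <- span[1] + (b - 1) * bin; hi <- lo + bin
    idx <- which(erp$times >= lo - 1e-9 & erp$times < hi - 1e-9)
    out[, b] <- rowMeans(chan_mean[, idx, drop = FALSE])
  }
  colnames(out) <- sprintf("bin_%d_%d", round(1000 * (span[1] + (seq_len(n_bins) - 1) * bin)),
                           round(1000 * (span[1] + seq_len(n_bins) * bin)))
  rownames(out) <- do.call(paste, c(unname(erp$conditions), sep = "|"))
  out
}
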