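#' Build distance-based channel clusters
#'
#' For every centre electrode, the cluster contains the centre plus all
#' electrodes within `radius` cm (3-D Euclidean chord distance on the
#' montage coordinates).
#'
#' @param layout montage `data.frame` (`channel_id`, `x_cm`, `y_cm`, `z_cm`).
#' @param radius neighbourhood radius in cm (default 4).
#' @return Named list: centre channel id -> character vector of member ids
#'   (always including the centre).
#' @export
build_clusters <- function(layout, radius = 4) {
  stopifnot(radius >= 0, nrow(layout) >= 1)
  pos <- montage_positions(layout)
  D <- as.matrix(stats::dist(pos))
  out <- lapply(seq_len(nrow(layout)), function(i)
    layout$channel_id[D[i, ] <= radius + 1e-12])
  names(out) <- layout$channel_id
  out
}

#' Channel-space searchlight decoding
#'
#' Scans the montage: for every centre electrode, features are the cluster
#' member channels' mean amplitudes over a +/-100 ms window around
#' `window_centre`, and decodability is the leave-one-out linear-SVM
#' accuracy for the class pair.  Trials may be pseudo-trial averaged first
#' (default on, mirroring the main pipeline).
#'
#' @param epochs an [epoch_set()] (e.g. pooled across subjects).
#' @param layout montage `data.frame` matching the epochs' channels.
#' @param class_pair length-2 character vector of class labels.
#' @param window_centre centre of the decoding window in seconds (e.g. the
#'   time of maximal whole-scalp decodability).
#' @param radius cluster radius in cm.
#' @param half_width half-width of the window in seconds (default 0.1).
#' @param k_pseudo pseudo-trial size (1 disables averaging).
#' @param seed seed for the pseudo-trial pairing.
#' @param cost SVM regularization constant.
#' @return A `data.frame` per centre: `centre`, `n_members`, `accuracy`,
#'   `threshold` (adjusted-Wald chance bound for the outcome count).
#' @export
searchlight_decode <- function(epochs, layout, class_pair, window_centre,
                               radius = 4, half_width = 0.1, k_pseudo = 2L,
                               seed = 1L, cost = 1) {
  truth <- .class_truth(epochs, class_pair)
  keep <- which(truth %in% class_pair & !is.na(truth))
  ep <- epochs[keep]
  label_col <- "searchlight_class"
  ep$labels[[label_col]] <- .class_truth(ep, class_pair)
  if (k_pseudo > 1L)
    ep <- make_pseudo_trials(ep, k = k_pseudo, seed = seed, label_col = label_col)
  t <- epoch_times(ep)
  idx <- which(t >= window_centre - half_width - 1e-9 &
                 t < window_centre + half_width - 1e-9)
  if (!length(idx)) stop("searchlight window lies outside the epoch")
  feats <- rowMeans(ep$data[, , idx, drop = FALSE], dims = 2)  # trials x channels
  colnames(feats) <- ep$channel_ids
  y <- factor(ep$labels[[label_col]])
  clusters <- build_clusters(layout, radius)
  thr <- chance_threshold(length(y))$threshold
  out <- lapply(names(clusters), function(centre) {
    members <- intersect(clusters[[centre]], colnames(feats))
    X <- feats[, members, drop = FALSE]
    data.frame(centre = centre, n_members = length(members),
               accuracy = .loo_accuracy(X, y, cost), threshold = thr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
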