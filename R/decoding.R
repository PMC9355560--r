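#' Sliding-window specification
#'
#' Windows of `window_length` seconds on the nominal grid
#' `{0, step, 2*step, ...}` relative to the decoding time origin.
#'
#' @param window_length window length in seconds (default 100 ms).
#' @param step grid step in seconds (default 10 ms).
#' @return A `sliding_window_spec` object.
#' @export
sliding_window_spec <- function(window_length = 0.100, step = 0.010) {
  stopifnot(window_length > 0, step > 0)
  structure(list(window_length = window_length, step = step),
            class = "sliding_window_spec")
}

#' Enumerate sliding windows as sample-index ranges
#'
#' Maps the nominal-time window grid onto sample indices: each window covers
#' `round(window_length * rate)` samples starting at the nearest sample to
#' its nominal start; windows whose start rounds to an already-used sample
#' are dropped (relevant when `step * rate` is non-integer, e.g. a 10 ms
#' step at 250 Hz is 2.5 samples).
#'
#' @param spec a [sliding_window_spec()].
#' @param sampling_rate sampling rate in Hz.
#' @param epoch_length epoch span in seconds.
#' @return A `data.frame` with columns `time_s` (nominal start), `start`,
#'   `end` (1-based inclusive sample indices).
#' @export
enumerate_windows <- function(spec, sampling_rate, epoch_length) {
  win_samp <- round(spec$window_length * sampling_rate)
  n_samp <- round(epoch_length * sampling_rate)
  if (win_samp > n_samp) stop("window longer than the epoch")
  last_start <- epoch_length - spec$window_length
  starts_s <- seq(0, last_start + 1e-9, by = spec$step)
  start_idx <- round(starts_s * sampling_rate)
  keep <- !duplicated(start_idx) & (start_idx + win_samp) <= n_samp
  data.frame(time_s = starts_s[keep], start = start_idx[keep] + 1L,
             end = start_idx[keep] + win_samp)
}

#' Average trials into pseudo-trials
#'
#' Within each class, trials are randomly partitioned into disjoint groups
#' of `k` and averaged (leftover trials are dropped), raising the
#' signal-to-noise ratio for classifier training.
#'
#' @param epochs an [epoch_set()]; the class of each trial is taken from
#'   `label_col`.
#' @param k trials per pseudo-trial (default 2; `k = 1` is the identity).
#' @param seed integer seed for the random pairing.
#' @param label_col label column holding the class.
#' @return An `epoch_set` of `sum(floor(n_class / k))` pseudo-trials whose
#'   labels keep the class column plus `n_averaged`.
#' @export
make_pseudo_trials <- function(epochs, k = 2L, seed = 1L,
                               label_col = "category") {
  stopifnot(k >= 1)
  y <- epochs$labels[[label_col]]
  if (is.null(y)) stop("no label column '", label_col, "'")
  if (k == 1L) return(epochs)
  counts <- table(y)
  short <- names(counts)[counts < k]
  if (length(short))
    stop("insufficient trials for pseudo-trial averaging in class: ",
         paste(short, collapse = ", "))
  with_seed(seed, {
    groups <- list(); classes <- character(0)
    for (cl in names(counts)) {
      idx <- sample(which(y == cl))
      n_groups <- floor(length(idx) / k)
      for (gi in seq_len(n_groups)) {
        groups[[length(groups) + 1L]] <- idx[((gi - 1) * k + 1):(gi * k)]
        classes <- c(classes, cl)
      }
    }
    d <- dim(epochs$data)
    out <- array(0, c(length(groups), d[2], d[3]))
    for (i in seq_along(groups))
      out[i, , ] <- colMeans(epochs$data[groups[[i]], , , drop = FALSE], dims = 1)
    labels <- data.frame(cl = classes, n_averaged = k, stringsAsFactors = FALSE)
    names(labels)[1] <- label_col
    epoch_set(out, epochs$sampling_rate, epochs$t0, epochs$channel_ids, labels)
  })
}

# features for one window: trials x channels matrix of window-mean amplitude
.window_features <- function(data, start, end) {
  n <- end - start + 1L
  if (n == 1L) return(data[, , start])
  rowMeans(data[, , start:end, drop = FALSE], dims = 2)
}

.fit_linear_svm <- function(X, y, cost = 1) {
  e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE, type = "C-classification")
}

# leave-one-out accuracy with a linear SVM refit on every split
.loo_accuracy <- function(X, y, cost = 1) {
  n <- length(y)
  correct <- logical(n)
  for (i in seq_len(n)) {
    fit <- .fit_linear_svm(X[-i, , drop = FALSE], y[-i], cost)
    correct[i] <- as.character(stats::predict(fit, X[i, , drop = FALSE])) ==
      as.character(y[i])
  }
  mean(correct)
}

#' Train a two-class sliding-window decoder
#'
#' For every window, features are the per-channel mean amplitudes over the
#' window; generalization is estimated by leave-one-out cross-validation of
#' a linear SVM (cost `cost`, no feature scaling).  The decoder is refit on
#' all pseudo-trials at the window with the highest leave-one-out accuracy
#' (ties broken towards the earliest window).
#'
#' @param pseudo an [epoch_set()] of pseudo-trials with exactly two classes
#'   in `label_col`.
#' @param spec a [sliding_window_spec()].
#' @param cost SVM regularization constant.
#' @param label_col label column holding the class.
#' @param decode_from time (s) taken as the decoding origin; windows start on
#'   the nominal grid from this time (default 0, the locking event).
#' @return A `trained_decoder`: `class_pair`, `weights`, `bias`,
#'   `positive_class` (predicted when the decision score is positive),
#'   `selected_window` (nominal start, s), `loo_accuracy`, `n_pseudo`, and
#'   the full `accuracy_curve` (window time vs LOO accuracy).
#' @export
train_decoder <- function(pseudo, spec = sliding_window_spec(), cost = 1,
                          label_col = "category", decode_from = 0) {
  y <- factor(pseudo$labels[[label_col]])
  if (nlevels(y) != 2L) stop("need exactly two classes, got ", nlevels(y))
  if (min(table(y)) < 2L) stop("need at least 2 pseudo-trials per class")
  work <- if (abs(pseudo$t0 - decode_from) > 1e-9)
    crop_epochs(pseudo, decode_from, pseudo$t0 + dim(pseudo$data)[3] / pseudo$sampling_rate)
  else pseudo
  span <- dim(work$data)[3] / work$sampling_rate
  win <- enumerate_windows(spec, work$sampling_rate, span)
  if (stats::var(as.vector(work$data)) == 0)
    stop("degenerate (constant) features; cannot train")
  acc <- numeric(nrow(win))
  for (w in seq_len(nrow(win))) {
    X <- .window_features(work$data, win$start[w], win$end[w])
    acc[w] <- .loo_accuracy(X, y, cost)
  }
  best <- which.max(acc)  # which.max returns the earliest maximum
  Xb <- .window_features(work$data, win$start[best], win$end[best])
  fit <- .fit_linear_svm(Xb, y, cost)
  w_vec <- drop(t(fit$coefs) %*% fit$SV)
  bias <- -fit$rho
  # orient the sign convention empirically against predict()
  scores <- drop(Xb %*% w_vec) + bias
  pred <- as.character(stats::predict(fit, Xb))
  pos_by_sign <- names(which.max(table(pred[scores > 0])))
  if (length(pos_by_sign) == 0) pos_by_sign <- levels(y)[1]
  structure(list(class_pair = levels(y), weights = w_vec, bias = bias,
                 positive_class = pos_by_sign,
                 selected_window = win$time_s[best],
                 loo_accuracy = acc[best], n_pseudo = length(y),
                 cost = cost, spec = spec,
                 accuracy_curve = data.frame(time_s = win$time_s,
                                             loo_accuracy = acc)),
            class = "trained_decoder")
}

#' @export
print.trained_decoder <- function(x, ...) {
  cat(sprintf("trained_decoder %s vs %s: LOO accuracy %.3f at %g s (n = %d pseudo-trials)\n",
              x$class_pair[1], x$class_pair[2], x$loo_accuracy,
              x$selected_window, x$n_pseudo))
  invisible(x)
}

#' Adjusted-Wald chance threshold for two-class accuracy
#'
#' Upper bound of the adjusted Wald (Agresti-Coull: add two successes and
#' two failures) binomial interval around chance (0.5):
#' `0.5 + z * sqrt(0.25 / (n + 4))`.  With `n = 48` this is 63.59% and with
#' `n = 90` it is 60.11%.
#'
#' @param n number of classification outcomes.
#' @param z standard-normal quantile (default 1.96, i.e. 95%).
#' @return A `chance_threshold` object with fields `n`, `z`, `threshold`.
#' @export
chance_threshold <- function(n, z = 1.96) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  structure(list(n = n, z = z, threshold = 0.5 + z * sqrt(0.25 / (n + 4))),
            class = "chance_threshold")
}

#' @export
print.chance_threshold <- function(x, ...) {
  cat(sprintf("chance threshold: %.2f%% (n = %g, z = %g)\n",
              100 * x$threshold, x$n, x$z))
  invisible(x)
}

#' Partition decoders by the above-chance criterion
#'
#' A decoder (subject) is kept iff its leave-one-out accuracy is strictly
#' greater than the adjusted-Wald threshold for its pseudo-trial count;
#' equality counts as not above chance.
#'
#' @param decoders list of `trained_decoder` objects.
#' @param z normal quantile for the threshold.
#' @return A list with `kept`, `excluded` (index vectors) and a per-decoder
#'   `report` data.frame.
#' @export
exclude_below_chance <- function(decoders, z = 1.96) {
  if (length(decoders) == 0)
    return(list(kept = integer(0), excluded = integer(0),
                report = data.frame(index = integer(0), loo_accuracy = numeric(0),
                                    n_pseudo = integer(0), threshold = numeric(0),
                                    kept = logical(0))))
  rep_df <- do.call(rbind, lapply(seq_along(decoders), function(i) {
    d <- decoders[[i]]
    thr <- chance_threshold(d$n_pseudo, z)$threshold
    data.frame(index = i, loo_accuracy = d$loo_accuracy,
               n_pseudo = d$n_pseudo, threshold = thr,
               kept = d$loo_accuracy > thr)
  }))
  list(kept = rep_df$index[rep_df$kept], excluded = rep_df$index[!rep_df$kept],
       report = rep_df)
}

# truth labels for a class pair: the label column in which both classes of
# the pair occur (category for DMS, outcome_cat / response_cat for the RL
# task); trials with other values are the caller's to filter
.class_truth <- function(epochs, class_pair) {
  candidates <- unique(c("category", "outcome_cat", "response_cat",
                         names(epochs$labels)))
  for (col in candidates) {
    v <- epochs$labels[[col]]
    if (!is.null(v) && (is.character(v) || is.factor(v)) &&
        all(class_pair %in% v))
      return(as.character(v))
  }
  stop("no label column matches class pair ", paste(class_pair, collapse = "/"))
}

#' Apply a trained decoder across tasks, per block
#'
#' Classifies every test trial at every sliding window and scores, for each
#' block, the fraction of correct classifications per window; the block's
#' representation-strength statistic is the maximum accuracy over windows.
#' Intended use: a decoder trained on DMS delay epochs applied to learning
#' task epochs restricted to blocks without devaluation.
#'
#' @param decoder a `trained_decoder`.
#' @param rl_epochs an [epoch_set()] of test epochs with `block` labels and a
#'   label column matching the decoder's class pair.
#' @param spec sliding-window spec for the test pass (defaults to the
#'   decoder's training spec).
#' @param restrict_nodev if `TRUE` (default), only `block_type == "NoDev"`
#'   trials are scored.
#' @param decode_from decoding time origin in seconds (see [train_decoder()]).
#' @return A `data.frame` with columns `block`, `n_trials`, `accuracy`
#'   (maximum over windows), `best_window_s`, in session block order.
#' @export
decode_cross_task <- function(decoder, rl_epochs, spec = NULL,
                              restrict_nodev = TRUE, decode_from = 0) {
  spec <- spec %||% decoder$spec
  ep <- rl_epochs
  if (restrict_nodev && !is.null(ep$labels$block_type)) {
    sel <- which(ep$labels$block_type == "NoDev")
    ep <- ep[sel]
  }
  if (abs(ep$t0 - decode_from) > 1e-9)
    ep <- crop_epochs(ep, decode_from, ep$t0 + dim(ep$data)[3] / ep$sampling_rate)
  span <- dim(ep$data)[3] / ep$sampling_rate
  win <- enumerate_windows(spec, ep$sampling_rate, span)
  truth <- .class_truth(ep, decoder$class_pair)
  blocks <- sort(unique(ep$labels$block))
  neg_class <- setdiff(decoder$class_pair, decoder$positive_class)
  correct <- matrix(NA, nrow = dim(ep$data)[1], ncol = nrow(win))
  for (w in seq_len(nrow(win))) {
    X <- .window_features(ep$data, win$start[w], win$end[w])
    scores <- drop(X %*% decoder$weights) + decoder$bias
    pred <- ifelse(scores > 0, decoder$positive_class, neg_class)
    correct[, w] <- pred == truth
  }
  out <- lapply(blocks, function(b) {
    rows <- which(ep$labels$block == b)
    if (!length(rows)) {
      warning("block ", b, " has no trials; skipped")
      return(NULL)
    }
    acc_w <- colMeans(correct[rows, , drop = FALSE])
    best <- which.max(acc_w)
    data.frame(block = b, n_trials = length(rows), accuracy = acc_w[best],
               best_window_s = win$time_s[best])
  })
  do.call(rbind, out)
}

#' Aggregate per-block accuracies into superblocks
#'
#' Averages consecutive disjoint groups of `group_size` blocks.  When
#' `group_size` divides the number of blocks, all blocks are used; otherwise
#' the first 24 blocks (in session order) are grouped, matching the grouping
#' of 27 learning-phase blocks into four six-block superblocks of 144
#' learning trials each.
#'
#' @param accuracy numeric per-block accuracies in session block order.
#' @param group_size blocks per superblock (2, 3, 6, or 12).
#' @return A `data.frame` with columns `block`, `accuracy`, `superblock`,
#'   `superblock_mean`; attribute `superblock_means` holds the means.
#' @export
aggregate_blocks <- function(accuracy, group_size = 6L) {
  m <- length(accuracy)
  use <- if (m %% group_size == 0) m else 24L
  if (use > m || use %% group_size != 0)
    stop_config("group size ", group_size, " does not divide ", m,
                " blocks (nor the first 24)")
  grouped <- accuracy[seq_len(use)]
  sb <- rep(seq_len(use / group_size), each = group_size)
  means <- tapply(grouped, sb, mean)
  out <- data.frame(block = seq_len(m), accuracy = accuracy,
                    superblock = c(sb, rep(NA_integer_, m - use)),
                    superblock_mean = c(means[sb], rep(NA_real_, m - use)))
  attr(out, "superblock_means") <- as.numeric(means)
  attr(out, "group_size") <- group_size
  out
}
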