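test_that("window enumeration maps the nominal grid onto samples", {
  spec <- sliding_window_spec(0.100, 0.010)
  # 2 s epoch, 100 ms window, 10 ms step: (2000 - 100)/10 + 1 windows
  win <- enumerate_windows(spec, 1000, 2)
  expect_equal(nrow(win), 191L)
  expect_true(all(win$end - win$start + 1 == 100L))
  # window equal to the epoch yields a single window
  expect_equal(nrow(enumerate_windows(sliding_window_spec(2, 0.01), 1000, 2)), 1L)
  # at 250 Hz the 10 ms step is 2.5 samples: starts alternate 2/3-sample
  # hops and stay strictly increasing after deduplication
  w250 <- enumerate_windows(spec, 250, 2)
  hops <- diff(w250$start)
  expect_true(all(hops %in% c(2L, 3L)))
  expect_true(all(hops > 0))
  expect_true(all(w250$end - w250$start + 1 == 25L))
  expect_error(enumerate_windows(sliding_window_spec(3, 0.01), 250, 2), "longer")
})

test_that("pseudo-trial averaging partitions classes into disjoint pairs", {
  set.seed(2)
  cls <- rep(c("a", "b"), each = 48)
  ep <- epoch_set(array(rnorm(96 * 2 * 10), c(96, 2, 10)), 100,
                  labels = data.frame(category = cls, stringsAsFactors = FALSE))
  ps <- make_pseudo_trials(ep, k = 2, seed = 9)
  expect_equal(dim(ps$data)[1], 48L)
  expect_equal(as.vector(table(ps$labels$category)), c(24L, 24L))
  # grand mean is preserved within each class (disjoint exhaustive pairs)
  for (cl in c("a", "b")) {
    expect_equal(apply(ps$data[ps$labels$category == cl, , , drop = FALSE], 2:3, mean),
                 apply(ep$data[cls == cl, , , drop = FALSE], 2:3, mean))
  }
  # k = 1 is the identity
  expect_identical(make_pseudo_trials(ep, k = 1), ep)
  # averaging two identical trials reproduces the trial
  twin <- epoch_set(array(rep(ep$data[1, , ], each = 2), c(2, 2, 10)), 100,
                    labels = data.frame(category = c("a", "a")))
  pt <- make_pseudo_trials(twin, k = 2, seed = 1)
  expect_equal(pt$data[1, , ], ep$data[1, , ])
  # class with too few trials errors, naming the class
  small <- epoch_set(array(0, c(3, 2, 10)), 100,
                     labels = data.frame(category = c("a", "a", "b")))
  expect_error(make_pseudo_trials(small, k = 2, seed = 1), "\\bb\\b")
})

test_that("adjusted-Wald chance thresholds reproduce the printed values", {
  expect_equal(round(100 * chance_threshold(48)$threshold, 2), 63.59)
  expect_equal(round(100 * chance_threshold(90)$threshold, 2), 60.11)
  expect_equal(chance_threshold(1e9)$threshold, 0.5, tolerance = 1e-4)
  ns <- c(5, 10, 50, 100, 500)
  expect_true(all(diff(vapply(ns, function(n) chance_threshold(n)$threshold, 0)) < 0))
  expect_error(chance_threshold(0), ">= 1")
})

test_that("the exclusion rule keeps strictly-above-threshold decoders only", {
  mk <- function(acc, n) structure(list(loo_accuracy = acc, n_pseudo = n),
                                   class = "trained_decoder")
  thr48 <- chance_threshold(48)$threshold
  part <- exclude_below_chance(list(mk(0.70, 48), mk(thr48, 48), mk(0.50, 48)))
  expect_equal(part$kept, 1L)
  expect_equal(part$excluded, c(2L, 3L))
  empty <- exclude_below_chance(list())
  expect_equal(length(empty$kept), 0L)
  expect_equal(nrow(empty$report), 0L)
})

test_that("well-separated classes are decoded perfectly at the signal window", {
  ep <- two_class_epochs(n_per_class = 8, sep = 5, noise = 0.2,
                         signal_idx = 6:15, seed = 3)
  spec <- sliding_window_spec(0.1, 0.05)
  dec <- train_decoder(ep, spec)
  expect_equal(dec$loo_accuracy, 1.0)
  # signal occupies samples 6-15 (50-150 ms); best window within a step
  expect_true(dec$selected_window >= 0.0 && dec$selected_window <= 0.15)
  expect_equal(dec$n_pseudo, 16L)
  # degenerate all-constant data cannot be trained on
  flat <- epoch_set(array(1, c(8, 2, 20)), 100,
                    labels = data.frame(category = rep(c("a", "b"), 4)))
  expect_error(train_decoder(flat, spec), "degenerate")
})

test_that("leave-one-out matches an independent exhaustive-refit oracle", {
  spec <- sliding_window_spec(0.1, 0.1)
  for (seed in 1:6) {
    ep <- two_class_epochs(n_per_class = 4, n_channels = 2, sep = 1.2,
                           noise = 1, signal_idx = 3:12, seed = seed)
    dec <- train_decoder(ep, spec)
    win <- enumerate_windows(spec, 100, 0.2)
    for (w in seq_len(nrow(win))) {
      X <- rowMeans(ep$data[, , win$start[w]:win$end[w], drop = FALSE], dims = 2)
      expect_equal(dec$accuracy_curve$loo_accuracy[w],
                   loo_oracle_kernlab(X, ep$labels$category),
                   info = sprintf("seed %d window %d", seed, w))
    }
  }
})

test_that("cross-task decoding recovers training-level accuracy on matched data", {
  spec <- sliding_window_spec(0.1, 0.05)
  train <- two_class_epochs(n_per_class = 12, sep = 3, noise = 0.5, seed = 10)
  dec <- train_decoder(train, spec)
  test <- two_class_epochs(n_per_class = 12, sep = 3, noise = 0.5, seed = 11)
  test$labels$block <- rep(1L, 24)
  test$labels$block_type <- "NoDev"
  out <- decode_cross_task(dec, test, spec)
  expect_equal(nrow(out), 1L)
  expect_lt(abs(out$accuracy - dec$loo_accuracy), 0.1 + 1e-9)
})

test_that("swapping test labels complements per-window accuracy exactly", {
  spec <- sliding_window_spec(0.1, 0.1)
  train <- two_class_epochs(n_per_class = 8, sep = 3, noise = 0.5, seed = 20)
  dec <- train_decoder(train, spec)
  test <- two_class_epochs(n_per_class = 8, sep = 3, noise = 0.5, seed = 21)
  win <- enumerate_windows(spec, 100, 0.2)
  X <- rowMeans(test$data[, , win$start[1]:win$end[1], drop = FALSE], dims = 2)
  sc <- drop(X %*% dec$weights) + dec$bias
  neg <- setdiff(dec$class_pair, dec$positive_class)
  pred <- ifelse(sc > 0, dec$positive_class, neg)
  acc <- mean(pred == test$labels$category)
  swapped <- ifelse(test$labels$category == "a", "b", "a")
  expect_equal(mean(pred == swapped), 1 - acc)
})

test_that("zero-amplitude test epochs stay within the chance band", {
  spec <- sliding_window_spec(0.1, 0.1)
  train <- two_class_epochs(n_per_class = 12, sep = 3, noise = 0.5, seed = 30)
  dec <- train_decoder(train, spec)
  noise_only <- two_class_epochs(n_per_class = 24, sep = 0, noise = 0.5, seed = 31)
  noise_only$labels$block <- rep(1:2, 24)
  noise_only$labels$block_type <- "NoDev"
  out <- decode_cross_task(dec, noise_only, spec)
  thr <- chance_threshold(24)$threshold  # 24 trials per block
  expect_true(all(out$accuracy <= thr))
})

test_that("block aggregation averages disjoint consecutive groups", {
  expect_equal(attr(aggregate_blocks(rep(0.7, 24), 6), "superblock_means"),
               rep(0.7, 4))
  dec_series <- seq(0.9, by = -0.01, length.out = 24)
  m <- attr(aggregate_blocks(dec_series, 6), "superblock_means")
  expect_equal(length(m), 4L)
  expect_true(all(diff(m) < 0))
  expect_equal(m[1], mean(dec_series[1:6]))
  # 27 blocks: group size 3 divides evenly (9 superblocks); 6 uses first 24
  expect_equal(length(attr(aggregate_blocks(rep(0.5, 27), 3), "superblock_means")), 9L)
  agg27 <- aggregate_blocks(seq(0, 1, length.out = 27), 6)
  expect_equal(length(attr(agg27, "superblock_means")), 4L)
  expect_true(all(is.na(agg27$superblock[25:27])))
  expect_equal(length(attr(aggregate_blocks(rep(0.5, 24), 12), "superblock_means")), 2L)
  expect_error(aggregate_blocks(rep(0.5, 27), 5), "group size")
})
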