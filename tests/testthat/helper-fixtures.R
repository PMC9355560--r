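# Small in-code fixtures shared across test files.

# tiny epoch set with known content: `values` is trials x channels x samples
tiny_epochs <- function(values, rate = 100, t0 = 0, labels = NULL) {
  epoch_set(values, sampling_rate = rate, t0 = t0, labels = labels)
}

# two-class Gaussian epochs: class patterns +/- `sep` on channel 1, a signal
# bump in samples `signal_idx`, white noise elsewhere
two_class_epochs <- function(n_per_class = 8, n_channels = 2, n_samples = 20,
                             sep = 3, noise = 0.5, rate = 100,
                             signal_idx = 6:10, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  data <- array(rnorm(n * n_channels * n_samples, sd = noise),
                c(n, n_channels, n_samples))
  cls <- rep(c("a", "b"), each = n_per_class)
  for (i in seq_len(n)) {
    s <- if (cls[i] == "a") sep else -sep
    data[i, 1, signal_idx] <- data[i, 1, signal_idx] + s
  }
  epoch_set(data, rate, 0, labels = data.frame(category = cls,
                                               stringsAsFactors = FALSE))
}

# independent leave-one-out oracle: refits a kernlab linear SVM on every
# split (a different SVM implementation than the package uses)
loo_oracle_kernlab <- function(X, y, cost = 1) {
  n <- length(y)
  correct <- logical(n)
  for (i in seq_len(n)) {
    fit <- kernlab::ksvm(X[-i, , drop = FALSE], factor(y[-i]),
                         kernel = "vanilladot", C = cost, scaled = FALSE,
                         kpar = list())
    correct[i] <- as.character(kernlab::predict(fit, X[i, , drop = FALSE])) ==
      as.character(y[i])
  }
  mean(correct)
}

# settings for fast no-signal decoding runs (type-I / chance-band checks)
null_settings <- function() {
  list(n_channels = 8L, sampling_rate = 50, epoch_length = 1,
       spec = sliding_window_spec(0.100, 0.100))
}

# generate a no-signal DMS-like subject and train one decoder on it
train_null_decoder <- function(seed) {
  st <- null_settings()
  model <- signal_model(n_channels = st$n_channels,
                        sampling_rate = st$sampling_rate,
                        epoch_length = st$epoch_length,
                        montage = spherical_montage(st$n_channels),
                        amplitude_schedule = constant_schedule(0),
                        dms_amplitude = 0, p1_amplitude = 0, late_amplitude = 0)
  dms <- generate_dms_session(seed, counts = c(object = 16L, scene = 16L,
                                               blue_symbol = 4L, red_symbol = 4L))
  ep <- generate_epochs(dms, model, "dms_delay", seed + 1000L)
  ps <- make_pseudo_trials(ep[ep$labels$category %in% c("object", "scene")],
                           k = 2, seed = seed + 2000L)
  train_decoder(ps, st$spec)
}
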