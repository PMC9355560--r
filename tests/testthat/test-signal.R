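test_that("category patterns are unit-norm and sited in the expected regions", {
  model <- signal_model(n_channels = 64, montage = spherical_montage(64))
  pat <- model$category_patterns
  expect_equal(unname(sqrt(colSums(pat^2))), rep(1, 4))
  mon <- model$montage
  # outcome maps load parieto-occipital sites, response maps centroparietal:
  # each pattern's squared loading near POz exceeds that near CPz or
  # vice versa
  load_near <- function(p, ref, radius = 5) {
    centre <- as.numeric(mon[mon$channel_id == ref, c("x_cm", "y_cm", "z_cm")])
    d <- sqrt(rowSums(sweep(as.matrix(mon[, c("x_cm", "y_cm", "z_cm")]),
                            2, centre)^2))
    sum(p[d <= radius]^2)
  }
  expect_gt(load_near(pat[, "object"], "POz"), load_near(pat[, "object"], "CPz"))
  expect_gt(load_near(pat[, "scene"], "POz"), load_near(pat[, "scene"], "CPz"))
  expect_gt(load_near(pat[, "blue_symbol"], "CPz"),
            load_near(pat[, "blue_symbol"], "POz"))
  # left/right lateralization within each pair keeps the two maps distinct
  expect_gt(sum((pat[, "object"] - pat[, "scene"])^2), 0.1)
})

test_that("epoch generation is deterministic and label-faithful", {
  model <- signal_model(n_channels = 8, sampling_rate = 50, epoch_length = 1,
                        montage = spherical_montage(8))
  dms <- generate_dms_session(1, counts = c(object = 6L, scene = 6L,
                                            blue_symbol = 2L, red_symbol = 2L))
  e1 <- generate_epochs(dms, model, "dms_delay", 42)
  e2 <- generate_epochs(dms, model, "dms_delay", 42)
  expect_identical(e1$data, e2$data)
  expect_false(identical(e1$data, generate_epochs(dms, model, "dms_delay", 43)$data))
  expect_equal(e1$labels$category, dms$category)
  expect_equal(dim(e1$data), c(16L, 8L, 50L))
  bad <- dms; bad$category[1] <- "house"
  expect_error(generate_epochs(bad, model, "dms_delay", 1), "unknown category")
})

test_that("noise-free epochs of one category are identical; amplitude zero is pure noise", {
  model <- signal_model(n_channels = 8, sampling_rate = 50, epoch_length = 1,
                        montage = spherical_montage(8), noise_scale = 0,
                        dms_amplitude = 0.5)
  dms <- data.frame(session = 1L, trial = 1:4,
                    category = c("object", "object", "scene", "scene"))
  ep <- generate_epochs(dms, model, "dms_delay", 1)
  expect_equal(ep$data[1, , ], ep$data[2, , ])
  expect_false(isTRUE(all.equal(ep$data[1, , ], ep$data[3, , ])))
  # amplitude 0, noise 0: nothing at all
  m0 <- signal_model(n_channels = 8, sampling_rate = 50, epoch_length = 1,
                     montage = spherical_montage(8), noise_scale = 0,
                     dms_amplitude = 0)
  expect_true(all(generate_epochs(dms, m0, "dms_delay", 1)$data == 0))
})

test_that("learning-task epochs carry block-scheduled amplitudes", {
  cfg <- task_config(n_blocks = 4, dev_high_blocks = 2, dev_low_blocks = 3)
  ag <- agent_params(habit_weight_schedule = rep(0, 4), timeout_prob = 0)
  tr <- generate_task_session(cfg, ag, 5)
  sched <- function(representation, block) if (block == 1) 2 else 0
  model <- signal_model(n_channels = 8, sampling_rate = 50, epoch_length = 1,
                        montage = spherical_montage(8), noise_scale = 0,
                        amplitude_schedule = sched,
                        p1_amplitude = 0, late_amplitude = 0)
  ep <- generate_epochs(tr, model, "rl_stimulus", 1)
  expect_equal(ep$t0, -0.2)
  b1 <- which(ep$labels$block == 1)
  b4 <- which(ep$labels$block == 4)
  expect_gt(max(abs(ep$data[b1, , ])), 0)
  expect_true(all(ep$data[b4, , ] == 0))
  # choice-locked epochs exist only for responded trials and start at 0
  ch <- generate_epochs(tr, model, "rl_choice", 1)
  expect_equal(ch$t0, 0)
  expect_equal(dim(ch$data)[1],
               sum(tr$trial_type == "learning" & !is.na(tr$response)))
})

test_that("decoding accuracy is monotone in the signal-to-noise ratio", {
  spec <- sliding_window_spec(0.2, 0.2)
  accs <- vapply(c(0.1, 0.6, 2), function(amp) {
    model <- signal_model(n_channels = 8, sampling_rate = 50, epoch_length = 1,
                          montage = spherical_montage(8), dms_amplitude = amp,
                          amplitude_schedule = constant_schedule(0))
    dms <- generate_dms_session(4, counts = c(object = 20L, scene = 20L,
                                              blue_symbol = 2L, red_symbol = 2L))
    ep <- generate_epochs(dms, model, "dms_delay", 9)
    ps <- make_pseudo_trials(ep[ep$labels$category %in% c("object", "scene")],
                             2, seed = 13)
    train_decoder(ps, spec)$loo_accuracy
  }, 0)
  expect_true(all(diff(accs) >= 0))
  expect_gt(accs[3], 0.9)
})
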