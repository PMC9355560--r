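test_that("session structure follows the configured schedule", {
  tr <- generate_task_session(seed = 11)
  expect_equal(nrow(tr), 33 * 27)
  expect_equal(sum(tr$trial_type == "consumption"), 33 * 3)
  # consumption trials sit at the configured within-block positions
  cons_idx <- sort(unique(tr$trial_index[tr$trial_type == "consumption"]))
  expect_equal(cons_idx, c(7L, 14L, 21L))
  # 12 learning trials per stimulus per block
  b1 <- tr[tr$block == 1 & tr$trial_type == "learning", ]
  expect_equal(as.vector(table(b1$stimulus)), c(12L, 12L))
  # devaluation blocks and feedback masking
  expect_equal(unique(tr$block[tr$block_type == "DevOhigh"]), c(2L, 16L, 29L))
  expect_equal(unique(tr$block[tr$block_type == "DevOlow"]), c(3L, 17L, 30L))
  expect_true(all(tr$feedback_masked[tr$block_type != "NoDev"] == 1))
  expect_true(all(tr$feedback_masked[tr$block_type == "NoDev"] == 0))
})

test_that("identical seeds give byte-identical sessions", {
  expect_identical(generate_task_session(seed = 5), generate_task_session(seed = 5))
  expect_false(identical(generate_task_session(seed = 5),
                         generate_task_session(seed = 6)))
})

test_that("a value-maximizing agent avoids devalued trades and tracks value in consumption", {
  ag <- agent_params(softmax_temperature = 1e-9, timeout_prob = 0)
  tr <- generate_task_session(agent = ag, seed = 3)
  dh <- tr[tr$block_type == "DevOhigh" & tr$trial_type == "learning" &
             tr$stimulus == "S_high", ]
  expect_equal(mean(dh$accepted), 0)  # net -5 is never chosen
  dl <- tr[tr$block_type == "DevOlow" & tr$trial_type == "learning" &
             tr$stimulus == "S_low", ]
  expect_equal(mean(dl$accepted), 0)
  # consumption: always the currently valued card, in every block type
  cons <- tr[tr$trial_type == "consumption", ]
  valued <- ifelse(cons$block_type == "DevOhigh", "scene", "object")
  expect_equal(mean(cons$outcome_cat == valued), 1.0)
})

test_that("the points ledger balances accepted-trade values minus response costs", {
  tr <- generate_task_session(seed = 9)
  learn <- tr[tr$trial_type == "learning" & !is.na(tr$response), ]
  dev <- (learn$block_type == "DevOhigh" & learn$outcome_cat == "object") |
    (learn$block_type == "DevOlow" & learn$outcome_cat == "scene")
  value <- ifelse(learn$outcome_cat == "object", 100,
                  ifelse(learn$outcome_cat == "scene", 20, 0))
  value[dev] <- 0
  expect_equal(sum(learn$points_delta),
               sum(value[learn$accepted == 1]) - 5 * sum(learn$accepted))
  # rejected trades cost nothing
  expect_true(all(learn$points_delta[learn$accepted == 0] == 0))
})

test_that("rising habit weight produces training-dependent devaluation insensitivity", {
  dev_prop <- function(g, block, seeds) {
    vapply(seeds, function(s) {
      ag <- agent_params(habit_weight_schedule = habit_weight_schedule(33, g))
      tr <- generate_task_session(agent = ag, seed = s)
      d <- tr[tr$block == block & tr$trial_type == "learning" &
                tr$stimulus == "S_high" & !is.na(tr$response), ]
      mean(d$accepted)
    }, 0)
  }
  early_stress <- mean(dev_prop(1, 2, 1:60))
  late_stress <- mean(dev_prop(1, 29, 1:60))
  late_control <- mean(dev_prop(0.15, 29, 61:120))
  expect_gt(late_stress, early_stress)   # insensitivity grows with training
  expect_gt(late_stress, late_control)   # and is specific to the habit profile
})

test_that("invalid configurations are rejected", {
  expect_error(task_config(dev_high_blocks = c(2, 16), dev_low_blocks = c(2, 17)),
               "disjoint")
  expect_error(task_config(dev_high_blocks = c(2, 16, 40)), "1..n_blocks")
  expect_error(task_config(value_high = 10, value_low = 20), "value_high")
  expect_error(generate_task_session(agent = agent_params(
    habit_weight_schedule = rep(0, 5))), "every block")
})

test_that("DMS sessions have 128 trials and pooled sessions respect the allocation", {
  d1 <- generate_dms_session(seed = 1)
  expect_equal(nrow(d1), 128L)
  d2 <- generate_dms_session(seed = 2, session = 2)
  pooled <- pool_dms_sessions(d1, d2)
  expect_equal(nrow(pooled), 256L)
  counts <- table(pooled$category)
  expect_equal(as.integer(counts[c("object", "scene")]), c(90L, 90L))
  # pooled counts approximate the 90/90/48/48 pool proportions within slack
  expect_true(all(abs(as.integer(counts[c("object", "scene", "blue_symbol",
                                          "red_symbol")]) -
                        c(90, 90, 48, 48)) <= 10))
  # never more than three same-category trials in a row
  for (s in list(d1, d2)) expect_lte(max(rle(s$category)$lengths), 3L)
  expect_identical(generate_dms_session(seed = 1), generate_dms_session(seed = 1))
})
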