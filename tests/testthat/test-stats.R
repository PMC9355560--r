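test_that("devaluation rates follow the trial arithmetic", {
  # constructed block: 12 devalued-stimulus trials, 3 devalued responses
  mk_trial <- function(block, btype, i, ttype, stim, resp, acc, out) {
    data.frame(block = block, block_type = btype, trial_index = i,
               trial_type = ttype, stimulus = stim, response = resp,
               response_cat = NA, outcome_cat = out, accepted = acc,
               points_delta = 0, feedback_masked = 1, rt_s = 0.5,
               stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, lapply(1:12, function(i)
    mk_trial(1, "DevOhigh", i, "learning", "S_high", "R1",
             as.integer(i <= 3), if (i <= 3) "object" else "none")))
  rows <- rbind(rows, mk_trial(1, "DevOhigh", 13, "consumption", NA, NA, 0, "scene"))
  dr <- devaluation_rates(rows)
  expect_equal(dr$prop_devalued, 0.25)
  expect_equal(dr$consumption_valued_prop, 1)
  # an all-timeout devaluation cell is reported missing and flagged
  to <- rows
  to$response <- NA_character_
  to$accepted <- 0L
  dto <- devaluation_rates(to)
  expect_true(is.na(dto$prop_devalued))
  expect_true(dto$flagged)
})

test_that("spearman correlation handles monotone data, ties, and errors", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_corr(x, x^3)$estimate, 1)
  expect_equal(spearman_corr(x, -exp(x))$estimate, -1)
  # tied data equals the brute-force average-rank computation
  tx <- c(1, 1, 2, 3); ty <- c(1, 2, 3, 3)
  brute <- function(a, b) {
    ra <- rank(a); rb <- rank(b)
    sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  }
  expect_equal(spearman_corr(tx, ty)$estimate, brute(tx, ty))
  # invariance under strictly monotone transforms of either variable
  set.seed(3)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(spearman_corr(exp(a), b)$estimate, spearman_corr(a, b)$estimate)
  expect_equal(spearman_corr(a, atan(b))$estimate, spearman_corr(a, b)$estimate)
  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
  expect_error(spearman_corr(1:2, 2:1), "at least 3")
  ci <- spearman_corr(rnorm(30), rnorm(30))$ci
  expect_true(ci[1] >= -1 && ci[2] <= 1 && ci[1] < ci[2])
})

test_that("Bayes-factor correlation behaves across effect sizes", {
  set.seed(11)
  n <- 40
  x <- rnorm(n)
  # near-zero sample correlation: the null is favoured
  y0 <- rnorm(n)
  y0 <- residuals(lm(y0 ~ x))  # exactly r = 0
  b0 <- bayes_corr(x, y0)
  expect_lt(b0$bf10, 1)
  # overwhelming effect
  y1 <- x + rnorm(n, sd = 0.1)
  x30 <- x[1:30]; y30 <- x30 * 1 + rnorm(30, sd = 0.12)
  b1 <- bayes_corr(x30, y30)
  expect_gt(b1$bf10, 100)
  # BF01 is the exact reciprocal
  expect_identical(b0$bf01, 1 / b0$bf10)
  expect_error(bayes_corr(rep(1, 5), rnorm(5)), "constant")
})

test_that("the quadrature matches a fine-grid trapezoid oracle", {
  trapz_oracle <- function(r, n, kappa = 0.707, grid = 2e5) {
    rho <- seq(-1 + 1e-9, 1 - 1e-9, length.out = grid)
    a <- 1 / kappa
    prior <- exp((a - 1) * log1p(-rho^2) - (2 * a - 1) * log(2) - lbeta(a, a))
    h0 <- instrudecode:::hyp2f1_half(n - 0.5, 0.5)
    lr <- (1 - rho^2)^((n - 1) / 2) * (1 - rho * r)^(1.5 - n) *
      instrudecode:::hyp2f1_half(n - 0.5, (1 + rho * r) / 2) / h0
    f <- lr * prior
    sum((f[-1] + f[-grid]) / 2) * diff(rho[1:2])
  }
  for (case in list(c(0.4, 40), c(-0.3, 25), c(0.1, 12), c(0.75, 18), c(0, 50))) {
    bf <- bayes_corr_bf(case[1], case[2])
    expect_equal(bf, trapz_oracle(case[1], case[2]), tolerance = 1e-4,
                 info = sprintf("r=%g n=%g", case[1], case[2]))
  }
})

test_that("evidence accumulates with sample size in the expected direction", {
  # growing n at fixed r != 0 increases BF10; at r = 0 it favours the null
  bfs <- vapply(c(10, 25, 60, 150), function(n) bayes_corr_bf(0.4, n), 0)
  expect_true(all(diff(bfs) > 0))
  expect_gt(bfs[4], 100)
  bf0 <- vapply(c(10, 50, 200), function(n) bayes_corr_bf(0, n), 0)
  expect_true(all(bf0 < 1))
})

test_that("effect sizes match closed-form hand computations", {
  expect_equal(effect_sizes(1:10, 1:10, paired = TRUE)$d, 0)
  # fixed two-sample case: hand-computed pooled-SD d
  a <- c(5, 7, 6, 8, 9, 10, 4, 6, 7, 8)
  b <- c(3, 4, 5, 4, 6, 5, 3, 4, 5, 6)
  sp <- sqrt(((10 - 1) * var(a) + (10 - 1) * var(b)) / 18)
  es <- effect_sizes(a, b)
  expect_equal(es$d, (mean(a) - mean(b)) / sp)
  expect_true(es$ci[1] < es$d && es$d < es$ci[2])
  # b = a + sd(a): d approaches 1 for large samples
  set.seed(2)
  big <- rnorm(4000)
  expect_equal(effect_sizes(big + sd(big), big)$d, 1, tolerance = 0.05)
  # paired uses the SD of differences
  d1 <- c(1, 2, 3, 4); d2 <- c(0, 1, 1, 2)
  expect_equal(effect_sizes(d1, d2, paired = TRUE)$d,
               mean(d1 - d2) / sd(d1 - d2))
  expect_error(effect_sizes(c(1, 2, 3), c(2, 3, 4), paired = TRUE), "zero variance")
})

test_that("difference scores use first-minus-last orientation", {
  acc <- c(rep(0.8, 6), rep(0.75, 12), rep(0.6, 6))
  dv <- data.frame(block = c(2, 16, 29), block_type = "DevOhigh",
                   occurrence = 1:3, prop_devalued = c(0.1, 0.2, 0.5))
  ds <- delta_scores(acc, dv)
  expect_equal(ds$delta_accuracy, 0.8 - 0.6)
  expect_equal(ds$delta_devalued, 0.1 - 0.5)
})
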