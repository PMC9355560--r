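#' Behavioural devaluation summary
#'
#' Per block, over valid (responded) learning trials: choice accuracy, the
#' proportion of responses leading to the currently devalued outcome
#' (devaluation blocks only; the devalued-outcome stimulus is S_high in
#' high-value and S_low in low-value devaluation blocks), the
#' consumption-trial proportion of currently-valued choices, and mean
#' reaction time.  A devaluation-block cell with zero valid trials is
#' reported as `NA` and flagged.
#'
#' @param trials a table from [generate_task_session()] (optionally with a
#'   `subject` column; the summary is per subject if present).
#' @return A `data.frame` with one row per (subject x) block: `block`,
#'   `block_type`, `occurrence` (1st/2nd/3rd within its type),
#'   `n_valid`, `prop_devalued`, `choice_accuracy`,
#'   `consumption_valued_prop`, `mean_rt_s`, `flagged`.
#' @export
devaluation_rates <- function(trials) {
  if (!is.null(trials$subject)) {
    parts <- split(trials, trials$subject)
    out <- do.call(rbind, lapply(names(parts), function(s) {
      cbind(subject = s, devaluation_rates(parts[[s]][setdiff(names(parts[[s]]), "subject")]),
            stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    return(out)
  }
  blocks <- sort(unique(trials$block))
  rows <- lapply(blocks, function(b) {
    tb <- trials[trials$block == b, ]
    btype <- tb$block_type[1]
    learn <- tb[tb$trial_type == "learning", ]
    valid <- learn[!is.na(learn$response), ]
    cons <- tb[tb$trial_type == "consumption", ]
    dev_stim <- switch(btype, DevOhigh = "S_high", DevOlow = "S_low", NA_character_)
    prop_dev <- NA_real_; flagged <- FALSE
    if (!is.na(dev_stim)) {
      vd <- valid[valid$stimulus == dev_stim, ]
      if (nrow(vd) == 0) flagged <- TRUE
      else prop_dev <- mean(vd$accepted == 1L)  # accepted = devalued outcome obtained
    }
    valued_cat <- switch(btype, DevOhigh = "scene", DevOlow = "object", "object")
    data.frame(block = b, block_type = btype, occurrence = NA_integer_,
               n_valid = nrow(valid),
               prop_devalued = prop_dev,
               choice_accuracy = if (nrow(valid)) mean(valid$accepted == 1L) else NA_real_,
               consumption_valued_prop = if (nrow(cons))
                 mean(cons$outcome_cat == valued_cat) else NA_real_,
               mean_rt_s = mean(valid$rt_s),
               flagged = flagged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  for (bt in unique(out$block_type)) {
    sel <- out$block_type == bt
    out$occurrence[sel] <- seq_len(sum(sel))
  }
  out
}

#' First-minus-last difference scores
#'
#' Decoding delta: mean per-block accuracy over the first six learning-phase
#' blocks minus the mean over the last six (of the 24 grouped blocks).
#' Behavioural delta: devalued responding in the first high-value
#' devaluation block minus the last one.  Higher scores mean larger
#' decreases over training.
#'
#' @param per_block_accuracy numeric per-block accuracies in session order.
#' @param devaluation a per-block summary from [devaluation_rates()].
#' @return List with `delta_accuracy` and `delta_devalued`.
#' @export
delta_scores <- function(per_block_accuracy = NULL, devaluation = NULL) {
  out <- list(delta_accuracy = NA_real_, delta_devalued = NA_real_)
  if (!is.null(per_block_accuracy)) {
    m <- min(length(per_block_accuracy), 24L)
    k <- min(6L, m %/% 2L)  # first/last six blocks when available
    a <- per_block_accuracy
    out$delta_accuracy <- mean(a[seq_len(k)]) - mean(a[(m - k + 1):m])
  }
  if (!is.null(devaluation)) {
    dv <- devaluation[devaluation$block_type == "DevOhigh", ]
    dv <- dv[order(dv$occurrence), ]
    if (nrow(dv) >= 2)
      out$delta_devalued <- dv$prop_devalued[1] - dv$prop_devalued[nrow(dv)]
  }
  out
}

#' Spearman rank correlation with Fisher-z confidence interval
#'
#' Rank correlation (average ranks for ties) with a 95% CI from the
#' Fisher-z approximation on the rank correlation and an asymptotic p-value.
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @param conf confidence level.
#' @return A `correlation_report` with `method`, `estimate`, `n`, `ci`, `p`.
#' @export
spearman_corr <- function(x, y, conf = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  rho <- stats::cor(rank(x), rank(y))
  z <- atanh(min(max(rho, -1 + 1e-12), 1 - 1e-12))
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- tanh(c(z - q * se, z + q * se))
  p <- 2 * stats::pnorm(-abs(z) / se)
  structure(list(method = "spearman", estimate = rho, n = n, ci = ci, p = p),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("%s correlation: %.3f (n = %d, 95%% CI %.3f to %.3f)\n",
              x$method, x$estimate, x$n, x$ci[1], x$ci[2]))
  if (!is.null(x$bf10))
    cat(sprintf("  BF10 = %.4g, BF01 = %.4g (prior width %g)\n",
                x$bf10, x$bf01, x$prior_width))
  invisible(x)
}

# Gauss hypergeometric 2F1(1/2, 1/2; c; z) for 0 <= z < 1, vectorized in z.
# Plain power series; converges quickly because c ~ n/2 is large here.
hyp2f1_half <- function(c_par, z, tol = 1e-12, max_iter = 5000L) {
  out <- rep(1, length(z))
  term <- rep(1, length(z))
  for (k in 0:(max_iter - 1)) {
    term <- term * (0.5 + k)^2 / ((c_par + k) * (k + 1)) * z
    out <- out + term
    if (all(abs(term) < tol * abs(out))) return(out)
  }
  warning("hypergeometric series did not fully converge")
  out
}

# likelihood ratio p(r | rho, n) / p(r | 0, n) for the Pearson correlation
# of a bivariate normal sample (nuisance parameters integrated out)
.corr_likelihood_ratio <- function(rho, r, n) {
  h0 <- hyp2f1_half(n - 0.5, (1 + 0) / 2)
  (1 - rho^2)^((n - 1) / 2) * (1 - rho * r)^(1.5 - n) *
    hyp2f1_half(n - 0.5, (1 + rho * r) / 2) / h0
}

# symmetric stretched-beta prior density on rho in (-1, 1) with width kappa:
# rho = 2u - 1, u ~ Beta(1/kappa, 1/kappa)
.stretched_beta_density <- function(rho, kappa) {
  a <- 1 / kappa
  exp((a - 1) * log1p(-rho^2) - (2 * a - 1) * log(2) - lbeta(a, a))
}

#' Bayes-factor test for a Pearson correlation
#'
#' BF10 for the presence of a linear correlation, computed by numerical
#' integration of the sampling distribution of the observed correlation
#' coefficient over a symmetric stretched-beta prior on the population
#' correlation (the default prior family of standard Bayesian correlation
#' software, width 0.707 by default).  BF01 is the exact reciprocal.
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @param prior_width prior scale kappa in (0, 2].
#' @param rel_tol quadrature relative tolerance.
#' @return A `correlation_report` with fields `estimate` (Pearson r), `n`,
#'   `ci` (Fisher-z 95% CI), `bf10`, `bf01`, `prior_width`.
#' @export
bayes_corr <- function(x, y, prior_width = 0.707, rel_tol = 1e-8) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  r <- stats::cor(x, y)
  bf10 <- bayes_corr_bf(r, n, prior_width, rel_tol)
  z <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12)); se <- 1 / sqrt(n - 3)
  structure(list(method = "pearson_bayes", estimate = r, n = n,
                 ci = tanh(c(z - 1.96 * se, z + 1.96 * se)),
                 bf10 = bf10, bf01 = 1 / bf10, prior_width = prior_width),
            class = "correlation_report")
}

#' Bayes factor from a correlation coefficient and sample size
#'
#' The quadrature core of [bayes_corr()], exposed for direct use on summary
#' statistics.
#'
#' @param r observed Pearson correlation.
#' @param n sample size (`>= 3`).
#' @param prior_width stretched-beta prior scale.
#' @param rel_tol quadrature relative tolerance.
#' @return BF10 as a scalar.
#' @export
bayes_corr_bf <- function(r, n, prior_width = 0.707, rel_tol = 1e-8) {
  stopifnot(n >= 3, abs(r) < 1, prior_width > 0)
  integrand <- function(rho)
    .corr_likelihood_ratio(rho, r, n) * .stretched_beta_density(rho, prior_width)
  q <- stats::integrate(integrand, -1, 1, rel.tol = rel_tol, abs.tol = 0,
                        stop.on.error = FALSE)
  if (q$message != "OK" && q$message != "the integral is probably divergent")
    stop("quadrature failed: ", q$message)
  q$value
}

#' Cohen's d with a noncentral-t confidence interval
#'
#' Standardized mean difference: pooled-SD d for independent samples, or the
#' mean of paired differences over their SD for paired samples.  The CI is
#' obtained by inverting the noncentral-t distribution of the associated
#' t statistic.
#'
#' @param a,b numeric samples (equal length if `paired`).
#' @param paired treat as paired samples?
#' @param conf confidence level.
#' @return List with `d`, `ci`, `n`, `paired`.
#' @export
effect_sizes <- function(a, b, paired = FALSE, conf = 0.95) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (paired) {
    stopifnot(length(a) == length(b))
    dif <- a - b
    s <- stats::sd(dif)
    if (s == 0) {
      if (mean(dif) == 0) return(list(d = 0, ci = c(0, 0), n = length(a), paired = TRUE))
      stop("zero variance of differences")
    }
    d <- mean(dif) / s
    n <- length(dif)
    t_obs <- d * sqrt(n); df <- n - 1; scale <- sqrt(n)
  } else {
    n1 <- length(a); n2 <- length(b)
    sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2))
    if (sp == 0) {
      if (mean(a) == mean(b)) return(list(d = 0, ci = c(0, 0), n = c(n1, n2), paired = FALSE))
      stop("zero pooled variance")
    }
    d <- (mean(a) - mean(b)) / sp
    scale <- sqrt(n1 * n2 / (n1 + n2))
    t_obs <- d * scale; df <- n1 + n2 - 2
    n <- c(n1, n2)
  }
  alpha <- 1 - conf
  q <- stats::qnorm(1 - alpha / 2)
  ci <- tryCatch(suppressWarnings(
    c(.ncp_limit(t_obs, df, 1 - alpha / 2),
      .ncp_limit(t_obs, df, alpha / 2)) / scale
  ), error = function(e) NULL)
  if (is.null(ci) || any(!is.finite(ci))) {
    # noncentral-t inversion is numerically unusable at extreme ncp; the
    # asymptotic variance of d is accurate there
    se <- if (paired) sqrt(1 / n[1] + d^2 / (2 * n[1]))
          else sqrt(sum(1 / n) + d^2 / (2 * sum(n)))
    ci <- d + c(-q, q) * se
  }
  list(d = d, ci = ci, n = n, paired = paired)
}

# ncp such that pt(t_obs, df, ncp) = p
.ncp_limit <- function(t_obs, df, p) {
  f <- function(ncp) stats::pt(t_obs, df, ncp) - p
  lo <- t_obs - 10 - 10 * abs(t_obs); hi <- t_obs + 10 + 10 * abs(t_obs)
  while (f(lo) < 0) lo <- lo - 10
  while (f(hi) > 0) hi <- hi + 10
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}
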