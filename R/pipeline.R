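#' Study-geometry settings
#'
#' Bundles the signal-model geometry, DMS allocation and sliding-window
#' spec used by [simulate_subject()] and [run_cohort()].  `"full"` is the
#' acquisition-scale geometry (128 channels, 250 Hz, 2 s epochs, 100 ms /
#' 10 ms windows, two 128-trial DMS sessions).  `"reduced"` is a smaller
#' geometry for simulation studies (32 channels, 100 Hz, 1 s epochs, 50 ms
#' window step, 80-trial DMS sessions); its base amplitude is scaled up by
#' ~sqrt(25/10) so the per-window feature signal-to-noise matches the full
#' geometry despite the shorter within-window average.
#'
#' @param scale `"full"` or `"reduced"`.
#' @return A list of settings consumed by [simulate_subject()].
#' @export
study_settings <- function(scale = c("full", "reduced")) {
  scale <- match.arg(scale)
  if (scale == "full") {
    list(scale = scale,
         n_channels = 128L, sampling_rate = 250, epoch_length = 2,
         spec = sliding_window_spec(0.100, 0.010),
         dms_counts = c(object = 45L, scene = 45L,
                        blue_symbol = 19L, red_symbol = 19L),
         dms_sessions = 2L, base_amplitude = 0.3, dms_amplitude = 0.6)
  } else {
    list(scale = scale,
         n_channels = 32L, sampling_rate = 100, epoch_length = 1,
         spec = sliding_window_spec(0.100, 0.050),
         dms_counts = c(object = 24L, scene = 24L,
                        blue_symbol = 16L, red_symbol = 16L),
         dms_sessions = 2L, base_amplitude = 0.45, dms_amplitude = 0.9)
  }
}

#' Draw a subject's latent habit susceptibility
#'
#' Truncated-normal draws encoding the group hypothesis: stressed subjects
#' centre at `g = 1` (habit schedule ramps up, outcome signal decays,
#' response signal grows), control subjects at `g = 0.15` (near-flat
#' schedules with slight opposite drift).
#'
#' @param group `"stress"` or `"control"`.
#' @param n number of draws.
#' @return Non-negative numeric vector.
#' @export
draw_habit_susceptibility <- function(group = c("stress", "control"), n = 1L) {
  group <- match.arg(group)
  mu <- if (group == "stress") 1 else 0.15
  sd <- if (group == "stress") 0.3 else 0.15
  pmax(stats::rnorm(n, mu, sd), 0)
}

#' Simulate one subject end to end
#'
#' Draws the subject's latent habit susceptibility, simulates the
#' behavioural session with the matching habit-weight schedule, and
#' generates DMS delay epochs (pooled sessions) plus stimulus- and
#' choice-locked learning-task epochs under the habit-coupled amplitude
#' schedule, so that neural and behavioural habit measures share one latent
#' cause.
#'
#' @param subject subject identifier (character).
#' @param group `"stress"` or `"control"`.
#' @param seed master seed; all stage seeds are derived from it and the
#'   subject id.
#' @param settings a [study_settings()] list.
#' @param config a [task_config()].
#' @param g optional fixed habit susceptibility (drawn if `NULL`).
#' @return List with `subject`, `group`, `g`, `trials`, `dms_epochs`,
#'   `rl_stimulus`, `rl_choice`, and the `model` used.
#' @export
simulate_subject <- function(subject, group, seed,
                             settings = study_settings("full"),
                             config = task_config(), g = NULL) {
  if (is.null(g)) {
    g <- with_seed(derive_seed(seed, paste0("g/", subject)),
                   draw_habit_susceptibility(group, 1))
  }
  agent <- agent_params(
    habit_weight_schedule = habit_weight_schedule(config$n_blocks, g))
  trials <- generate_task_session(config, agent,
                                  derive_seed(seed, paste0("task/", subject)))
  model <- signal_model(
    n_channels = settings$n_channels, sampling_rate = settings$sampling_rate,
    epoch_length = settings$epoch_length,
    montage = spherical_montage(settings$n_channels),
    amplitude_schedule = habit_coupled_schedule(
      g, config$n_blocks, base = settings$base_amplitude),
    dms_amplitude = settings$dms_amplitude)
  dms <- do.call(pool_dms_sessions, lapply(seq_len(settings$dms_sessions),
    function(s) generate_dms_session(
      derive_seed(seed, sprintf("dms%d/%s", s, subject)),
      counts = settings$dms_counts, session = s)))
  list(subject = subject, group = group, g = g, trials = trials,
       model = model,
       dms_epochs = generate_epochs(dms, model, "dms_delay",
                                    derive_seed(seed, paste0("dmsepo/", subject)),
                                    group = group, subject = subject),
       rl_stimulus = generate_epochs(trials, model, "rl_stimulus",
                                     derive_seed(seed, paste0("stimepo/", subject)),
                                     group = group, subject = subject),
       rl_choice = generate_epochs(trials, model, "rl_choice",
                                   derive_seed(seed, paste0("choiceepo/", subject)),
                                   group = group, subject = subject))
}

#' Train and apply both decoders for one simulated subject
#'
#' Trains the outcome (object vs scene) and response (blue vs red symbol)
#' decoders on the subject's pooled DMS delay epochs with pseudo-trial
#' averaging, checks them against the adjusted-Wald chance threshold, and
#' decodes the three representations per learning-phase block: outcome at
#' stimulus, outcome at choice, response at stimulus.
#'
#' @param subj a list from [simulate_subject()].
#' @param spec sliding-window spec (defaults to the full-scale spec).
#' @param k pseudo-trial size.
#' @param group_size blocks per superblock.
#' @param seed seed for the pseudo-trial pairing.
#' @param cost SVM regularization constant.
#' @return List with `decoders` (outcome, response), `kept` (named logical),
#'   `series` (named list of per-block accuracy tables), `superblocks`
#'   (named list of [aggregate_blocks()] outputs), `deltas`, `devaluation`.
#' @export
decode_subject <- function(subj, spec = sliding_window_spec(), k = 2L,
                           group_size = 6L, seed = 1L, cost = 1) {
  dms <- subj$dms_epochs
  train_one <- function(pair, tag) {
    sub <- dms[dms$labels$category %in% pair]
    pseudo <- make_pseudo_trials(sub, k = k,
                                 seed = derive_seed(seed, paste0("pseudo/", tag)))
    train_decoder(pseudo, spec, cost = cost)
  }
  dec_out <- train_one(c("object", "scene"), "outcome")
  dec_resp <- train_one(c("blue_symbol", "red_symbol"), "response")
  kept <- c(
    outcome = dec_out$loo_accuracy > chance_threshold(dec_out$n_pseudo)$threshold,
    response = dec_resp$loo_accuracy > chance_threshold(dec_resp$n_pseudo)$threshold)
  series <- list(
    outcome_stimulus = decode_cross_task(dec_out, subj$rl_stimulus, spec),
    outcome_choice = decode_cross_task(dec_out, subj$rl_choice, spec),
    response_stimulus = decode_cross_task(dec_resp, subj$rl_stimulus, spec))
  superblocks <- lapply(series, function(s)
    aggregate_blocks(s$accuracy, group_size))
  devaluation <- devaluation_rates(subj$trials)
  deltas <- list(
    outcome_stimulus = delta_scores(series$outcome_stimulus$accuracy, devaluation),
    outcome_choice = delta_scores(series$outcome_choice$accuracy, devaluation),
    response_stimulus = delta_scores(series$response_stimulus$accuracy, devaluation))
  list(decoders = list(outcome = dec_out, response = dec_resp), kept = kept,
       series = series, superblocks = superblocks, deltas = deltas,
       devaluation = devaluation)
}

# per-subject ERP summary: P1 (grand average at Oz) + condition-wise fixed
# window means + late centroparietal bins, in long form
.erp_metrics <- function(stim_epochs) {
  erp <- compute_erp(baseline_correct(stim_epochs, c(-0.2, 0)),
                     by = c("block_type", "stimulus"))
  p1 <- find_p1_peak(erp)
  wm <- window_mean(erp)
  lb <- late_bins(erp)
  conds <- names(wm)
  rbind(
    data.frame(condition = "grand", metric = "p1_latency_s",
               value = p1$latency_s, stringsAsFactors = FALSE),
    data.frame(condition = "grand", metric = "p1_amplitude",
               value = p1$amplitude, stringsAsFactors = FALSE),
    data.frame(condition = conds, metric = "p1_window_mean",
               value = unname(wm), stringsAsFactors = FALSE),
    do.call(rbind, lapply(colnames(lb), function(bn)
      data.frame(condition = conds, metric = bn, value = unname(lb[, bn]),
                 stringsAsFactors = FALSE))))
}

#' Simulate and analyse a two-group cohort
#'
#' Runs [simulate_subject()] and [decode_subject()] for `n_per_group`
#' subjects per group and assembles the group-level tables: the group x
#' superblock mean-accuracy table for the three representations, per-subject
#' difference scores, and the brain-behaviour correlations (Spearman
#' delta-accuracy vs delta-devalued-responding; Bayes-factor correlation
#' between the outcome and response delta scores).
#'
#' @param n_per_group subjects per group.
#' @param seed master seed.
#' @param settings a [study_settings()] list.
#' @param config a [task_config()].
#' @param group_size blocks per superblock.
#' @param keep_epochs keep each subject's epoch sets in the return value
#'   (memory-heavy; default drops them).
#' @return A `cohort_result` list: `subjects` (per-subject table with g,
#'   decoder accuracies, kept flags, deltas, devalued responding),
#'   `superblock_table` (group x representation x superblock means),
#'   `series` (per-subject per-block accuracies), `correlations`.
#' @export
run_cohort <- function(n_per_group = 20L, seed = 1L,
                       settings = study_settings("full"),
                       config = task_config(), group_size = 6L,
                       keep_epochs = FALSE) {
  roster <- data.frame(
    subject = sprintf("s%02d", seq_len(2L * n_per_group)),
    group = rep(c("stress", "control"), each = n_per_group),
    stringsAsFactors = FALSE)
  subj_rows <- list(); series <- list(); sblocks <- list(); epochs <- list()
  trials_list <- list(); dev_list <- list(); erp_list <- list()
  decoders <- list()
  for (i in seq_len(nrow(roster))) {
    subj <- simulate_subject(roster$subject[i], roster$group[i], seed,
                             settings, config)
    res <- decode_subject(subj, settings$spec, group_size = group_size,
                          seed = derive_seed(seed, paste0("decode/", subj$subject)))
    dv <- res$devaluation
    trials_list[[i]] <- cbind(subject = subj$subject, group = subj$group,
                              subj$trials, stringsAsFactors = FALSE)
    dev_list[[i]] <- cbind(subject = subj$subject, group = subj$group, dv,
                           stringsAsFactors = FALSE)
    erp_list[[i]] <- tryCatch(
      cbind(subject = subj$subject, group = subj$group,
            .erp_metrics(subj$rl_stimulus), stringsAsFactors = FALSE),
      error = function(e) NULL)
    dev_last <- dv$prop_devalued[dv$block_type == "DevOhigh"]
    subj_rows[[i]] <- data.frame(
      subject = subj$subject, group = subj$group, g = subj$g,
      loo_outcome = res$decoders$outcome$loo_accuracy,
      loo_response = res$decoders$response$loo_accuracy,
      kept_outcome = res$kept[["outcome"]],
      kept_response = res$kept[["response"]],
      delta_outcome = res$deltas$outcome_stimulus$delta_accuracy,
      delta_outcome_choice = res$deltas$outcome_choice$delta_accuracy,
      delta_response = res$deltas$response_stimulus$delta_accuracy,
      delta_devalued = res$deltas$outcome_stimulus$delta_devalued,
      devalued_first = if (length(dev_last)) dev_last[1] else NA_real_,
      devalued_last = if (length(dev_last)) dev_last[length(dev_last)] else NA_real_,
      stringsAsFactors = FALSE)
    series[[subj$subject]] <- res$series
    sblocks[[subj$subject]] <- lapply(res$superblocks, attr, "superblock_means")
    decoders[[subj$subject]] <- lapply(res$decoders, function(d)
      list(class_pair = d$class_pair, weights = unname(d$weights),
           bias = d$bias, selected_window_s = d$selected_window,
           loo_accuracy = d$loo_accuracy, n_pseudo = d$n_pseudo))
    if (keep_epochs) epochs[[subj$subject]] <- subj
  }
  subjects <- do.call(rbind, subj_rows)
  reps <- c("outcome_stimulus", "outcome_choice", "response_stimulus")
  sb_tab <- do.call(rbind, lapply(reps, function(rp) {
    do.call(rbind, lapply(c("stress", "control"), function(gp) {
      mats <- do.call(rbind, lapply(subjects$subject[subjects$group == gp],
                                    function(s) sblocks[[s]][[rp]]))
      data.frame(representation = rp, group = gp,
                 superblock = seq_len(ncol(mats)),
                 mean_accuracy = colMeans(mats),
                 se_accuracy = apply(mats, 2, stats::sd) / sqrt(nrow(mats)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(sb_tab) <- NULL
  safe <- function(expr) tryCatch(expr, error = function(e) NULL)
  correlations <- list(
    outcome_vs_devalued = safe(spearman_corr(subjects$delta_outcome,
                                             subjects$delta_devalued)),
    response_vs_devalued = safe(spearman_corr(subjects$delta_response,
                                              subjects$delta_devalued)),
    outcome_vs_response = safe(bayes_corr(subjects$delta_outcome,
                                          subjects$delta_response)))
  structure(list(subjects = subjects, superblock_table = sb_tab,
                 series = series, correlations = correlations,
                 trials = do.call(rbind, trials_list),
                 decoders = decoders,
                 devaluation = do.call(rbind, dev_list),
                 erp = do.call(rbind, erp_list),
                 settings = settings, seed = seed,
                 epochs = if (keep_epochs) epochs else NULL),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("cohort_result: %d subjects (%s geometry, seed %d)\n",
              nrow(x$subjects), x$settings$scale, x$seed))
  tab <- x$superblock_table
  last <- max(tab$superblock)
  for (rp in unique(tab$representation)) {
    sel <- tab[tab$representation == rp & tab$superblock == last, ]
    cat(sprintf("  %s, final superblock: stress %.3f vs control %.3f\n", rp,
                sel$mean_accuracy[sel$group == "stress"],
                sel$mean_accuracy[sel$group == "control"]))
  }
  cr <- x$correlations
  if (!is.null(cr$outcome_vs_devalued) && !is.null(cr$response_vs_devalued))
    cat(sprintf("  Spearman d_outcome vs d_devalued: %.3f; d_response vs d_devalued: %.3f\n",
                cr$outcome_vs_devalued$estimate, cr$response_vs_devalued$estimate))
  if (!is.null(cr$outcome_vs_response))
    cat(sprintf("  BF01 (d_outcome vs d_response): %.3g\n",
                cr$outcome_vs_response$bf01))
  invisible(x)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param n_per_group subjects per group.
#' @param seed master seed; every stage seed is derived from it.
#' @param scale study geometry (see [study_settings()]).
#' @param group_size blocks per superblock.
#' @param n_blocks number of task blocks (devaluation schedule is scaled in
#'   from the default when shortened; mainly for smoke runs).
#' @return A `run_config` list; round-trips through YAML via
#'   [write_run_config()] / [read_run_config()].
#' @export
run_config <- function(n_per_group = 20L, seed = 1L,
                       scale = c("full", "reduced"), group_size = 6L,
                       n_blocks = 33L) {
  scale <- match.arg(scale)
  structure(list(n_per_group = as.integer(n_per_group),
                 seed = as.integer(seed), scale = scale,
                 group_size = as.integer(group_size),
                 n_blocks = as.integer(n_blocks)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(run_config, v)
}

.task_config_for <- function(n_blocks) {
  if (n_blocks >= 33L) return(task_config(n_blocks = n_blocks))
  # compress the devaluation schedule into a shorter session (smoke runs):
  # one high/low devaluation pair per ~11 blocks, keeping NoDev majority
  stopifnot(n_blocks >= 4L)
  n_pairs <- max(1L, n_blocks %/% 11L)
  hi <- unique(round(seq(2, n_blocks - 1, length.out = n_pairs)))
  task_config(n_blocks = n_blocks, dev_high_blocks = hi, dev_low_blocks = hi + 1L)
}

#' Run the full synthetic study and write a report bundle
#'
#' Simulates the cohort, decodes every subject, and writes: the pooled trial
#' table (CSV), per-subject decoder summaries (JSON), the per-block decoding
#' series (CSV), the group x superblock accuracy table (CSV), the
#' devaluation summary (CSV), correlation reports (JSON) and a plain-text
#' summary.  Identical configs produce identical bundles.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @param searchlight also run a searchlight map on one representative
#'   subject's DMS epochs (adds runtime).
#' @return The [run_cohort()] result, invisibly.
#' @export
run_pipeline <- function(config, out_dir, searchlight = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  task_cfg <- .task_config_for(config$n_blocks)
  gs <- config$group_size
  n_nodev <- sum(block_type_of(seq_len(task_cfg$n_blocks), task_cfg) == "NoDev")
  if (n_nodev %% gs != 0 && n_nodev < 24) gs <- n_nodev  # smoke configs
  res <- run_cohort(config$n_per_group, config$seed,
                    study_settings(config$scale), task_cfg, group_size = gs,
                    keep_epochs = FALSE)

  utils::write.csv(res$subjects, file.path(out_dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(res$trials, file.path(out_dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(res$devaluation, file.path(out_dir, "devaluation.csv"),
                   row.names = FALSE)
  if (!is.null(res$erp))
    utils::write.csv(res$erp, file.path(out_dir, "erp.csv"), row.names = FALSE)
  series_tab <- do.call(rbind, lapply(names(res$series), function(s) {
    do.call(rbind, lapply(names(res$series[[s]]), function(rp) {
      agg <- aggregate_blocks(res$series[[s]][[rp]]$accuracy, gs)
      cbind(subject = s, representation = rp, agg)
    }))
  }))
  utils::write.csv(series_tab, file.path(out_dir, "series.csv"), row.names = FALSE)
  utils::write.csv(res$superblock_table, file.path(out_dir, "superblocks.csv"),
                   row.names = FALSE)
  corr_json <- lapply(res$correlations, function(cr) {
    out <- list(method = cr$method, estimate = cr$estimate, n = cr$n,
                ci_low = cr$ci[1], ci_high = cr$ci[2])
    if (!is.null(cr$bf10)) {
      out$bf10 <- cr$bf10; out$bf01 <- cr$bf01; out$prior_width <- cr$prior_width
    }
    out
  })
  jsonlite::write_json(corr_json, file.path(out_dir, "correlations.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$decoders, file.path(out_dir, "decoders.json"),
                       auto_unbox = TRUE, digits = NA)
  if (isTRUE(searchlight)) {
    # searchlight on one representative subject's pooled DMS epochs, at the
    # outcome decoder's selected window centre
    subj <- simulate_subject(res$subjects$subject[1], res$subjects$group[1],
                             config$seed, study_settings(config$scale), task_cfg)
    d1 <- res$decoders[[subj$subject]]$outcome
    centre_t <- d1$selected_window_s + study_settings(config$scale)$spec$window_length / 2
    sl <- searchlight_decode(subj$dms_epochs, subj$model$montage,
                             c("object", "scene"), centre_t,
                             seed = derive_seed(config$seed, "searchlight"))
    utils::write.csv(sl, file.path(out_dir, "searchlight.csv"),
                     row.names = FALSE)
  }
  con <- file(file.path(out_dir, "summary.txt"), "w")
  sink(con); print(res); sink(); close(con)
  invisible(res)
}
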