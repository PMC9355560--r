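#' Reinforcement-learning task configuration
#'
#' Describes the block and trial structure of the instrumental learning
#' session: 33 blocks of 27 trials (12 learning trials per stimulus plus 3
#' consumption trials), with the high-valued outcome devalued in blocks
#' 2/16/29 and the low-valued outcome devalued in blocks 3/17/30.  Accepted
#' trades earn the current outcome value minus a fixed response cost;
#' rejected trades earn nothing and cost nothing.
#'
#' @param n_blocks number of blocks in the session.
#' @param learning_trials_per_stimulus learning trials per stimulus per block.
#' @param consumption_positions within-block trial indices of the free-choice
#'   consumption trials.
#' @param value_high,value_low point values of the two outcome categories.
#' @param response_cost points paid on every accepted trade.
#' @param dev_high_blocks,dev_low_blocks block indices in which the
#'   high-/low-valued outcome is devalued (worth 0 points, feedback masked).
#' @param timeout response deadline in seconds.
#' @return A `task_config` object (list).
#' @export
task_config <- function(n_blocks = 33L,
                        learning_trials_per_stimulus = 12L,
                        consumption_positions = c(7L, 14L, 21L),
                        value_high = 100,
                        value_low = 20,
                        response_cost = 5,
                        dev_high_blocks = c(2L, 16L, 29L),
                        dev_low_blocks = c(3L, 17L, 30L),
                        timeout = 2) {
  cfg <- list(n_blocks = as.integer(n_blocks),
              learning_trials_per_stimulus = as.integer(learning_trials_per_stimulus),
              consumption_positions = as.integer(consumption_positions),
              trials_per_block = 2L * as.integer(learning_trials_per_stimulus) +
                length(consumption_positions),
              value_high = value_high, value_low = value_low,
              response_cost = response_cost,
              dev_high_blocks = as.integer(dev_high_blocks),
              dev_low_blocks = as.integer(dev_low_blocks),
              timeout = timeout)
  class(cfg) <- "task_config"
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  if (length(intersect(cfg$dev_high_blocks, cfg$dev_low_blocks)) > 0)
    stop_config("dev_high_blocks and dev_low_blocks must be disjoint")
  if (any(c(cfg$dev_high_blocks, cfg$dev_low_blocks) < 1) ||
      any(c(cfg$dev_high_blocks, cfg$dev_low_blocks) > cfg$n_blocks))
    stop_config("devaluation block indices outside 1..n_blocks")
  if (!(cfg$value_high > cfg$value_low && cfg$value_low > cfg$response_cost &&
        cfg$response_cost > 0))
    stop_config("need value_high > value_low > response_cost > 0")
  if (any(cfg$consumption_positions < 1) ||
      any(cfg$consumption_positions > cfg$trials_per_block) ||
      anyDuplicated(cfg$consumption_positions))
    stop_config("consumption_positions must be distinct indices within a block")
  invisible(cfg)
}

#' Two-controller agent parameters
#'
#' The simulated agent mixes a goal-directed controller, which scores each
#' response by its expected net point value under the current (devaluation
#' aware) outcome values, with a habitual controller whose stimulus-response
#' strength grows by `habit_rate` on every executed (S, R) pair.  Choice is a
#' softmax over `goal_weight * EV + habit_weight[block] * habit strength`
#' with temperature `softmax_temperature` (in points).
#'
#' @param goal_weight weight of the expected-net-value term (dimensionless).
#' @param habit_rate per-execution habit-strength increment.
#' @param habit_weight_schedule numeric vector, one habit weight per block.
#' @param softmax_temperature softmax temperature in points; as it tends to 0
#'   choices become value-maximizing.
#' @param value_knowledge if `TRUE` (default) the agent knows the current
#'   devaluation state, so consumption-trial choices always track value.
#' @param timeout_prob probability that a learning trial times out.
#' @param rt_meanlog,rt_sdlog log-normal reaction-time parameters (seconds).
#' @return An `agent_params` object.
#' @seealso [habit_weight_schedule()] for stress/control profiles.
#' @export
agent_params <- function(goal_weight = 1,
                         habit_rate = 0.01,
                         habit_weight_schedule = rep(0, 33),
                         softmax_temperature = 2,
                         value_knowledge = TRUE,
                         timeout_prob = 0.01,
                         rt_meanlog = log(0.7),
                         rt_sdlog = 0.25) {
  stopifnot(goal_weight >= 0, habit_rate >= 0, softmax_temperature > 0,
            all(habit_weight_schedule >= 0), timeout_prob >= 0, timeout_prob < 1)
  structure(list(goal_weight = goal_weight, habit_rate = habit_rate,
                 habit_weight_schedule = habit_weight_schedule,
                 softmax_temperature = softmax_temperature,
                 value_knowledge = isTRUE(value_knowledge),
                 timeout_prob = timeout_prob,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog),
            class = "agent_params")
}

#' Habit-weight schedule for a stress or control profile
#'
#' Stressed agents ramp the weight of the habitual controller linearly across
#' training (scaled by the subject's latent habit susceptibility `g`), while
#' control agents keep it low and flat-ish.  The default gain is chosen so
#' that, with the default [agent_params()], devalued responding in the final
#' high-value devaluation block reaches roughly 0.4-0.5 for `g = 1` and stays
#' near 0.1 for `g = 0.15`, the qualitative group pattern the behavioural
#' paradigm is designed to detect.
#'
#' @param n_blocks number of blocks.
#' @param g latent habit susceptibility (>= 0); typical stress subjects ~1,
#'   control subjects ~0.15.
#' @param gain schedule endpoint for `g = 1`.
#' @return Numeric vector of length `n_blocks`.
#' @export
habit_weight_schedule <- function(n_blocks = 33L, g = 1, gain = 1.5) {
  stopifnot(g >= 0, n_blocks >= 1)
  x <- if (n_blocks == 1) 0 else (seq_len(n_blocks) - 1) / (n_blocks - 1)
  gain * g * x
}

# Fixed S-R-O mapping used by the generator (counterbalancing across real
# participants is irrelevant for synthetic data): S_high--R1->object (high
# value), S_low--R2->scene (low value); R1/R2 are cued by the blue/red symbol.
.SRO <- list(
  stimuli    = c("S_high", "S_low"),
  correct    = c(S_high = "R1", S_low = "R2"),
  outcome    = c(S_high = "object", S_low = "scene"),
  symbol     = c(R1 = "blue_symbol", R2 = "red_symbol")
)

block_type_of <- function(block, cfg) {
  ifelse(block %in% cfg$dev_high_blocks, "DevOhigh",
         ifelse(block %in% cfg$dev_low_blocks, "DevOlow", "NoDev"))
}

# current point value of an outcome category within a block type
current_value <- function(outcome_cat, block_type, cfg) {
  base <- ifelse(outcome_cat == "object", cfg$value_high,
                 ifelse(outcome_cat == "scene", cfg$value_low, 0))
  dev <- (block_type == "DevOhigh" & outcome_cat == "object") |
         (block_type == "DevOlow"  & outcome_cat == "scene")
  ifelse(dev, 0, base)
}

#' Simulate one behavioural session of the instrumental learning task
#'
#' Runs the two-controller agent through the configured session and returns
#' one row per trial.  Learning-trial choices are softmax draws over the
#' goal-directed and habitual utilities; consumption trials are free choices
#' between the two outcome categories at their current values (no response
#' cost, no habit contribution).  Feedback is masked (`feedback_masked = 1`)
#' on every trial of a devaluation block.
#'
#' @param config a [task_config()].
#' @param agent an [agent_params()]; `habit_weight_schedule` must cover every
#'   block.
#' @param seed integer seed; identical inputs give identical tables.
#' @return A `data.frame` with columns `block`, `block_type`, `trial_index`,
#'   `trial_type`, `stimulus`, `response`, `response_cat`, `outcome_cat`,
#'   `accepted`, `points_delta`, `feedback_masked`, `rt_s`.  Timed-out trials
#'   have `NA` response.  `outcome_cat` is the category obtained ("none" when
#'   the trade was rejected); on consumption trials it is the chosen card.
#' @export
generate_task_session <- function(config = task_config(),
                                  agent = agent_params(),
                                  seed = 1L) {
  validate_task_config(config)
  if (length(agent$habit_weight_schedule) < config$n_blocks)
    stop_config("habit_weight_schedule must cover every block")
  with_seed(seed, {
    n_learn <- 2L * config$learning_trials_per_stimulus
    rows <- vector("list", config$n_blocks)
    habit <- matrix(0, nrow = 2, ncol = 2,
                    dimnames = list(.SRO$stimuli, c("R1", "R2")))
    for (b in seq_len(config$n_blocks)) {
      btype <- block_type_of(b, config)
      hw <- agent$habit_weight_schedule[b]
      stim_seq <- sample(rep(.SRO$stimuli, config$learning_trials_per_stimulus))
      df <- data.frame(block = b, block_type = btype,
                       trial_index = seq_len(config$trials_per_block),
                       trial_type = "learning", stimulus = NA_character_,
                       response = NA_character_, response_cat = NA_character_,
                       outcome_cat = "none", accepted = 0L, points_delta = 0,
                       feedback_masked = as.integer(btype != "NoDev"),
                       rt_s = NA_real_, stringsAsFactors = FALSE)
      df$trial_type[config$consumption_positions] <- "consumption"
      df$stimulus[df$trial_type == "learning"] <- stim_seq
      for (i in seq_len(config$trials_per_block)) {
        if (df$trial_type[i] == "consumption") {
          # free choice between the two cards at current value, no cost
          v <- current_value(c("object", "scene"), btype, config)
          if (!agent$value_knowledge)
            v <- current_value(c("object", "scene"), "NoDev", config)
          u <- agent$goal_weight * v
          p <- 1 / (1 + exp(-(u[1] - u[2]) / agent$softmax_temperature))
          pick <- if (stats::runif(1) < p) "object" else "scene"
          df$outcome_cat[i] <- pick
          df$points_delta[i] <- current_value(pick, btype, config)
          df$rt_s[i] <- min(stats::rlnorm(1, agent$rt_meanlog, agent$rt_sdlog),
                            config$timeout)
          next
        }
        s <- df$stimulus[i]
        if (stats::runif(1) < agent$timeout_prob) next  # timeout: NA response
        r_corr <- .SRO$correct[[s]]
        r_alt <- setdiff(c("R1", "R2"), r_corr)
        o <- .SRO$outcome[[s]]
        ev_corr <- current_value(o, btype, config) - config$response_cost
        ev_alt <- 0
        u_corr <- agent$goal_weight * ev_corr + hw * habit[s, r_corr]
        u_alt <- agent$goal_weight * ev_alt + hw * habit[s, r_alt]
        p_corr <- 1 / (1 + exp(-(u_corr - u_alt) / agent$softmax_temperature))
        r <- if (stats::runif(1) < p_corr) r_corr else r_alt
        habit[s, r] <- habit[s, r] + agent$habit_rate
        acc <- as.integer(r == r_corr)
        df$response[i] <- r
        df$response_cat[i] <- .SRO$symbol[[r]]
        df$accepted[i] <- acc
        df$outcome_cat[i] <- if (acc == 1L) o else "none"
        df$points_delta[i] <- if (acc == 1L)
          current_value(o, btype, config) - config$response_cost else 0
        df$rt_s[i] <- min(stats::rlnorm(1, agent$rt_meanlog, agent$rt_sdlog),
                          config$timeout)
      }
      rows[[b]] <- df
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate one delayed-matching-to-sample (DMS) session
#'
#' Produces the per-trial category sequence of one 128-trial DMS session over
#' the four target categories (object and scene cards, blue and red symbols),
#' with the constraint that the same category never occurs more than
#' `max_run` times in a row.  Two sessions (before/after learning) are pooled
#' with [pool_dms_sessions()] for classifier training.
#'
#' @param seed integer seed.
#' @param counts named per-session trial counts; the default 45/45/19/19
#'   preserves the pooled object+scene raw count of 180 across two sessions
#'   (90 pseudo-trials after pairwise averaging).
#' @param max_run maximal run length of a single category.
#' @param session session index stored in the output (1 or 2).
#' @return A `data.frame` with columns `session`, `trial`, `category`.
#' @export
generate_dms_session <- function(seed = 1L,
                                 counts = c(object = 45L, scene = 45L,
                                            blue_symbol = 19L, red_symbol = 19L),
                                 max_run = 3L,
                                 session = 1L) {
  stopifnot(all(counts >= 0), !is.null(names(counts)), max_run >= 1)
  with_seed(seed, {
    for (attempt in 1:100) {
      remaining <- counts
      seq_out <- character(sum(counts))
      ok <- TRUE
      for (i in seq_along(seq_out)) {
        cand <- names(remaining)[remaining > 0]
        if (i > max_run) {
          last <- seq_out[(i - max_run):(i - 1)]
          if (length(unique(last)) == 1L) cand <- setdiff(cand, last[1])
        }
        if (length(cand) == 0L) { ok <- FALSE; break }
        pick <- if (length(cand) == 1L) cand else
          sample(cand, 1, prob = remaining[cand])
        seq_out[i] <- pick
        remaining[pick] <- remaining[pick] - 1L
      }
      if (ok) break
    }
    if (!ok) stop("could not satisfy the run-length constraint")
    data.frame(session = as.integer(session), trial = seq_along(seq_out),
               category = seq_out, stringsAsFactors = FALSE)
  })
}

#' Pool DMS sessions for classifier training
#'
#' @param ... DMS trial tables from [generate_dms_session()].
#' @return A single table with renumbered `trial`.
#' @export
pool_dms_sessions <- function(...) {
  out <- do.call(rbind, list(...))
  out$trial <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
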