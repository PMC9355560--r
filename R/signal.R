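#' Spherical-head EEG montage fixture
#'
#' Deterministic 10-5-style electrode layout on a spherical head: channels
#' are spread quasi-uniformly (Fibonacci lattice) over a cap extending
#' `theta_max` degrees from the vertex, and the points nearest to a set of
#' canonical 10-10 landmark directions (Cz, Oz, POz, Pz, CPz, ...) are
#' snapped to those landmarks and given their names.  Coordinates are
#' head-centred cm: +x nose, +y left ear, +z vertex.
#'
#' @param n_channels number of electrodes.
#' @param head_radius head radius in cm.
#' @param theta_max cap half-angle in degrees (how far below the vertex the
#'   montage extends).
#' @return A `data.frame` with columns `channel_id`, `x_cm`, `y_cm`, `z_cm`.
#' @export
spherical_montage <- function(n_channels = 128L, head_radius = 9.5,
                              theta_max = 90) {
  stopifnot(n_channels >= 1, head_radius > 0)
  # Fibonacci lattice over the cap
  i <- seq_len(n_channels) - 0.5
  zmin <- cos(theta_max * pi / 180)
  z <- 1 - i / n_channels * (1 - zmin)
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden
  pts <- cbind(x = sqrt(1 - z^2) * cos(phi),
               y = sqrt(1 - z^2) * sin(phi),
               z = z) * head_radius
  ids <- sprintf("E%03d", seq_len(n_channels))

  anchors <- .montage_anchors()
  avail <- rep(TRUE, n_channels)
  for (k in seq_len(nrow(anchors))) {
    a <- .sph_to_cart(anchors$theta[k], anchors$phi[k], head_radius)
    d2 <- rowSums((pts - matrix(a, n_channels, 3, byrow = TRUE))^2)
    d2[!avail] <- Inf
    j <- which.min(d2)
    if (!is.finite(d2[j])) next
    pts[j, ] <- a                       # snap to the canonical position
    ids[j] <- anchors$name[k]
    avail[j] <- FALSE
  }
  data.frame(channel_id = ids, x_cm = pts[, 1], y_cm = pts[, 2],
             z_cm = pts[, 3], stringsAsFactors = FALSE)
}

# canonical 10-10 landmark directions: theta = polar angle from vertex,
# phi = azimuth (0 = nose, 90 = left ear, 180 = inion), degrees
.montage_anchors <- function() {
  # ordered so that small montages still get a mix of midline and lateral
  # sites (lateral asymmetry matters for the lateralized category patterns)
  data.frame(
    name  = c("Cz", "Oz", "CPz", "Pz", "CP1", "CP2", "PO7", "PO8",
              "O1", "O2", "C3", "C4", "POz", "Fz", "FCz", "Fpz",
              "P3", "P4", "CP3", "CP4", "T7", "T8"),
    theta = c(0, 92, 23, 46, 32, 32, 92, 92,
              92, 92, 46, 46, 69, 46, 23, 92,
              60, 60, 40, 40, 92, 92),
    phi   = c(0, 180, 180, 180, 155, 205, 144, 216,
              162, 198, 90, 270, 180, 0, 0, 0,
              145, 215, 135, 225, 90, 270),
    stringsAsFactors = FALSE
  )
}

.sph_to_cart <- function(theta_deg, phi_deg, r) {
  th <- theta_deg * pi / 180; ph <- phi_deg * pi / 180
  c(r * sin(th) * cos(ph), r * sin(th) * sin(ph), r * cos(th))
}

montage_positions <- function(montage) {
  as.matrix(montage[, c("x_cm", "y_cm", "z_cm")])
}

# Gaussian spatial weight map around a scalp direction, unit Euclidean norm
.spatial_pattern <- function(montage, theta, phi, width_cm, head_radius) {
  centre <- .sph_to_cart(theta, phi, head_radius)
  d <- sqrt(rowSums((montage_positions(montage) -
                       matrix(centre, nrow(montage), 3, byrow = TRUE))^2))
  w <- exp(-d^2 / (2 * width_cm^2))
  w / sqrt(sum(w^2))
}

#' Constant amplitude schedule
#'
#' @param amplitude signal amplitude used for every representation and block.
#' @return A function `(representation, block) -> amplitude`.
#' @export
constant_schedule <- function(amplitude = 0.25) {
  force(amplitude)
  function(representation, block) rep(amplitude, length(block))
}

#' Training-stage amplitude schedule tied to habit susceptibility
#'
#' Encodes the generative hypothesis linking neural representations to the
#' behavioural habit shift: a subject's latent habit susceptibility `g`
#' drives, across blocks, a decline of the outcome-category signal and a rise
#' of the response-category signal.  Stressed subjects (high `g`, ~1) lose
#' outcome signal and gain response signal; control subjects (low `g`, ~0.15)
#' drift slightly the opposite way.  Used both for the EEG amplitudes and
#' (through [habit_weight_schedule()]) for behaviour, so decoding and
#' devaluation measures share one latent cause.
#'
#' @param g latent habit susceptibility.
#' @param n_blocks number of task blocks.
#' @param base baseline signal amplitude.
#' @param outcome_slope,response_slope coupling strengths.
#' @param outcome_pivot,response_pivot values of `g` at which the respective
#'   schedule is flat.
#' @return A function `(representation, block) -> amplitude`, with
#'   representation one of `"outcome"`, `"response"`, `"outcome_choice"`.
#' @export
habit_coupled_schedule <- function(g, n_blocks = 33L, base = 0.25,
                                   outcome_slope = 1.0, response_slope = 1.1,
                                   outcome_pivot = 0.25, response_pivot = 0.4) {
  force(g); force(n_blocks); force(base)
  function(representation, block) {
    x <- (block - 1) / max(n_blocks - 1, 1)
    a <- switch(representation,
      outcome        = base * (1 - outcome_slope * (g - outcome_pivot) * x),
      outcome_choice = 0.9 * base * (1 - outcome_slope * (g - outcome_pivot) * x),
      response       = base * (1 + response_slope * (g - response_pivot) * x),
      stop("unknown representation: ", representation))
    pmax(a, 0)
  }
}

#' EEG signal model for synthetic epochs
#'
#' Generative model of category-specific epochs: each trial is a sum of
#' unit-norm spatial patterns (parieto-occipital maps for the outcome
#' categories object/scene, centroparietal maps for the response-symbol
#' categories) modulated by a Gaussian temporal kernel peaking
#' `kernel_latency` seconds after the event, plus spatially correlated
#' Gaussian noise (exponential spatial covariance, so montage geometry
#' matters for the searchlight).  Stimulus-locked learning-task epochs can
#' additionally carry evoked components: an occipital P1-like bump at 115 ms
#' (value-insensitive) and a late centroparietal 400-700 ms component scaled
#' by the current outcome value.
#'
#' @param n_channels,sampling_rate,epoch_length tensor geometry (defaults:
#'   128 channels, 250 Hz, 2 s).
#' @param montage electrode layout, default [spherical_montage()].
#' @param amplitude_schedule function `(representation, block) -> amplitude`
#'   for learning-task epochs; see [habit_coupled_schedule()].
#' @param dms_amplitude category-signal amplitude in DMS delay epochs.
#' @param kernel_latency,kernel_width Gaussian temporal kernel (s).
#' @param pattern_width spatial width (cm) of the category maps.
#' @param noise_scale noise standard deviation per channel and sample.
#' @param spatial_noise_correlation noise correlation between channels 2 cm
#'   apart; decays exponentially with distance.
#' @param p1_amplitude,late_amplitude evoked-component amplitudes (0 to
#'   disable).
#' @return A `signal_model` object with precomputed category patterns and
#'   noise Cholesky factor.
#' @export
signal_model <- function(n_channels = 128L, sampling_rate = 250,
                         epoch_length = 2,
                         montage = spherical_montage(n_channels),
                         amplitude_schedule = constant_schedule(0.25),
                         dms_amplitude = 0.25,
                         kernel_latency = 0.2, kernel_width = 0.05,
                         pattern_width = 3,
                         noise_scale = 1, spatial_noise_correlation = 0.6,
                         p1_amplitude = 0.6, late_amplitude = 0.4) {
  stopifnot(nrow(montage) == n_channels, noise_scale >= 0,
            spatial_noise_correlation >= 0, spatial_noise_correlation < 1,
            dms_amplitude >= 0)
  head_radius <- sqrt(max(rowSums(montage_positions(montage)^2)))
  # category maps: outcome categories parieto-occipital, response symbols
  # centroparietal, lateralized within each pair
  pat <- cbind(
    object      = .spatial_pattern(montage, 80, 150, pattern_width, head_radius),
    scene       = .spatial_pattern(montage, 80, 210, pattern_width, head_radius),
    blue_symbol = .spatial_pattern(montage, 35, 130, pattern_width, head_radius),
    red_symbol  = .spatial_pattern(montage, 35, 230, pattern_width, head_radius))
  p1_pat   <- .spatial_pattern(montage, 92, 180, 2.5, head_radius)  # at Oz
  late_pat <- .spatial_pattern(montage, 23, 180, 3.0, head_radius)  # at CPz
  L <- NULL
  if (noise_scale > 0 && spatial_noise_correlation > 0) {
    D <- as.matrix(stats::dist(montage_positions(montage)))
    Sigma <- spatial_noise_correlation^(D / 2)
    L <- t(chol(Sigma))
  }
  structure(list(n_channels = as.integer(n_channels),
                 sampling_rate = sampling_rate, epoch_length = epoch_length,
                 montage = montage, category_patterns = pat,
                 amplitude_schedule = amplitude_schedule,
                 dms_amplitude = dms_amplitude,
                 kernel_latency = kernel_latency, kernel_width = kernel_width,
                 noise_scale = noise_scale,
                 spatial_noise_correlation = spatial_noise_correlation,
                 p1_amplitude = p1_amplitude, late_amplitude = late_amplitude,
                 p1_pattern = p1_pat, late_pattern = late_pat,
                 noise_chol = L),
            class = "signal_model")
}

.gauss_kernel <- function(t, latency, width) exp(-(t - latency)^2 / (2 * width^2))

.late_kernel <- function(t, on = 0.4, off = 0.7, ramp = 0.02) {
  1 / (1 + exp(-(t - on) / ramp)) * (1 - 1 / (1 + exp(-(t - off) / ramp)))
}

.sample_noise <- function(model, n_ch, n_samp) {
  if (model$noise_scale == 0) return(matrix(0, n_ch, n_samp))
  z <- matrix(stats::rnorm(n_ch * n_samp), n_ch, n_samp)
  if (!is.null(model$noise_chol)) z <- model$noise_chol %*% z
  model$noise_scale * z
}

#' Generate synthetic EEG epochs for a trial table
#'
#' Builds one epoch per applicable trial: DMS delay epochs carry the trial's
#' category pattern at `dms_amplitude`; learning-task stimulus-locked epochs
#' carry the stimulus's associated outcome-category pattern (amplitude
#' `amplitude_schedule("outcome", block)`) plus the chosen response's symbol
#' pattern (`"response"` amplitude) plus optional evoked P1/late components;
#' choice-locked epochs carry the outcome pattern at the `"outcome_choice"`
#' amplitude.  Consumption and timed-out trials yield no learning-task epoch.
#'
#' @param trials a DMS table ([generate_dms_session()] /
#'   [pool_dms_sessions()]) for `phase = "dms_delay"`, otherwise a task table
#'   from [generate_task_session()].
#' @param model a [signal_model()].
#' @param phase which event the epochs are locked to.
#' @param seed integer seed (same inputs, same seed: identical tensor).
#' @param group,subject stored in the label table.
#' @return An [epoch_set()].  Stimulus-locked epochs start at `t0 = -0.2` s
#'   (a prestimulus baseline for ERP use); the other phases start at 0.
#' @export
generate_epochs <- function(trials, model,
                            phase = c("dms_delay", "rl_stimulus", "rl_choice"),
                            seed = 1L, group = NA_character_,
                            subject = NA_character_) {
  phase <- match.arg(phase)
  rate <- model$sampling_rate
  t0 <- if (phase == "rl_stimulus") -0.2 else 0
  n_samp <- round((model$epoch_length - t0) * rate)
  t <- t0 + (seq_len(n_samp) - 1) / rate
  # delay-phase epochs carry a sustained maintenance signal (ramping on by
  # ~100 ms and held across the delay); event-locked learning-task epochs
  # carry a transient representation peaking at kernel_latency
  kern <- if (phase == "dms_delay") {
    1 / (1 + exp(-(t - 0.1) / 0.02))
  } else {
    .gauss_kernel(t, model$kernel_latency, model$kernel_width)
  }

  if (phase == "dms_delay") {
    if (!("category" %in% names(trials)))
      stop("DMS trial table must have a category column")
    bad <- setdiff(unique(trials$category), colnames(model$category_patterns))
    if (length(bad)) stop("unknown category label(s): ", paste(bad, collapse = ", "))
    keep <- trials
    labels <- data.frame(task = "DMS", phase = "delay",
                         category = keep$category,
                         session = keep$session %||% NA_integer_,
                         block = NA_integer_, block_type = NA_character_,
                         group = group, subject = subject,
                         stringsAsFactors = FALSE)
    amp_mat <- cbind(rep(model$dms_amplitude, nrow(keep)))
    pats <- lapply(keep$category, function(cat)
      model$category_patterns[, cat, drop = FALSE])
  } else {
    # stimulus-locked epochs exist even for timeouts (the stimulus was
    # shown); choice-locked epochs require a response
    keep <- trials[trials$trial_type == "learning", , drop = FALSE]
    if (phase == "rl_choice")
      keep <- keep[!is.na(keep$response), , drop = FALSE]
    out_cat <- unname(.SRO$outcome[keep$stimulus])
    resp_cat <- ifelse(is.na(keep$response_cat),
                       unname(.SRO$symbol[unname(.SRO$correct[keep$stimulus])]),
                       keep$response_cat)
    labels <- data.frame(task = "RL",
                         phase = if (phase == "rl_stimulus") "stimulus" else "choice",
                         category = NA_character_,
                         session = NA_integer_,
                         block = keep$block, block_type = keep$block_type,
                         stimulus = keep$stimulus,
                         outcome_cat = out_cat, response_cat = resp_cat,
                         group = group, subject = subject,
                         stringsAsFactors = FALSE)
    sched <- model$amplitude_schedule
    if (phase == "rl_stimulus") {
      amp_out <- vapply(keep$block, function(b) sched("outcome", b), 0)
      amp_resp <- vapply(keep$block, function(b) sched("response", b), 0)
      amp_mat <- cbind(amp_out, amp_resp)
      pats <- Map(function(oc, rc) cbind(model$category_patterns[, oc],
                                         model$category_patterns[, rc]),
                  out_cat, resp_cat)
    } else {
      amp_mat <- cbind(vapply(keep$block, function(b) sched("outcome_choice", b), 0))
      pats <- lapply(out_cat, function(oc)
        model$category_patterns[, oc, drop = FALSE])
    }
  }

  n_tr <- nrow(keep)
  data <- array(0, c(n_tr, model$n_channels, n_samp))
  with_seed(seed, {
    for (i in seq_len(n_tr)) {
      sig <- pats[[i]] %*% outer(amp_mat[i, seq_len(ncol(pats[[i]]))], kern)
      if (phase == "rl_stimulus" &&
          (model$p1_amplitude > 0 || model$late_amplitude > 0)) {
        cfg_vals <- c(object = 100, scene = 20)
        val <- cfg_vals[[labels$outcome_cat[i]]]
        if (labels$block_type[i] == "DevOhigh" && labels$outcome_cat[i] == "object") val <- 0
        if (labels$block_type[i] == "DevOlow" && labels$outcome_cat[i] == "scene") val <- 0
        sig <- sig +
          model$p1_amplitude * model$p1_pattern %o% .gauss_kernel(t, 0.115, 0.03) +
          model$late_amplitude * (val / 100) * model$late_pattern %o% .late_kernel(t)
      }
      data[i, , ] <- sig + .sample_noise(model, model$n_channels, n_samp)
    }
  })
  epoch_set(data, rate, t0, model$montage$channel_id, labels)
}
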