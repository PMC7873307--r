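# Synthetic session generator: reversal-learning task schedule, RW agent,
# and multi-array Poisson populations with planted tuning, a caudo-rostral
# latency/strength gradient, and lagged directed coupling between arrays.
# Every planted effect is recorded in the ground-truth object so downstream
# stages can be tested for recovery.

REGIONS <- c("rdlPFC", "mdlPFC", "cdlPFC", "vlPFC")
DOMAINS <- c("action", "object", "reward", "value")

#' Electrode-array layout
#'
#' Default layout of the recording preparation: four arrays per hemisphere
#' (array numbers 1-4 mapped to rdlPFC, mdlPFC, cdlPFC, vlPFC), 96 electrodes
#' each, 768 electrodes total. The number of simulated neurons per array is a
#' generator choice, not an electrode count.
#'
#' @param n_numbers How many array numbers (1..4) to include per hemisphere.
#' @param hemispheres Character vector, subset of `c("L", "R")`.
#' @param n_electrodes Electrodes per array.
#' @param n_neurons Simulated neurons per array.
#' @return data.frame with one row per array: `array_id` (e.g. "L3"),
#'   `array_number`, `hemisphere`, `region`, `n_electrodes`, `n_neurons`.
#'   Attribute `total_electrodes` holds the electrode sum.
#' @export
array_layout <- function(n_numbers = 4, hemispheres = c("L", "R"),
                         n_electrodes = 96, n_neurons = 20) {
  stopifnot(n_numbers >= 1, n_numbers <= 4,
            all(hemispheres %in% c("L", "R")))
  grid <- expand.grid(array_number = seq_len(n_numbers),
                      hemisphere = hemispheres,
                      stringsAsFactors = FALSE)
  layout <- data.frame(
    array_id = paste0(grid$hemisphere, grid$array_number),
    array_number = grid$array_number,
    hemisphere = grid$hemisphere,
    region = REGIONS[grid$array_number],
    n_electrodes = n_electrodes,
    n_neurons = n_neurons,
    stringsAsFactors = FALSE
  )
  attr(layout, "total_electrodes") <- sum(layout$n_electrodes)
  layout
}

#' Generate one task block schedule
#'
#' One block of the reversal-learning bandit: 80 trials, a reversal trial
#' drawn uniformly from 30..50 inclusive, random left/right object placement
#' on every trial, and a 70%/30% stochastic reward schedule attached to
#' objects (What blocks) or to actions (Where blocks). The reward mapping
#' flips from the reversal trial onward. Uses the current RNG stream.
#'
#' @param block_type `"What"` or `"Where"`.
#' @param n_trials Trials per block.
#' @param reversal_range Inclusive range the reversal trial is drawn from.
#' @param p_better Reward probability of the currently better option (the
#'   other option rewards at `1 - p_better`).
#' @return data.frame with columns `block_type`, `trial_index_in_block`,
#'   `object_left`, `object_right`, `reversal_trial`, `better_initial`,
#'   `better_current`, `p_better`.
#' @export
generate_task_block <- function(block_type = c("What", "Where"),
                                n_trials = 80L,
                                reversal_range = c(30L, 50L),
                                p_better = 0.7) {
  block_type <- match.arg(block_type)
  reversal <- sample(seq.int(reversal_range[1], reversal_range[2]), 1L)
  left_is_A <- stats::runif(n_trials) < 0.5
  options <- if (block_type == "What") c("A", "B") else c("left", "right")
  better_initial <- sample(options, 1L)
  better_other <- setdiff(options, better_initial)
  idx <- seq_len(n_trials)
  better_current <- ifelse(idx < reversal, better_initial, better_other)
  data.frame(
    block_type = block_type,
    trial_index_in_block = idx,
    object_left = ifelse(left_is_A, "A", "B"),
    object_right = ifelse(left_is_A, "B", "A"),
    reversal_trial = reversal,
    better_initial = better_initial,
    better_current = better_current,
    p_better = p_better,
    stringsAsFactors = FALSE
  )
}

#' Simulate an agent on a block schedule
#'
#' Plays one block: choices are sampled from the Rescorla-Wagner logistic
#' policy (`policy = "rw"`), forced to the currently better option
#' (`"best"`, tracking the reversal), forced to the initially better option
#' (`"initial"`, ignoring the reversal), or uniform random (`"random"`).
#' Rewards are drawn from the
#' schedule's 70%/30% probabilities given the choice; values are updated
#' trial by trial. Option 1 is object "A" in What blocks and action "left"
#' in Where blocks.
#'
#' @param schedule Output of [generate_task_block()].
#' @param params [rw_params()] used for `policy = "rw"` (and for value
#'   updates under all policies).
#' @param policy Choice policy.
#' @param v0 Initial option values at block start.
#' @param rt_mean,rt_sd Reaction-time fill values (ms); descriptive only.
#' @return The schedule augmented with `chosen_action`, `chosen_object`,
#'   `reward`, `reaction_time`, and agent traces `agent_v1`, `agent_v2`,
#'   `agent_v_chosen`, `agent_d1`.
#' @export
simulate_agent <- function(schedule, params,
                           policy = c("rw", "best", "initial", "random"),
                           v0 = 0.5, rt_mean = 210, rt_sd = 15) {
  policy <- match.arg(policy)
  n <- nrow(schedule)
  bt <- schedule$block_type[1]
  what <- bt == "What"
  v <- c(v0, v0)
  chosen_action <- chosen_object <- character(n)
  reward <- integer(n)
  v1 <- v2 <- vch <- d1v <- numeric(n)
  for (k in seq_len(n)) {
    d1 <- stats::plogis(params$beta * (v[1] - v[2]))
    v1[k] <- v[1]; v2[k] <- v[2]; d1v[k] <- d1
    left_obj <- schedule$object_left[k]
    choose1 <- switch(policy,
      rw = stats::runif(1) < d1,
      random = stats::runif(1) < 0.5,
      best = {
        # option 1 is "A"/"left"; pick whichever option is currently better
        schedule$better_current[k] %in% c("A", "left")
      },
      initial = schedule$better_initial[k] %in% c("A", "left"))
    if (what) {
      chosen_object[k] <- if (choose1) "A" else "B"
      chosen_action[k] <- if (chosen_object[k] == left_obj) "left" else "right"
    } else {
      chosen_action[k] <- if (choose1) "left" else "right"
      chosen_object[k] <- if (chosen_action[k] == "left") left_obj else
        setdiff(c("A", "B"), left_obj)
    }
    chosen_key <- if (what) chosen_object[k] else chosen_action[k]
    p_r <- if (chosen_key == schedule$better_current[k])
      schedule$p_better[k] else 1 - schedule$p_better[k]
    reward[k] <- stats::rbinom(1, 1, p_r)
    ch_idx <- if (choose1) 1L else 2L
    vch[k] <- v[ch_idx]
    v <- update_values(v, ch_idx, reward[k], params)
  }
  out <- schedule
  out$chosen_action <- chosen_action
  out$chosen_object <- chosen_object
  out$reward <- reward
  out$reaction_time <- stats::rnorm(n, rt_mean, rt_sd)
  out$agent_v1 <- v1; out$agent_v2 <- v2
  out$agent_v_chosen <- vch; out$agent_d1 <- d1v
  out
}

#' Default synthetic-session configuration
#'
#' Returns the generator's study conditions: 24 blocks of 80 trials, reversal
#' in 30..50, 70%/30% rewards, an agent at `beta = 5`, `delta_pos = 0.6`,
#' `delta_neg = 0.3`, the 8-array layout, 20 neurons per array, a
#' caudo-rostral tuning-prevalence/strength/latency gradient (onsets
#' 250/200/150/100 ms for arrays 1-4; modulation depth = `modulation_gain`
#' x baseline, scaled down rostrally), and a default directed coupling set:
#' within-domain caudal-to-rostral chains (4 to 3, 3 to 2, 2 to 1; lag 2
#' decoding bins = 40 ms, gain 0.8) for action and object, plus an
#' object-to-action cross-domain link 4 to 3 (lag 3 bins, gain 0.5) in What
#' blocks. Any field can be overridden by name; unknown names are rejected.
#'
#' @param ... Named overrides of the default fields.
#' @return A named list (class `session_config`).
#' @export
session_config <- function(...) {
  cfg <- list(
    n_blocks = 24L,
    n_trials_per_block = 80L,
    reversal_range = c(30L, 50L),
    p_better = 0.7,
    agent = list(beta = 5, delta_pos = 0.6, delta_neg = 0.3),
    agent_policy = "rw",
    layout = array_layout(),
    window_s = c(-1.5, 1.5),
    base_bin_ms = 10,
    # per array number 1..4 (rostral -> caudal/ventral)
    tuned_fraction_by_number = c(0.4, 0.6, 0.8, 0.9),
    domain_mix = c(action = 0.3, object = 0.3, reward = 0.2, value = 0.2),
    modulation_gain = 0.5,
    modulation_scale_by_number = c(0.5, 0.7, 0.85, 1.0),
    modulation_jitter_sdlog = 0.2,
    onset_ms_by_number = c(250, 200, 150, 100),
    ramp_ms = 150,
    hold_gain = 0.3,
    baseline_median_hz = 5,
    baseline_sdlog = 0.5,
    baseline_scale_by_number = c(0.85, 0.9, 1.0, 1.1),
    latent_noise_sd = 0.6,
    latent_ar_rho = 0.4,
    coupling = c(
      lapply(c("action", "object"), function(dm) {
        list(
          list(src_number = 4L, tgt_number = 3L, src_domain = dm,
               tgt_domain = dm, lag_bins = 2L, gain = 0.8),
          list(src_number = 3L, tgt_number = 2L, src_domain = dm,
               tgt_domain = dm, lag_bins = 2L, gain = 0.8),
          list(src_number = 2L, tgt_number = 1L, src_domain = dm,
               tgt_domain = dm, lag_bins = 2L, gain = 0.8))
      }) |> unlist(recursive = FALSE),
      list(list(src_number = 4L, tgt_number = 3L, src_domain = "object",
                tgt_domain = "action", lag_bins = 3L, gain = 0.5,
                block_type = "What"))
    ),
    keep_latents = FALSE,
    return_spike_times = FALSE
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad) || is.null(names(overrides)) ||
        any(names(overrides) == "")) {
      stop("unknown or unnamed config field(s): ",
           paste(bad, collapse = ", "))
    }
    cfg[names(overrides)] <- overrides
  }
  structure(cfg, class = "session_config")
}

# Per-neuron ground-truth tuning table for a layout.
plan_ground_truth <- function(layout, cfg) {
  rows <- list()
  nid <- 0L
  for (a in seq_len(nrow(layout))) {
    num <- layout$array_number[a]
    n <- layout$n_neurons[a]
    tuned <- stats::runif(n) < cfg$tuned_fraction_by_number[num]
    domain <- ifelse(tuned,
                     sample(names(cfg$domain_mix), n, replace = TRUE,
                            prob = cfg$domain_mix),
                     "none")
    baseline <- cfg$baseline_scale_by_number[num] *
      stats::rlnorm(n, log(cfg$baseline_median_hz), cfg$baseline_sdlog)
    rows[[a]] <- data.frame(
      neuron_id = nid + seq_len(n),
      array_id = layout$array_id[a],
      array_number = num,
      hemisphere = layout$hemisphere[a],
      region = layout$region[a],
      domain = domain,
      pref_sign = sample(c(-1, 1), n, replace = TRUE),
      baseline_hz = baseline,
      # modulation depth scales with the neuron's own baseline (gain
      # modulation), keeping negative-rate clipping rare by construction
      modulation_hz = ifelse(
        tuned,
        baseline * cfg$modulation_gain *
          cfg$modulation_scale_by_number[num] *
          stats::rlnorm(n, 0, cfg$modulation_jitter_sdlog),
        0),
      onset_ms = cfg$onset_ms_by_number[num],
      stringsAsFactors = FALSE
    )
    nid <- nid + n
  }
  do.call(rbind, rows)
}

# AR(1) noise matrix (trials x bins) with stationary sd `sd` and per-bin
# autocorrelation `rho`.
ar1_noise <- function(n_trials, n_bins, sd, rho) {
  e <- matrix(stats::rnorm(n_trials * n_bins), n_trials, n_bins)
  if (n_bins == 0 || sd == 0) return(e * 0)
  out <- matrix(0, n_trials, n_bins)
  out[, 1] <- e[, 1]
  w <- sqrt(1 - rho^2)
  for (t in seq_len(n_bins)[-1]) out[, t] <- rho * out[, t - 1] + w * e[, t]
  out * sd
}

# Shift a trials x bins matrix right by `lag` bins (prepend zeros).
lag_shift <- function(m, lag) {
  if (lag == 0) return(m)
  cbind(matrix(0, nrow(m), lag), m[, seq_len(ncol(m) - lag), drop = FALSE])
}

# Trial-level signed signals per domain. Value signal is the agent's chosen
# option value rescaled to [-1, 1]; plan sign is the sign of the agent's
# value difference, used for pre-cue (hold period) encoding in the block's
# relevant domain.
trial_signals <- function(trials) {
  list(
    action = ifelse(trials$chosen_action == "left", 1, -1),
    object = ifelse(trials$chosen_object == "A", 1, -1),
    reward = ifelse(trials$reward == 1, 1, -1),
    value = 2 * trials$agent_v_chosen - 1,
    plan = sign(trials$agent_v1 - trials$agent_v2)
  )
}

#' Generate planted-structure spike counts for a behavioural session
#'
#' Builds, for every (array, domain), a latent information signal
#' `z(trial, t) = ramp(t - onset_array) * x_domain(trial) + hold + noise`,
#' where `x_domain` is the signed trial variable (chosen action/object sign,
#' reward sign, or rescaled chosen-option value), the hold component carries
#' the agent's value-difference sign before cue onset in the block-relevant
#' domain, and the noise is trial-wise AR(1). Directed coupling entries add a
#' lag-shifted, gain-scaled copy of the source array's stochastic latent
#' component to the target latent (same hemisphere), so decoded information
#' on the target is predictable from the source at the planted lag while the
#' target's deterministic onset latency stays exactly as planted (copying
#' the full latent would let targets inherit the source's earlier ramp and
#' distort the latency gradient). Each neuron then fires
#' as an inhomogeneous Poisson process with rate
#' `baseline + modulation * pref_sign * z` (negative rates clipped at 0 and
#' counted; a warning is issued if more than 1% of bins clip).
#'
#' @param layout [array_layout()] data.frame.
#' @param trials Behavioural trial table for the session (all blocks).
#' @param truth Per-neuron tuning table from the ground-truth plan.
#' @param cfg [session_config()] list.
#' @return List with `tensor` (a `spike_tensor` on the 10-ms base grid),
#'   `clip_fraction`, and (if `cfg$keep_latents`) `latents`, a named list
#'   `"<array_id>.<domain>"` of trials x bins latent matrices.
#' @export
generate_population <- function(layout, trials, truth, cfg) {
  n_trials <- nrow(trials)
  bw <- cfg$base_bin_ms
  starts_ms <- seq(cfg$window_s[1] * 1000, cfg$window_s[2] * 1000 - bw, by = bw)
  centers_ms <- starts_ms + bw / 2
  n_bins <- length(starts_ms)
  sig <- trial_signals(trials)
  relevant <- ifelse(trials$block_type == "What", "object", "action")
  hold_on <- as.numeric(centers_ms < 0 & centers_ms >= -500)

  # pre-coupling latents; the stochastic component is kept separately so
  # coupling can transfer it without duplicating the deterministic ramp
  latents <- list()
  noise <- list()
  for (a in seq_len(nrow(layout))) {
    onset <- cfg$onset_ms_by_number[layout$array_number[a]]
    ramp <- pmin(pmax((centers_ms - onset) / cfg$ramp_ms, 0), 1)
    for (dm in DOMAINS) {
      key <- paste0(layout$array_id[a], ".", dm)
      eta <- ar1_noise(n_trials, n_bins, cfg$latent_noise_sd,
                       cfg$latent_ar_rho)
      z <- outer(sig[[dm]], ramp) + eta
      if (cfg$hold_gain != 0) {
        plan <- cfg$hold_gain * sig$plan * (relevant == dm)
        z <- z + outer(plan, hold_on)
      }
      noise[[key]] <- eta
      latents[[key]] <- z
    }
  }
  # apply directed coupling (sources contribute their own stochastic latent)
  pre <- noise
  for (cp in cfg$coupling) {
    lag_base <- as.integer(cp$lag_bins * 20 / bw)
    rows <- rep(TRUE, n_trials)
    if (!is.null(cp$block_type)) rows <- rows & trials$block_type == cp$block_type
    if (!is.null(cp$trial_min)) rows <- rows & trials$trial_index_in_block >= cp$trial_min
    if (!is.null(cp$trial_max)) rows <- rows & trials$trial_index_in_block <= cp$trial_max
    for (h in unique(layout$hemisphere)) {
      src_id <- paste0(h, cp$src_number); tgt_id <- paste0(h, cp$tgt_number)
      src_key <- paste0(src_id, ".", cp$src_domain)
      tgt_key <- paste0(tgt_id, ".", cp$tgt_domain)
      if (is.null(pre[[src_key]]) || is.null(latents[[tgt_key]])) next
      add <- lag_shift(pre[[src_key]], lag_base) * cp$gain
      latents[[tgt_key]][rows, ] <-
        latents[[tgt_key]][rows, , drop = FALSE] + add[rows, , drop = FALSE]
    }
  }

  # Poisson counts per neuron
  n_neurons <- nrow(truth)
  counts <- array(0L, dim = c(n_trials, n_neurons, n_bins))
  dt <- bw / 1000
  n_clipped <- 0
  for (n in seq_len(n_neurons)) {
    rate <- truth$baseline_hz[n]
    if (truth$domain[n] != "none") {
      z <- latents[[paste0(truth$array_id[n], ".", truth$domain[n])]]
      rate <- rate + truth$modulation_hz[n] * truth$pref_sign[n] * z
    } else {
      rate <- matrix(rate, n_trials, n_bins)
    }
    n_clipped <- n_clipped + sum(rate < 0)
    lam <- pmax(rate, 0) * dt
    counts[, n, ] <- stats::rpois(length(lam), lam)
  }
  clip_fraction <- n_clipped / (n_trials * n_neurons * n_bins)
  if (clip_fraction > 0.01) {
    warning(sprintf("%.2f%% of rate bins were negative and clipped at 0",
                    100 * clip_fraction))
  }
  tensor <- new_spike_tensor(
    counts = counts, bin_width_ms = bw, step_ms = bw,
    window_s = cfg$window_s, bin_starts_s = starts_ms / 1000,
    neurons = truth[, c("neuron_id", "array_id", "array_number",
                        "hemisphere", "region")],
    trial_id = seq_len(n_trials))
  out <- list(tensor = tensor, clip_fraction = clip_fraction)
  if (isTRUE(cfg$keep_latents)) out$latents <- latents
  out
}

#' Generate a complete synthetic session
#'
#' Produces a full session bundle: a block-interleaved behavioural trial
#' table (default 24 blocks x 80 trials, What/Where randomly interleaved),
#' planted-structure spike counts on a 10-ms base grid for the full array
#' layout, and the ground truth of every planted effect. Deterministic given
#' `seed` (the caller's RNG state is restored on exit).
#'
#' @param config A [session_config()].
#' @param seed Integer seed.
#' @param session_id Session label stored in the trial table.
#' @return Object of class `lpfc_session`: list with `trials`, `spikes`
#'   (base-grid `spike_tensor`), `truth` (list: `neurons`, `coupling`,
#'   `agent`, `seed`, optional `latents`), `layout`, `config`, `seed`,
#'   `clip_fraction`, and optionally `spike_times`.
#' @export
generate_session <- function(config = session_config(), seed = 1L,
                             session_id = paste0("synth-", seed)) {
  if (!inherits(config, "session_config")) {
    stop("`config` must be built with session_config()")
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  n_each <- config$n_blocks %/% 2L
  types <- sample(c(rep("What", n_each),
                    rep("Where", config$n_blocks - n_each)))
  agent <- rw_params(config$agent$beta, config$agent$delta_pos,
                     config$agent$delta_neg)
  blocks <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    sched <- generate_task_block(types[b],
                                 n_trials = config$n_trials_per_block,
                                 reversal_range = config$reversal_range,
                                 p_better = config$p_better)
    blk <- simulate_agent(sched, agent, policy = config$agent_policy)
    blk$block_id <- b
    blocks[[b]] <- blk
  }
  trials <- do.call(rbind, blocks)
  trials$session_id <- session_id
  trials$trial_id <- seq_len(nrow(trials))

  truth_neurons <- plan_ground_truth(config$layout, config)
  pop <- generate_population(config$layout, trials, truth_neurons, config)

  out <- structure(list(
    trials = trials,
    spikes = pop$tensor,
    truth = c(list(neurons = truth_neurons, coupling = config$coupling,
                   agent = config$agent, seed = seed),
              if (!is.null(pop$latents)) list(latents = pop$latents)),
    layout = config$layout,
    config = config,
    seed = seed,
    clip_fraction = pop$clip_fraction
  ), class = "lpfc_session")
  if (isTRUE(config$return_spike_times)) {
    out$spike_times <- tensor_to_spike_times(pop$tensor)
  }
  out
}

#' @export
print.lpfc_session <- function(x, ...) {
  cat(sprintf(
    "Synthetic LPFC session '%s': %d blocks x %d trials, %d arrays, %d neurons\n",
    x$trials$session_id[1], length(unique(x$trials$block_id)),
    max(x$trials$trial_index_in_block), nrow(x$layout),
    nrow(x$truth$neurons)))
  invisible(x)
}

#' Simulate a network of coupled decoded-information time series
#'
#' Lightweight surrogate for calibrating and validating the information-flow
#' estimator without spiking data: each array carries a latent AR(1) series
#' per trial; directed coupling entries add a lag-shifted, gain-scaled copy
#' of the source array's pre-coupling latent to the target (same
#' hemisphere); series are mapped through the logistic function so they live
#' on the posterior-probability scale.
#'
#' @param n_trials,n_bins Trials and 20-ms bins per trial.
#' @param n_numbers,hemispheres Arrays to simulate (as in [array_layout()]).
#' @param coupling List of `list(src_number, tgt_number, lag_bins, gain)`.
#' @param ar_rho,noise_sd AR(1) parameters of the latent series.
#' @param seed Optional seed (caller RNG restored on exit).
#' @return Named list of trials x bins matrices in (0, 1), names = array ids.
#' @export
simulate_posterior_network <- function(n_trials = 40, n_bins = 100,
                                       n_numbers = 2,
                                       hemispheres = c("L", "R"),
                                       coupling = list(),
                                       ar_rho = 0.8, noise_sd = 1,
                                       seed = NULL) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  layout <- array_layout(n_numbers = n_numbers, hemispheres = hemispheres)
  lat <- lapply(seq_len(nrow(layout)), function(i)
    ar1_noise(n_trials, n_bins, noise_sd, ar_rho))
  names(lat) <- layout$array_id
  pre <- lat
  for (cp in coupling) {
    for (h in hemispheres) {
      src <- paste0(h, cp$src_number); tgt <- paste0(h, cp$tgt_number)
      if (is.null(pre[[src]]) || is.null(lat[[tgt]])) next
      lat[[tgt]] <- lat[[tgt]] + cp$gain * lag_shift(pre[[src]], cp$lag_bins)
    }
  }
  lapply(lat, stats::plogis)
}
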