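# Shared fixtures and independent brute-force oracles. Oracles are written
# as plain trial/fold/term loops so they share no code path with the
# vectorised implementations they check.

# --- Rescorla-Wagner likelihood oracle: scalar loop over one block ---------
rw_nll_oracle_block <- function(choice, reward, beta, dpos, dneg, v0 = 0.5,
                                floor = 1e-12) {
  v <- c(v0, v0)
  nll <- 0
  for (k in seq_along(choice)) {
    d1 <- 1 / (1 + exp(beta * (v[2] - v[1])))
    p <- if (choice[k] == 1) d1 else 1 - d1
    nll <- nll - log(max(p, floor))
    delta <- if (reward[k] == 1) dpos else dneg
    v[choice[k]] <- v[choice[k]] + delta * (reward[k] - v[choice[k]])
  }
  nll
}

rw_nll_oracle <- function(trials, beta, dpos, dneg, mapping, v0 = 0.5) {
  total <- 0
  for (b in split(trials, trials$block_id)) {
    b <- b[order(b$trial_index_in_block), ]
    choice <- if (mapping == "object") {
      ifelse(b$chosen_object == "A", 1L, 2L)
    } else {
      ifelse(b$chosen_action == "left", 1L, 2L)
    }
    total <- total + rw_nll_oracle_block(choice, b$reward, beta, dpos, dneg, v0)
  }
  total
}

# --- behavioural session fixture ------------------------------------------
make_agent_trials <- function(n_sessions = 1, n_blocks = 4,
                              params = rw_params(5, 0.6, 0.3),
                              policy = "rw", seed = 1,
                              block_types = NULL, n_trials = 80L) {
  set.seed(seed)
  out <- list()
  for (s in seq_len(n_sessions)) {
    types <- if (is.null(block_types)) {
      sample(rep(c("What", "Where"), length.out = n_blocks))
    } else rep(block_types, length.out = n_blocks)
    for (b in seq_len(n_blocks)) {
      blk <- simulate_agent(
        generate_task_block(types[b], n_trials = n_trials), params,
        policy = policy)
      blk$block_id <- (s - 1) * n_blocks + b
      blk$session_id <- paste0("S", s)
      out[[length(out) + 1L]] <- blk
    }
  }
  trials <- do.call(rbind, out)
  trials$trial_id <- seq_len(nrow(trials))
  trials
}

# --- leave-one-trial-out decoding oracle: explicit fold loop ---------------
loto_oracle <- function(tensor, labels) {
  labels <- factor(labels)
  n_trials <- dim(tensor$counts)[1]
  n_bins <- dim(tensor$counts)[3]
  p_true <- matrix(NA_real_, n_trials, n_bins)
  for (k in seq_len(n_trials)) {
    train <- setdiff(seq_len(n_trials), k)
    if (nlevels(droplevels(labels[train])) < 2) next
    for (b in seq_len(n_bins)) {
      Y <- tensor$counts[, , b, drop = FALSE]
      dim(Y) <- dim(tensor$counts)[1:2]
      tmpl <- class_templates(Y[train, , drop = FALSE], labels[train])
      p <- posterior_probability(Y[k, ], tmpl)
      p_true[k, b] <- p[as.character(labels[k])]
    }
  }
  p_true
}

# --- OLS oracle: explicit normal equations --------------------------------
ols_oracle <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# --- permutation p-value for the fVar of one dropped array number ----------
perm_fvar_p <- function(output, inputs, drop_number, output_id,
                        n_perm = 99) {
  obs <- flow_strength(
    fit_flow_model(output, inputs),
    fit_partial_model(output, inputs, drop_number, output_id = output_id))
  drop_ids <- names(inputs)[lpfcflow:::parse_array_number(names(inputs)) ==
                              drop_number]
  null <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    perm <- sample(nrow(output))
    ip <- inputs
    for (id in drop_ids) ip[[id]] <- ip[[id]][perm, , drop = FALSE]
    null[i] <- flow_strength(
      fit_flow_model(output, ip),
      fit_partial_model(output, ip, drop_number, output_id = output_id))
  }
  (1 + sum(null >= obs)) / (n_perm + 1)
}

# --- coupled posterior-series sessions for learning-trajectory tests -------
# Bilateral layout (L1, L2, R1, R2); coupling 2 -> 1 within hemisphere at
# `lag_bins`, active only on rows where `gate` is TRUE.
make_gated_session <- function(trials, gate, lag_bins = 3, gain = 1.5,
                               n_bins = 60, rho = 0.5) {
  n <- nrow(trials)
  ids <- c("L1", "L2", "R1", "R2")
  lat <- lapply(ids, function(i) lpfcflow:::ar1_noise(n, n_bins, 1, rho))
  names(lat) <- ids
  for (h in c("L", "R")) {
    shift <- lpfcflow:::lag_shift(lat[[paste0(h, "2")]], lag_bins) * gain
    tgt <- paste0(h, "1")
    lat[[tgt]][gate, ] <- lat[[tgt]][gate, , drop = FALSE] +
      shift[gate, , drop = FALSE]
  }
  posts <- lapply(lat, plogis)
  list(posteriors = list(action = posts), trials = trials)
}

# skeleton trial table (no neural data) for posterior-level flow tests
make_flow_trials <- function(n_blocks_per_type = 3, n_trials = 40,
                             session_id = "S1") {
  bt <- rep(c("What", "Where"), each = n_blocks_per_type)
  out <- do.call(rbind, lapply(seq_along(bt), function(b) {
    data.frame(session_id = session_id, block_id = b, block_type = bt[b],
               trial_index_in_block = seq_len(n_trials))
  }))
  out
}
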