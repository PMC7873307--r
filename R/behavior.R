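# Rescorla-Wagner behavioural model with asymmetric learning rates:
# value update, logistic choice rule, likelihood, bounded multi-start MLE,
# and reversal-aligned choice summaries.

#' Rescorla-Wagner parameter set
#'
#' Container for the three free parameters of the asymmetric-learning-rate
#' Rescorla-Wagner model: inverse temperature `beta` and the two
#' outcome-dependent learning rates `delta_pos` (applied after rewarded
#' choices) and `delta_neg` (after unrewarded choices).
#'
#' @param beta Inverse temperature, `beta >= 0`.
#' @param delta_pos Learning rate after reward, in `[0, 1]`.
#' @param delta_neg Learning rate after non-reward, in `[0, 1]`.
#' @param block_type Optional block-type label ("What" or "Where") the
#'   parameter set belongs to; models are fit separately per block type.
#' @return An object of class `rw_params` (a named list).
#' @export
rw_params <- function(beta, delta_pos, delta_neg, block_type = NA_character_) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta), beta >= 0)
  for (d in c(delta_pos, delta_neg)) {
    stopifnot(is.numeric(d), length(d) == 1L, is.finite(d), d >= 0, d <= 1)
  }
  structure(
    list(beta = beta, delta_pos = delta_pos, delta_neg = delta_neg,
         block_type = block_type),
    class = "rw_params"
  )
}

#' @export
print.rw_params <- function(x, ...) {
  cat(sprintf(
    "Rescorla-Wagner parameters%s: beta = %.4g, delta_pos = %.4g, delta_neg = %.4g\n",
    if (is.na(x$block_type)) "" else paste0(" [", x$block_type, "]"),
    x$beta, x$delta_pos, x$delta_neg))
  invisible(x)
}

#' Single Rescorla-Wagner value update
#'
#' Updates the chosen option's value by `v + delta_f * (R - v)`, where
#' `delta_f` is `delta_pos` if the trial was rewarded (`R = 1`) and
#' `delta_neg` otherwise. Unchosen options are left unchanged.
#'
#' @param v Numeric vector of current option values.
#' @param chosen Index of the chosen option (1-based).
#' @param reward Outcome, exactly 0 or 1.
#' @param params An [rw_params()] object (only the learning rates are used).
#' @return Numeric vector of updated values, same length as `v`.
#' @export
update_values <- function(v, chosen, reward, params) {
  stopifnot(is.numeric(v), all(is.finite(v)))
  if (!(length(reward) == 1L && reward %in% c(0, 1))) {
    stop("`reward` must be exactly 0 or 1")
  }
  stopifnot(chosen >= 1L, chosen <= length(v))
  delta <- if (reward == 1) params$delta_pos else params$delta_neg
  v[chosen] <- v[chosen] + delta * (reward - v[chosen])
  v
}

#' Logistic choice probabilities from two option values
#'
#' `d1 = 1 / (1 + exp(beta * (v2 - v1)))`, `d2 = 1 - d1`. Computed through
#' `plogis()` so large `|beta * (v1 - v2)|` cannot overflow.
#'
#' @param v Numeric vector of length 2, option values `(v1, v2)`.
#' @param beta Inverse temperature, `beta >= 0`.
#' @return Named numeric vector `c(d1, d2)`; the two entries sum to 1.
#' @export
choice_probability <- function(v, beta) {
  stopifnot(length(v) == 2L, is.numeric(v), all(is.finite(v)),
            is.numeric(beta), length(beta) == 1L, beta >= 0)
  d1 <- stats::plogis(beta * (v[1] - v[2]))
  c(d1 = d1, d2 = 1 - d1)
}

# Trial-by-trial value/choice-probability recursion, vectorised across blocks.
# choice, reward: K x B matrices (K trials per block, B blocks); choice is
# 1 or 2 (index of the chosen option). Returns K x B matrices of pre-choice
# values and choice probabilities, plus the log-likelihood.
rw_recursion <- function(choice, reward, beta, delta_pos, delta_neg,
                         v0 = 0.5, prob_floor = 1e-12, trace = TRUE) {
  stopifnot(is.matrix(choice), is.matrix(reward),
            all(dim(choice) == dim(reward)))
  if (!all(reward %in% c(0, 1))) stop("rewards must be 0 or 1")
  if (!all(choice %in% c(1L, 2L))) stop("choices must be 1 or 2")
  K <- nrow(choice); B <- ncol(choice)
  delta_all <- delta_pos * reward + delta_neg * (1 - reward)
  chose1 <- choice == 1L
  d1 <- matrix(NA_real_, K, B)
  if (trace) {
    v1 <- matrix(NA_real_, K, B); v2 <- matrix(NA_real_, K, B)
  }
  cv1 <- rep(v0, B); cv2 <- rep(v0, B)
  for (k in seq_len(K)) {
    if (trace) { v1[k, ] <- cv1; v2[k, ] <- cv2 }
    d1[k, ] <- stats::plogis(beta * (cv1 - cv2))
    m <- chose1[k, ]
    r <- reward[k, ]
    delta <- delta_all[k, ]
    cv1 <- cv1 + (delta * (r - cv1)) * m
    cv2 <- cv2 + (delta * (r - cv2)) * (1 - m)
  }
  p_choice <- d1
  p_choice[!chose1] <- 1 - d1[!chose1]
  ll <- sum(log(pmax(p_choice, prob_floor)))
  if (!trace) return(list(log_likelihood = ll))
  list(v1 = v1, v2 = v2, d1 = d1, d2 = 1 - d1,
       p_choice = p_choice, log_likelihood = ll)
}

# Map a trial-table slice (one block type) onto option codes 1/2.
# In What blocks options are the two objects (1 = "A"); in Where blocks the
# two actions (1 = "left").
option_codes <- function(trials, option_mapping = c("object", "action")) {
  option_mapping <- match.arg(option_mapping)
  if (option_mapping == "object") {
    ifelse(trials$chosen_object == "A", 1L, 2L)
  } else {
    ifelse(trials$chosen_action == "left", 1L, 2L)
  }
}

# Stack a block-structured trial table into K x B choice/reward matrices.
# All blocks must have equal length (the task has 80 trials/block).
stack_blocks <- function(trials, option_mapping) {
  blocks <- split(trials, trials$block_id)
  lens <- vapply(blocks, nrow, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("blocks have unequal trial counts; cannot stack")
  }
  blocks <- lapply(blocks, function(b) b[order(b$trial_index_in_block), ])
  choice <- vapply(blocks, option_codes, integer(lens[1]),
                   option_mapping = option_mapping)
  reward <- vapply(blocks, function(b) as.integer(b$reward), integer(lens[1]))
  list(choice = matrix(choice, nrow = lens[1]),
       reward = matrix(reward, nrow = lens[1]),
       block_id = names(blocks))
}

#' Negative log-likelihood of choices under the Rescorla-Wagner model
#'
#' Evaluates `-log prod_k [d1(k) c1(k) + d2(k) c2(k)]` over a slice of the
#' trial table, updating values trial-by-trial within each block (values are
#' reset to `v0` at every block start; blocks use novel options). Options are
#' the two objects in What blocks and the two actions in Where blocks, chosen
#' through `option_mapping`.
#'
#' @param trials Trial-table slice (see [generate_session()]), typically all
#'   blocks of one type, ordered by trial index within block.
#' @param params An [rw_params()] object.
#' @param option_mapping `"object"` or `"action"`: what the two options are.
#' @param v0 Initial value of both options at each block start.
#' @param prob_floor Probability floor applied inside the log.
#' @return List with `nll` (scalar) and `trace`, a data.frame with per-trial
#'   `v1`, `v2`, `d1`, `d2`, `p_choice` and `v_chosen` (the pre-choice value
#'   of the chosen option, the default ANOVA value covariate).
#' @export
negative_log_likelihood <- function(trials, params,
                                    option_mapping = c("object", "action"),
                                    v0 = 0.5, prob_floor = 1e-12) {
  option_mapping <- match.arg(option_mapping)
  if (is.null(trials) || nrow(trials) == 0L) stop("empty trial table")
  st <- stack_blocks(trials, option_mapping)
  rec <- rw_recursion(st$choice, st$reward, params$beta, params$delta_pos,
                      params$delta_neg, v0 = v0, prob_floor = prob_floor)
  K <- nrow(st$choice); B <- ncol(st$choice)
  trace <- data.frame(
    block_id = rep(st$block_id, each = K),
    trial_index_in_block = rep(seq_len(K), times = B),
    v1 = as.vector(rec$v1), v2 = as.vector(rec$v2),
    d1 = as.vector(rec$d1), d2 = as.vector(rec$d2),
    p_choice = as.vector(rec$p_choice),
    v_chosen = as.vector(ifelse(st$choice == 1L, rec$v1, rec$v2)),
    stringsAsFactors = FALSE
  )
  list(nll = -rec$log_likelihood, trace = trace)
}

#' Fit the Rescorla-Wagner model by bounded multi-start maximum likelihood
#'
#' Fits `(beta, delta_pos, delta_neg)` separately per block type by
#' minimising the negative log-likelihood with `optim(method = "L-BFGS-B")`
#' from `n_starts` random initial points (plus one central start). In What
#' blocks the options are the two objects; in Where blocks the two actions.
#'
#' @param trials Full trial table (both block types allowed).
#' @param n_starts Number of random multi-starts per block type.
#' @param bounds List with `beta = c(lo, hi)` and `delta = c(lo, hi)`.
#' @param seed Integer seed for the start points (fit is deterministic given
#'   the seed).
#' @param v0 Initial option value at block start.
#' @return Object of class `rw_fit`: a list with one element per block type,
#'   each containing `params` ([rw_params()]), `nll`, `converged` (TRUE if
#'   any start converged), `n_starts`, and `trace` (per-trial value trace of
#'   the best fit). A fit where no start converged is flagged with
#'   `converged = FALSE` and a warning, never dropped silently.
#' @export
fit_rw_model <- function(trials, n_starts = 10,
                         bounds = list(beta = c(0, 50), delta = c(0, 1)),
                         seed = 1L, v0 = 0.5) {
  stopifnot(nrow(trials) > 0L)
  block_types <- sort(unique(as.character(trials$block_type)))
  fits <- list()
  for (bt in block_types) {
    sub <- trials[trials$block_type == bt, ]
    mapping <- if (bt == "What") "object" else "action"
    # stack once; the optimizer only re-runs the value recursion
    st <- stack_blocks(sub, mapping)
    nll_fun <- function(par) {
      -rw_recursion(st$choice, st$reward, par[1], par[2], par[3],
                    v0 = v0, trace = FALSE)$log_likelihood
    }
    lower <- c(bounds$beta[1], bounds$delta[1], bounds$delta[1])
    upper <- c(bounds$beta[2], bounds$delta[2], bounds$delta[2])
    # reproducible start points: one central + n_starts - 1 random
    starts <- local({
      rng_state <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(rng_state)) assign(".Random.seed", rng_state,
                                              envir = globalenv()))
      set.seed(seed)
      rand <- matrix(stats::runif(3 * max(n_starts - 1L, 0L)), ncol = 3)
      rand <- sweep(sweep(rand, 2, upper - lower, "*"), 2, lower, "+")
      rbind(c(5, 0.5, 0.5), rand)
    })
    best <- NULL; any_converged <- FALSE
    for (i in seq_len(nrow(starts))) {
      res <- tryCatch(
        stats::optim(starts[i, ], nll_fun, method = "L-BFGS-B",
                     lower = lower, upper = upper),
        error = function(e) NULL)
      if (is.null(res)) next
      if (res$convergence == 0) any_converged <- TRUE
      if (is.null(best) || res$value < best$value) best <- res
    }
    if (is.null(best)) stop("all optimizer starts failed for block type ", bt)
    if (!any_converged) {
      warning("no optimizer start converged for block type ", bt,
              "; returning best non-converged fit (flagged)")
    }
    params <- rw_params(best$par[1], best$par[2], best$par[3], bt)
    ev <- negative_log_likelihood(sub, params, option_mapping = mapping,
                                  v0 = v0)
    fits[[bt]] <- list(params = params, nll = ev$nll,
                       converged = any_converged, n_starts = nrow(starts),
                       trace = ev$trace)
  }
  structure(fits, class = "rw_fit")
}

#' @export
print.rw_fit <- function(x, ...) {
  cat("Rescorla-Wagner fit (bounded multi-start MLE)\n")
  for (bt in names(x)) {
    f <- x[[bt]]
    cat(sprintf(
      "  %-6s beta = %6.3f  delta_pos = %.3f  delta_neg = %.3f  NLL = %.2f%s\n",
      bt, f$params$beta, f$params$delta_pos, f$params$delta_neg, f$nll,
      if (f$converged) "" else "  [NOT CONVERGED]"))
  }
  invisible(x)
}

# Per-trial fitted value covariate (chosen-option value) for a full trial
# table, using the per-block-type fits. Returned in the row order of `trials`.
#' Fitted chosen-option value per trial
#'
#' Convenience extractor: evaluates the fitted model of each block type on
#' its trials and returns the pre-choice value of the chosen option aligned
#' to the rows of `trials`. Used as the "value" covariate of the encoding
#' ANOVA.
#'
#' @param fit An `rw_fit` object from [fit_rw_model()].
#' @param trials The trial table the fit was computed from.
#' @return Numeric vector, one value per row of `trials`.
#' @export
fitted_value_trace <- function(fit, trials) {
  out <- rep(NA_real_, nrow(trials))
  for (bt in names(fit)) {
    idx <- which(trials$block_type == bt)
    tr <- fit[[bt]]$trace
    key_fit <- paste(tr$block_id, tr$trial_index_in_block)
    key_dat <- paste(trials$block_id[idx], trials$trial_index_in_block[idx])
    out[idx] <- tr$v_chosen[match(key_dat, key_fit)]
  }
  out
}

#' Reversal-aligned choice curve
#'
#' Fraction of choices of the initially better option, indexed by trial
#' relative to the block's reversal trial (0 = first trial under the flipped
#' mapping), averaged across blocks within session and then across sessions;
#' SEM across sessions. Aligned positions covered by fewer than
#' `min_blocks` blocks within a session are missing for that session.
#'
#' @param trials Trial table with `session_id`, `block_id`, `reversal_trial`,
#'   `better_initial`, `chosen_object`, `chosen_action`, `block_type`.
#' @param min_blocks Minimum blocks covering an aligned position within a
#'   session for it to contribute.
#' @return data.frame with `aligned_trial`, `mean`, `sem`, `n_sessions`.
#' @export
reversal_aligned_choice_curve <- function(trials, min_blocks = 2L) {
  stopifnot(all(c("reversal_trial", "better_initial") %in% names(trials)))
  chosen <- ifelse(trials$block_type == "What",
                   trials$chosen_object, trials$chosen_action)
  chose_initial <- as.numeric(chosen == trials$better_initial)
  aligned <- trials$trial_index_in_block - trials$reversal_trial
  sess <- as.character(trials$session_id)
  # per-session mean over blocks at each aligned index
  per_sess <- tapply(chose_initial, list(aligned, sess), mean)
  cover <- tapply(trials$block_id, list(aligned, sess),
                  function(b) length(unique(b)))
  per_sess[is.na(cover) | cover < min_blocks] <- NA_real_
  n_sessions <- rowSums(!is.na(per_sess))
  m <- rowMeans(per_sess, na.rm = TRUE)
  s <- apply(per_sess, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) NA_real_ else stats::sd(x) / sqrt(length(x))
  })
  m[n_sessions == 0] <- NA_real_
  data.frame(aligned_trial = as.integer(rownames(per_sess)),
             mean = unname(m), sem = unname(s),
             n_sessions = unname(n_sessions))
}
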