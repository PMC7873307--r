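# Granger-style information-flow analysis: the chosen-option posterior of an
# output array at time t is regressed on its own lagged posterior (lags 1:10)
# and the current-plus-lagged posteriors (lags 0:10) of the other arrays.
# Dropping an array number (bilaterally, averaging the two single-hemisphere
# drops) gives the Partial model; the normalised drop in variance explained
# (fVar) is the flow strength attributed to the dropped array. Lags never
# cross trial boundaries: within each trial the first max(lag) bins serve
# only as predictors.

parse_array_number <- function(ids) as.integer(sub("^[LR]", "", ids))
parse_hemisphere <- function(ids) substr(ids, 1, 1)

# Pooled lagged design over trials. output: trials x bins matrix; inputs:
# named list of trials x bins matrices (same dims). Observation order:
# trial-major within each predicted bin column.
flow_design <- function(output, inputs, self_lags = 1:10, cross_lags = 0:10) {
  stopifnot(is.matrix(output))
  B <- ncol(output)
  max_lag <- max(c(self_lags, cross_lags))
  if (B <= max_lag) stop("fewer bins than the maximum lag")
  t_idx <- (max_lag + 1):B
  lag_block <- function(m, lags, prefix) {
    cols <- lapply(lags, function(l) as.vector(m[, t_idx - l, drop = FALSE]))
    out <- do.call(cbind, cols)
    colnames(out) <- paste0(prefix, "_lag", lags)
    out
  }
  X <- cbind(`(Intercept)` = 1,
             lag_block(output, self_lags, "self"))
  for (nm in names(inputs)) {
    stopifnot(all(dim(inputs[[nm]]) == dim(output)))
    X <- cbind(X, lag_block(inputs[[nm]], cross_lags, nm))
  }
  list(y = as.vector(output[, t_idx, drop = FALSE]), X = X,
       n_trials = nrow(output), bins_used = t_idx)
}

#' Fit the full information-flow regression for one output array
#'
#' Ordinary least squares of the output array's chosen-option posterior at
#' time t on its own lags (`self_lags`, default 1..10 bins of 20 ms) and on
#' the current and lagged posteriors of every input array (`cross_lags`,
#' default 0..10; set `1:10` for the strictly-lagged variant). Observations
#' are pooled over trials; lags never cross trial boundaries. Rank-deficient
#' designs are resolved by pivoted least squares (aliased coefficients set
#' to 0) with a warning.
#'
#' @param output Trials x bins matrix of the output array's chosen-option
#'   posterior (from [loto_decode()] `p_true`).
#' @param inputs Named list of trials x bins posterior matrices of the other
#'   arrays (names are array ids such as "L3"; the output array itself must
#'   not be among them). For cross-domain flow these series are of the other
#'   domain.
#' @param self_lags,cross_lags Integer lag vectors (in bins).
#' @return Object of class `flow_fit`: `coefficients` (named),
#'   `variance_explained` (1 - SSE/SStot, in-sample), `fitted` (trials x
#'   predicted-bins matrix), `observed` (same shape), `bins_used`,
#'   `kernels` (data.frame `input`, `lag`, `coef`), `self_lags`,
#'   `cross_lags`, `inputs` (ids).
#' @export
fit_flow_model <- function(output, inputs, self_lags = 1:10,
                           cross_lags = 0:10) {
  des <- flow_design(output, inputs, self_lags, cross_lags)
  qx <- qr(des$X)
  if (qx$rank < ncol(des$X)) {
    warning("rank-deficient flow design; aliased coefficients set to 0 ",
            "(pivoted least squares)")
  }
  beta <- qr.coef(qx, des$y)
  beta[is.na(beta)] <- 0
  fitted <- qr.fitted(qx, des$y)
  sse <- sum((des$y - fitted)^2)
  sstot <- sum((des$y - mean(des$y))^2)
  n_used <- length(des$bins_used)
  kern <- data.frame(
    input = c(rep("self", length(self_lags)),
              rep(names(inputs), each = length(cross_lags))),
    lag = c(self_lags, rep(cross_lags, times = length(inputs))),
    coef = unname(beta[-1]),
    stringsAsFactors = FALSE)
  structure(list(
    coefficients = beta,
    variance_explained = 1 - sse / sstot,
    fitted = matrix(fitted, des$n_trials, n_used),
    observed = matrix(des$y, des$n_trials, n_used),
    bins_used = des$bins_used,
    kernels = kern,
    self_lags = self_lags, cross_lags = cross_lags,
    inputs = names(inputs)
  ), class = "flow_fit")
}

#' @export
print.flow_fit <- function(x, ...) {
  cat(sprintf(
    "flow_fit: %d inputs, self lags %d..%d, cross lags %d..%d, R^2 = %.3f\n",
    length(x$inputs), min(x$self_lags), max(x$self_lags),
    min(x$cross_lags), max(x$cross_lags), x$variance_explained))
  invisible(x)
}

#' Fit the partial (array-dropped) information-flow model
#'
#' Refits the flow regression excluding the left-hemisphere instance of the
#' dropped array number, then excluding the right-hemisphere instance, and
#' averages the two predicted series and the two variance-explained values
#' (`mode = "average"`, the bilateral-drop convention). `mode = "both"`
#' drops both instances simultaneously in a single refit. Layouts with only
#' one instance of the number fall back to that single drop.
#'
#' @inheritParams fit_flow_model
#' @param drop_number Array number (1..4) to drop from the inputs.
#' @param output_id Optional output array id; if given, dropping the
#'   output's own number is rejected.
#' @param mode Bilateral-drop convention (see above).
#' @return Object of class `flow_partial`: `variance_explained` (averaged),
#'   `fitted` (averaged prediction matrix), `fits` (the per-hemisphere
#'   refits), `dropped_ids`, `drop_number`.
#' @export
fit_partial_model <- function(output, inputs, drop_number, output_id = NULL,
                              mode = c("average", "both"),
                              self_lags = 1:10, cross_lags = 0:10) {
  mode <- match.arg(mode)
  if (!is.null(output_id) &&
      parse_array_number(output_id) == drop_number) {
    stop("cannot drop the output array's own number (", drop_number, ")")
  }
  drop_ids <- names(inputs)[parse_array_number(names(inputs)) == drop_number]
  if (length(drop_ids) == 0) stop("no input array has number ", drop_number)
  drop_sets <- if (mode == "both") list(drop_ids) else as.list(drop_ids)
  fits <- lapply(drop_sets, function(ids) {
    rest <- inputs[setdiff(names(inputs), ids)]
    if (length(rest) == 0) stop("dropping leaves no input arrays")
    fit_flow_model(output, rest, self_lags, cross_lags)
  })
  ve <- mean(vapply(fits, `[[`, numeric(1), "variance_explained"))
  fitted <- Reduce(`+`, lapply(fits, `[[`, "fitted")) / length(fits)
  structure(list(variance_explained = ve, fitted = fitted, fits = fits,
                 dropped_ids = drop_ids, drop_number = drop_number),
            class = "flow_partial")
}

#' Per-bin prediction difference between full and partial models
#'
#' Mean over trials, per predicted bin, of (full prediction - partial
#' prediction); the time course of the dropped array's contribution.
#'
#' @param full A `flow_fit`.
#' @param partial A `flow_partial` (or `flow_fit`) on the same trials/bins.
#' @param bin_centers_s Optional bin centers of the posterior grid; if given,
#'   the output carries the centers of the predicted bins.
#' @return data.frame `bin` (index into the posterior grid), optional
#'   `bin_center_s`, and `delta`.
#' @export
delta_posterior <- function(full, partial, bin_centers_s = NULL) {
  stopifnot(all(dim(full$fitted) == dim(partial$fitted)))
  delta <- colMeans(full$fitted - partial$fitted)
  out <- data.frame(bin = full$bins_used, delta = delta)
  if (!is.null(bin_centers_s)) out$bin_center_s <- bin_centers_s[full$bins_used]
  out
}

#' Flow strength fVar of a dropped array
#'
#' `fVar = (Var_full - Var_partial) / Var_full`, the drop in variance
#' explained caused by removing the array, normalised by the full model's
#' variance explained. Because each partial refit is nested in the full
#' model, in-sample fVar is non-negative.
#'
#' @param full `flow_fit` (or its variance explained).
#' @param partial `flow_partial` (or its variance explained).
#' @return Scalar fVar; `NA` with a warning when `Var_full <= 0`.
#' @export
flow_strength <- function(full, partial) {
  vf <- if (is.list(full)) full$variance_explained else full
  vp <- if (is.list(partial)) partial$variance_explained else partial
  if (!is.finite(vf) || vf <= 0) {
    warning("full-model variance explained is not positive; fVar undefined")
    return(NA_real_)
  }
  (vf - vp) / vf
}

#' Session-level information-flow sweep
#'
#' Fits, for every block type, output array, domain pair and dropped array
#' number, the full and bilateral-partial flow models, and tabulates fVar.
#' This is the per-session unit the group summaries (ordinal distance,
#' cross-domain contrasts, learning trajectories) are built from.
#'
#' @param posteriors Nested list: `posteriors[[domain]][[array_id]]` is the
#'   trials x bins chosen-option posterior matrix of that array (all arrays
#'   on a common 20-ms grid, rows aligned with `trials`).
#' @param trials Trial table aligned with the posterior rows (needs
#'   `block_type`; `trial_index_in_block` if `trial_subset` is used).
#' @param session_id Session label for the output rows.
#' @param domain_pairs data.frame with columns `out_domain`, `in_domain`
#'   (default: within-domain action/object plus both cross-domain pairs).
#' @param outputs Output array ids (default: all arrays of the first
#'   domain).
#' @param drop_numbers Array numbers to drop (default: all numbers present
#'   except, per output, its own).
#' @param block_types Block types to analyse.
#' @param trial_subset Optional logical vector over trials (applied before
#'   the block-type split), e.g. a learning window.
#' @param min_trials Minimum trials per fit.
#' @param self_lags,cross_lags Lag ranges (see [fit_flow_model()]).
#' @param mode Bilateral-drop convention of [fit_partial_model()].
#' @return data.frame of class `flow_summary`: `session_id`, `block_type`,
#'   `out_domain`, `in_domain`, `output_array`, `out_number`,
#'   `out_hemisphere`, `in_number` (dropped), `distance`
#'   (`in_number - out_number`; positive = caudal-to-rostral),
#'   `var_full`, `var_partial`, `fvar`.
#' @export
flow_session <- function(posteriors, trials,
                         session_id = trials$session_id[1],
                         domain_pairs = NULL, outputs = NULL,
                         drop_numbers = NULL,
                         block_types = unique(trials$block_type),
                         trial_subset = NULL, min_trials = 30L,
                         self_lags = 1:10, cross_lags = 0:10,
                         mode = "average") {
  domains <- names(posteriors)
  if (is.null(domain_pairs)) {
    within <- intersect(c("action", "object"), domains)
    domain_pairs <- expand.grid(out_domain = within, in_domain = within,
                                stringsAsFactors = FALSE)
  }
  ids <- names(posteriors[[1]])
  if (is.null(outputs)) outputs <- ids
  numbers <- sort(unique(parse_array_number(ids)))
  rows <- list(); ri <- 0L
  for (bt in block_types) {
    sel <- trials$block_type == bt
    if (!is.null(trial_subset)) sel <- sel & trial_subset
    if (sum(sel) < min_trials) next
    for (dp in seq_len(nrow(domain_pairs))) {
      odm <- domain_pairs$out_domain[dp]; idm <- domain_pairs$in_domain[dp]
      for (out_id in outputs) {
        out_mat <- posteriors[[odm]][[out_id]][sel, , drop = FALSE]
        in_ids <- setdiff(ids, out_id)
        in_list <- lapply(posteriors[[idm]][in_ids],
                          function(m) m[sel, , drop = FALSE])
        full <- fit_flow_model(out_mat, in_list, self_lags, cross_lags)
        out_num <- parse_array_number(out_id)
        drops <- if (is.null(drop_numbers)) setdiff(numbers, out_num) else
          setdiff(drop_numbers, out_num)
        for (dn in drops) {
          part <- fit_partial_model(out_mat, in_list, dn,
                                    output_id = out_id, mode = mode,
                                    self_lags = self_lags,
                                    cross_lags = cross_lags)
          ri <- ri + 1L
          rows[[ri]] <- data.frame(
            session_id = session_id, block_type = bt,
            out_domain = odm, in_domain = idm,
            output_array = out_id, out_number = out_num,
            out_hemisphere = parse_hemisphere(out_id),
            in_number = dn, distance = dn - out_num,
            var_full = full$variance_explained,
            var_partial = part$variance_explained,
            fvar = flow_strength(full, part),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("flow_summary", "data.frame")
  out
}

#' Mean flow strength by signed ordinal distance
#'
#' Groups flow summaries by the signed ordinal distance between the dropped
#' (input) and output array numbers — positive distances label
#' caudal-to-rostral flow (the input sits caudal/ventral of the output) —
#' and by domain pair, returning mean and SEM of fVar across rows (sessions
#' x block types x hemispheres x pairs).
#'
#' @param flow_df A `flow_summary` (rows may span several sessions).
#' @param by Extra grouping columns (e.g. "block_type").
#' @return data.frame `distance`, `out_domain`, `in_domain`, extra groups,
#'   `mean_fvar`, `sem_fvar`, `n`.
#' @export
ordinal_distance_summary <- function(flow_df, by = character()) {
  keys <- c("distance", "out_domain", "in_domain", by)
  grp <- interaction(flow_df[keys], drop = TRUE, sep = "\r")
  agg <- function(f) tapply(flow_df$fvar, grp, f)
  m <- agg(mean)
  s <- agg(function(x) if (length(x) < 2) NA_real_ else
    stats::sd(x) / sqrt(length(x)))
  n <- agg(length)
  key_mat <- do.call(rbind, strsplit(names(m), "\r", fixed = TRUE))
  out <- data.frame(key_mat, stringsAsFactors = FALSE)
  names(out) <- keys
  out$distance <- as.integer(out$distance)
  out$mean_fvar <- unname(m); out$sem_fvar <- unname(s); out$n <- unname(as.integer(n))
  out[order(out$out_domain, out$in_domain, out$distance), ]
}

#' Cross-domain information flow
#'
#' Convenience wrapper around [flow_session()] for fits whose output domain
#' differs from the input domain (predicting action information from object
#' information or vice versa). `cross_lags = 1:10` gives the strictly-lagged
#' robustness variant.
#'
#' @inheritParams flow_session
#' @param direction `"object_to_action"` (output = action, inputs = object)
#'   or `"action_to_object"`.
#' @return A `flow_summary` (see [flow_session()]).
#' @export
cross_domain_flow <- function(posteriors, trials,
                              direction = c("object_to_action",
                                            "action_to_object"),
                              session_id = trials$session_id[1],
                              block_types = unique(trials$block_type),
                              outputs = NULL, drop_numbers = NULL,
                              self_lags = 1:10, cross_lags = 0:10,
                              min_trials = 30L, mode = "average") {
  direction <- match.arg(direction)
  dp <- if (direction == "object_to_action") {
    data.frame(out_domain = "action", in_domain = "object",
               stringsAsFactors = FALSE)
  } else {
    data.frame(out_domain = "object", in_domain = "action",
               stringsAsFactors = FALSE)
  }
  flow_session(posteriors, trials, session_id = session_id,
               domain_pairs = dp, outputs = outputs,
               drop_numbers = drop_numbers, block_types = block_types,
               self_lags = self_lags, cross_lags = cross_lags,
               min_trials = min_trials, mode = mode)
}

#' Flow contrast between the caudal-dorsal (3) and ventral (4) arrays
#'
#' Compares fVar for flow 4 -> 3 (ventral to caudal-dorsal: output number 3,
#' dropped input number 4) against flow 3 -> 4, per domain pair and block
#' type, across the rows of a flow summary.
#'
#' @param flow_df A `flow_summary`.
#' @return data.frame with means per direction and their difference, grouped
#'   by `out_domain`, `in_domain`, `block_type`.
#' @export
vl_cdl_contrast <- function(flow_df) {
  sub <- flow_df[(flow_df$out_number == 3 & flow_df$in_number == 4) |
                   (flow_df$out_number == 4 & flow_df$in_number == 3), ]
  sub$direction <- ifelse(sub$in_number == 4, "4_to_3", "3_to_4")
  agg <- stats::aggregate(fvar ~ direction + out_domain + in_domain + block_type,
                          data = sub, FUN = mean)
  wide <- stats::reshape(agg, idvar = c("out_domain", "in_domain", "block_type"),
                         timevar = "direction", direction = "wide")
  names(wide) <- sub("^fvar\\.", "fvar_", names(wide))
  wide$diff_4to3_minus_3to4 <- wide$fvar_4_to_3 - wide$fvar_3_to_4
  rownames(wide) <- NULL
  wide
}

#' Information flow across learning: sliding trial-window comparison
#'
#' Slides a window over the within-block trial index (bin = `window` trials,
#' step = `step` trial), computes mean fVar per session and block type inside
#' each window, and tests What vs Where across sessions with a two-sided
#' paired t-test, yielding a p-value per window.
#'
#' @param sessions List of sessions, each a list with `posteriors` (as in
#'   [flow_session()]) and `trials`.
#' @param window,step Trial-window length and step.
#' @param domain_pairs,outputs,drop_numbers,self_lags,cross_lags,min_trials,mode
#'   Passed to [flow_session()].
#' @return data.frame `window_start`, `window_end`, `mean_What`,
#'   `mean_Where`, `p` (NA where a window lacks enough trials or sessions).
#' @export
learning_trajectory_flow <- function(sessions, window = 10L, step = 1L,
                                     domain_pairs = NULL, outputs = NULL,
                                     drop_numbers = NULL,
                                     self_lags = 1:10, cross_lags = 0:10,
                                     min_trials = 10L, mode = "average") {
  if (length(sessions) < 2) stop("needs >= 2 sessions for the paired test")
  max_idx <- max(vapply(sessions,
                        function(s) max(s$trials$trial_index_in_block),
                        numeric(1)))
  starts <- seq(1L, max_idx - window + 1L, by = step)
  out <- vector("list", length(starts))
  for (w in seq_along(starts)) {
    lo <- starts[w]; hi <- lo + window - 1L
    per_sess <- vapply(sessions, function(s) {
      sel <- s$trials$trial_index_in_block >= lo &
        s$trials$trial_index_in_block <= hi
      fs <- tryCatch(
        flow_session(s$posteriors, s$trials, domain_pairs = domain_pairs,
                     outputs = outputs, drop_numbers = drop_numbers,
                     block_types = c("What", "Where"), trial_subset = sel,
                     min_trials = min_trials, self_lags = self_lags,
                     cross_lags = cross_lags, mode = mode),
        error = function(e) NULL)
      if (is.null(fs)) return(c(NA_real_, NA_real_))
      c(mean(fs$fvar[fs$block_type == "What"]),
        mean(fs$fvar[fs$block_type == "Where"]))
    }, numeric(2))
    what <- per_sess[1, ]; where <- per_sess[2, ]
    ok <- is.finite(what) & is.finite(where)
    p <- if (sum(ok) >= 2 && stats::sd(what[ok] - where[ok]) > 0) {
      stats::t.test(what[ok], where[ok], paired = TRUE)$p.value
    } else NA_real_
    out[[w]] <- data.frame(window_start = lo, window_end = hi,
                           mean_What = mean(what, na.rm = TRUE),
                           mean_Where = mean(where, na.rm = TRUE),
                           p = p)
  }
  do.call(rbind, out)
}
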