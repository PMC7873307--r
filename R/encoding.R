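# Per-neuron sliding-window fixed-effect ANOVA of task factors (chosen
# object, chosen action, reward, value), fraction-significant population
# time courses, response-latency detection against the pre-cue baseline,
# encoding co-occurrence, and group-level factorial ANOVA summaries.

#' Sliding-window fixed-effect ANOVA of spike counts on task factors
#'
#' For every neuron and time bin, fits a fixed-effects linear model of the
#' windowed spike count on the nominal factors chosen object, chosen action
#' and reward plus the continuous value covariate, and reports the per-factor
#' F-test p-value (the drop-one-term F against the full model; all terms have
#' one degree of freedom here, so this equals the usual partial F). The
#' design matrix is shared across neurons and bins, so the fit is a single QR
#' factorisation per (full or reduced) model applied to all neurons at once.
#' A factor constant across the analysed trials yields missing p-values for
#' that factor, never p = 1.
#'
#' @param tensor A `spike_tensor` (encoding convention: 50-ms bins, 10-ms
#'   steps, window -1.5..1.5 s from cue onset).
#' @param factors data.frame, one row per trial of `tensor`, with columns
#'   among `chosen_object`, `chosen_action`, `reward` (nominal) and `value`
#'   (numeric, typically the fitted chosen-option value from
#'   [fitted_value_trace()]).
#' @param alpha Per-bin significance level (no multiple-testing correction;
#'   the time courses are descriptive).
#' @return Long data.frame of class `encoding_map`: `neuron_id`,
#'   `bin_center_s`, `factor`, `p`, `significant`; attributes `alpha`,
#'   `neurons` (metadata), `bin_centers_s`.
#' @export
sliding_anova <- function(tensor, factors, alpha = 0.05) {
  stopifnot(inherits(tensor, "spike_tensor"),
            nrow(factors) == dim(tensor$counts)[1])
  fac_names <- intersect(c("chosen_object", "chosen_action", "reward", "value"),
                         names(factors))
  if (length(fac_names) == 0) stop("no recognised factor columns")
  nominal <- setdiff(fac_names, "value")
  df <- factors[, fac_names, drop = FALSE]
  for (nm in nominal) df[[nm]] <- factor(df[[nm]])

  usable <- vapply(fac_names, function(nm) {
    v <- df[[nm]]
    if (is.factor(v)) nlevels(droplevels(v)) >= 2 else stats::var(v) > 0
  }, logical(1))

  full_terms <- fac_names[usable]
  n <- nrow(df)
  make_X <- function(terms) {
    if (length(terms) == 0) return(matrix(1, n, 1))
    stats::model.matrix(stats::reformulate(terms), data = df)
  }
  qr_full <- qr(make_X(full_terms))
  p_full <- qr_full$rank
  qr_red <- lapply(full_terms, function(tm) qr(make_X(setdiff(full_terms, tm))))

  n_bins <- dim(tensor$counts)[3]
  n_neur <- dim(tensor$counts)[2]
  res <- vector("list", length(fac_names))
  names(res) <- fac_names
  for (nm in fac_names) res[[nm]] <- matrix(NA_real_, n_neur, n_bins)

  for (b in seq_len(n_bins)) {
    Y <- tensor$counts[, , b]
    if (n_neur == 1L) Y <- matrix(Y, ncol = 1)
    sse_full <- colSums(qr.resid(qr_full, Y)^2)
    df_res <- n - p_full
    for (i in seq_along(full_terms)) {
      sse_red <- colSums(qr.resid(qr_red[[i]], Y)^2)
      df_num <- p_full - qr_red[[i]]$rank
      Fst <- ((sse_red - sse_full) / df_num) / (sse_full / df_res)
      p <- stats::pf(Fst, df_num, df_res, lower.tail = FALSE)
      p[sse_full == 0] <- NA_real_
      res[[full_terms[i]]][, b] <- p
    }
  }

  out <- data.frame(
    neuron_id = rep(tensor$neurons$neuron_id, times = n_bins * length(fac_names)),
    bin_center_s = rep(rep(tensor$bin_centers_s, each = n_neur),
                       times = length(fac_names)),
    factor = rep(fac_names, each = n_neur * n_bins),
    p = unlist(lapply(res, as.vector), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  out$significant <- !is.na(out$p) & out$p < alpha
  attr(out, "alpha") <- alpha
  attr(out, "neurons") <- tensor$neurons
  attr(out, "bin_centers_s") <- tensor$bin_centers_s
  class(out) <- c("encoding_map", "data.frame")
  out
}

# Task-related neurons: significant for any factor in any post-cue bin.
task_related_neurons <- function(emap) {
  post <- emap[emap$bin_center_s >= 0 & emap$significant, ]
  unique(post$neuron_id)
}

#' Percentage of significant neurons over time, per array and factor
#'
#' For each group (by default each array) and time bin, the percentage of
#' task-related neurons whose factor p-value is below alpha. "Task-related"
#' defaults to: significant for any factor in any post-cue bin (no single
#' operational definition of the denominator is standard; the choice is
#' configurable).
#'
#' @param emap An `encoding_map` from [sliding_anova()].
#' @param group_by Column of the neuron metadata to group by.
#' @param task_related Optional vector of neuron ids to use as denominator;
#'   default computed as above.
#' @return data.frame `group`, `factor`, `bin_center_s`, `pct`,
#'   `n_neurons`. Groups with no task-related neurons are omitted (missing,
#'   not zero).
#' @export
fraction_significant <- function(emap, group_by = "array_id",
                                 task_related = NULL) {
  neurons <- attr(emap, "neurons")
  if (is.null(task_related)) task_related <- task_related_neurons(emap)
  keep <- neurons$neuron_id %in% task_related
  groups <- split(neurons$neuron_id[keep], neurons[[group_by]][keep])
  groups <- groups[lengths(groups) > 0]
  out <- list()
  for (g in names(groups)) {
    sub <- emap[emap$neuron_id %in% groups[[g]], ]
    agg <- stats::aggregate(significant ~ factor + bin_center_s, data = sub,
                            FUN = mean)
    out[[g]] <- data.frame(group = g, factor = agg$factor,
                           bin_center_s = agg$bin_center_s,
                           pct = 100 * agg$significant,
                           n_neurons = length(groups[[g]]),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Response latency of a population time course
#'
#' Implements the latency rule: a paired t-test compares each bin of a
#' population time course (percentage of significant neurons, or decoding
#' accuracy) against the mean of the pre-cue baseline window, pairing across
#' replicates (sessions, or session x array combinations). The first bin
#' with `p < alpha` (optionally required to start a run of
#' `min_consecutive` significant bins) is the latency; `NA` if no bin is
#' significant.
#'
#' @param timecourses Replicates x bins matrix.
#' @param bin_centers_s Bin centers (s, relative to cue onset).
#' @param baseline_window Baseline interval, default -1.5..-0.5 s.
#' @param alpha Significance level of the paired t-test.
#' @param min_consecutive Require this many consecutive significant bins
#'   (default 1 = the literal first-significant-bin rule).
#' @param search_from Only bins at or after this time are eligible as the
#'   latency (default: the whole time course, matching the literal rule).
#' @return Latency in seconds (`NA_real_` if none), with attributes `p`
#'   (per-bin p-values) and `suspicious_precue` (TRUE when every pre-cue bin
#'   outside the baseline is significant, a diagnostic for unplanned
#'   pre-cue signal).
#' @export
response_latency <- function(timecourses, bin_centers_s,
                             baseline_window = c(-1.5, -0.5),
                             alpha = 0.05, min_consecutive = 1L,
                             search_from = -Inf) {
  stopifnot(is.matrix(timecourses),
            ncol(timecourses) == length(bin_centers_s))
  if (nrow(timecourses) < 2) {
    stop("latency detection needs >= 2 replicates (sessions) for the paired t-test")
  }
  base_idx <- bin_centers_s >= baseline_window[1] &
    bin_centers_s < baseline_window[2]
  if (!any(base_idx)) stop("baseline window contains no bins")
  baseline <- rowMeans(timecourses[, base_idx, drop = FALSE])
  p <- vapply(seq_along(bin_centers_s), function(b) {
    x <- timecourses[, b]
    if (all(is.na(x)) || stats::sd(x - baseline, na.rm = TRUE) == 0) {
      return(NA_real_)
    }
    stats::t.test(x, baseline, paired = TRUE)$p.value
  }, numeric(1))
  sig <- !is.na(p) & p < alpha
  eligible <- bin_centers_s >= search_from
  lat <- NA_real_
  run <- rle(sig & eligible)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1
  ok <- which(run$values & run$lengths >= min_consecutive)
  if (length(ok) > 0) lat <- bin_centers_s[starts[ok[1]]]
  precue <- bin_centers_s < 0 & !base_idx
  structure(lat, p = p,
            suspicious_precue = any(precue) && all(sig[precue]))
}

#' Encoding latency (first significant deviation of the percentage course)
#'
#' Thin wrapper around [response_latency()] for encoding fraction-significant
#' time courses (rows = sessions or session x array replicates).
#' @inheritParams response_latency
#' @return See [response_latency()].
#' @export
encoding_latency <- function(timecourses, bin_centers_s,
                             baseline_window = c(-1.5, -0.5), alpha = 0.05,
                             min_consecutive = 1L, search_from = -Inf) {
  response_latency(timecourses, bin_centers_s, baseline_window, alpha,
                   min_consecutive, search_from)
}

#' Co-occurrence of significant encoding across conditions
#'
#' Given per-neuron significance flags in several conditions (e.g. action
#' encoding in What blocks vs action encoding in Where blocks), returns the
#' proportion of neurons significant in both members of every condition
#' pair, along with the marginal proportions.
#'
#' @param flags Logical matrix, neurons x conditions (column names label the
#'   conditions), or a named list of logical vectors over the same neurons.
#' @return List with `pairs` (data.frame `cond_a`, `cond_b`,
#'   `p_both`, `p_a`, `p_b`) and `marginals`.
#' @export
cooccurrence_counts <- function(flags) {
  if (is.list(flags) && !is.data.frame(flags) && !is.matrix(flags)) {
    lens <- lengths(flags)
    if (length(unique(lens)) != 1L) {
      stop("condition vectors cover mismatched neuron sets")
    }
    flags <- do.call(cbind, flags)
  }
  flags <- as.matrix(flags)
  if (anyNA(flags)) stop("significance flags contain NA")
  marg <- colMeans(flags)
  cmb <- expand.grid(a = seq_len(ncol(flags)), b = seq_len(ncol(flags)))
  cmb <- cmb[cmb$a <= cmb$b, ]
  pairs <- data.frame(
    cond_a = colnames(flags)[cmb$a],
    cond_b = colnames(flags)[cmb$b],
    p_both = mapply(function(i, j) mean(flags[, i] & flags[, j]),
                    cmb$a, cmb$b),
    p_a = marg[cmb$a], p_b = marg[cmb$b],
    stringsAsFactors = FALSE)
  list(pairs = pairs, marginals = marg)
}

#' Group-level factorial ANOVA of session summaries
#'
#' Fixed-effects linear model of a per-session summary (e.g. hold-period
#' percentage, latency) on hemisphere, block type, domain and array with all
#' main effects and two-way interactions, as a standard non-nested linear
#' model. Rank-deficient designs raise an error listing the aliased terms.
#'
#' @param data data.frame with the response and factor columns.
#' @param response Name of the response column.
#' @param factors Factor column names.
#' @param max_interaction Interaction order (2 = all two-way interactions).
#' @return data.frame `term`, `df`, `sum_sq`, `F`, `p` (sequential ANOVA
#'   table of the fixed-effects fit; residual row included).
#' @export
group_anova <- function(data, response,
                        factors = c("hemisphere", "block_type", "domain",
                                    "array_number"),
                        max_interaction = 2L) {
  stopifnot(response %in% names(data), all(factors %in% names(data)))
  for (f in factors) data[[f]] <- factor(data[[f]])
  rhs <- paste0("(", paste(factors, collapse = " + "), ")^", max_interaction)
  fit <- stats::lm(stats::reformulate(rhs, response = response), data = data)
  alias_info <- stats::alias(fit)$Complete
  if (!is.null(alias_info) && nrow(alias_info) > 0) {
    stop("rank-deficient design; aliased terms: ",
         paste(rownames(alias_info), collapse = ", "))
  }
  tab <- stats::anova(fit)
  data.frame(term = rownames(tab), df = tab$Df, sum_sq = tab$`Sum Sq`,
             F = tab$`F value`, p = tab$`Pr(>F)`,
             stringsAsFactors = FALSE, row.names = NULL)
}
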