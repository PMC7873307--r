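# Leave-one-trial-out linear Gaussian population decoding: per-class mean
# templates, softmax of negative squared distances (spherical covariance),
# accuracy time courses, hold-period accuracy, and decoding latency. Raw
# spike counts in 20-ms bins are used; nothing is normalised.

#' Per-class mean population templates
#'
#' Across-trial mean spike-count vector per class for one time bin.
#'
#' @param x Trials x neurons count matrix (training trials).
#' @param labels Class label per trial (2 classes).
#' @return Classes x neurons matrix of means, rownames = class levels.
#' @export
class_templates <- function(x, labels) {
  x <- as.matrix(x)
  if (anyNA(labels)) stop("labels contain NA")
  if (!is.factor(labels)) labels <- factor(labels)
  if (any(table(labels) == 0)) {
    stop("a class is absent from the training trials")
  }
  t(vapply(levels(labels),
           function(l) colMeans(x[labels == l, , drop = FALSE]),
           numeric(ncol(x))))
}

#' Posterior probability of each class from squared template distances
#'
#' `p_i = exp(-||x - T_i||^2) / sum_j exp(-||x - T_j||^2)` with the unscaled
#' squared Euclidean norm over neurons (a linear Gaussian decoder with
#' spherical covariance), evaluated stably in log space.
#'
#' @param x Population count vector (one trial, one bin).
#' @param templates Classes x neurons matrix from [class_templates()].
#' @return Named probability vector over classes (sums to 1).
#' @export
posterior_probability <- function(x, templates) {
  if (length(x) != ncol(templates)) {
    stop("population vector and templates have mismatched dimensions")
  }
  d <- colSums((t(templates) - x)^2)
  logw <- -d - max(-d)
  p <- exp(logw) / sum(exp(logw))
  stats::setNames(p, rownames(templates))
}

#' Leave-one-trial-out decoding of a binary trial variable
#'
#' For every time bin and held-out trial, class templates are computed from
#' all remaining trials and the held-out trial's posterior follows the
#' spherical Gaussian rule of [posterior_probability()]. Accuracy per bin is
#' the fraction of trials whose true-class posterior exceeds 0.5, with exact
#' ties credited 0.5. Folds whose training set lacks a class are skipped and
#' counted. Computed in closed form (hold-one-out means), which equals the
#' naive per-fold loop.
#'
#' @param tensor A `spike_tensor` (decoding convention: 20-ms bins, 20-ms
#'   steps, window -0.5..1.5 s from cue onset).
#' @param labels Per-trial class labels (exactly 2 levels; chosen action,
#'   chosen object, or reward).
#' @param domain Label stored with the result ("action", "object",
#'   "reward").
#' @return Object of class `posterior_series`: list with `accuracy` (per
#'   bin), `p_class1` and `p_true` (trials x bins posterior matrices),
#'   `labels`, `classes`, `bin_centers_s`, `domain`, `n_skipped_folds`.
#' @export
loto_decode <- function(tensor, labels, domain = NA_character_) {
  stopifnot(inherits(tensor, "spike_tensor"))
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("loto_decode requires exactly 2 classes")
  if (length(labels) != dim(tensor$counts)[1]) {
    stop("labels and tensor trial counts differ")
  }
  n_trials <- length(labels)
  cls <- levels(labels)
  n1 <- sum(labels == cls[1]); n2 <- sum(labels == cls[2])
  if (min(n1, n2) < 1) stop("a class has no trials")
  own_n <- ifelse(labels == cls[1], n1, n2)
  skipped <- own_n == 1          # training set would lack this trial's class
  n_bins <- dim(tensor$counts)[3]

  p_true <- matrix(NA_real_, n_trials, n_bins)
  p_c1 <- matrix(NA_real_, n_trials, n_bins)
  is1 <- labels == cls[1]
  for (b in seq_len(n_bins)) {
    Y <- tensor$counts[, , b, drop = FALSE]
    dim(Y) <- dim(tensor$counts)[1:2]
    m1 <- colMeans(Y[is1, , drop = FALSE])
    m2 <- colMeans(Y[!is1, , drop = FALSE])
    d1 <- colSums((t(Y) - m1)^2)
    d2 <- colSums((t(Y) - m2)^2)
    # hold-one-out correction: own-class distance scales by (n_c/(n_c-1))^2
    f1 <- (n1 / (n1 - 1))^2
    f2 <- (n2 / (n2 - 1))^2
    d1 <- ifelse(is1, d1 * f1, d1)
    d2 <- ifelse(!is1, d2 * f2, d2)
    p1 <- stats::plogis(d2 - d1)
    p1[skipped] <- NA_real_
    p_c1[, b] <- p1
    p_true[, b] <- ifelse(is1, p1, 1 - p1)
  }
  acc <- colMeans((p_true > 0.5) + 0.5 * (p_true == 0.5), na.rm = TRUE)
  structure(list(
    accuracy = acc,
    p_class1 = p_c1,
    p_true = p_true,
    labels = labels,
    classes = cls,
    bin_centers_s = tensor$bin_centers_s,
    domain = domain,
    n_skipped_folds = sum(skipped)
  ), class = "posterior_series")
}

#' @export
print.posterior_series <- function(x, ...) {
  cat(sprintf(
    "posterior_series [%s]: %d trials x %d bins, mean accuracy %.1f%%%s\n",
    x$domain, nrow(x$p_true), ncol(x$p_true), 100 * mean(x$accuracy),
    if (x$n_skipped_folds > 0)
      sprintf(" (%d folds skipped)", x$n_skipped_folds) else ""))
  invisible(x)
}

#' Mean decoding accuracy over the hold period
#'
#' Mean of the accuracy time course over bins whose centers fall in
#' `[-0.5, 0)` s (before cue onset).
#'
#' @param accuracy Accuracy per bin (or a `posterior_series`).
#' @param bin_centers_s Bin centers; taken from the series if omitted.
#' @param hold_window Hold-period interval.
#' @return Scalar mean accuracy.
#' @export
hold_period_accuracy <- function(accuracy, bin_centers_s = NULL,
                                 hold_window = c(-0.5, 0)) {
  if (inherits(accuracy, "posterior_series")) {
    bin_centers_s <- accuracy$bin_centers_s
    accuracy <- accuracy$accuracy
  }
  idx <- bin_centers_s >= hold_window[1] & bin_centers_s < hold_window[2]
  mean(accuracy[idx], na.rm = TRUE)
}

#' Decoding latency (first significant deviation of accuracy from baseline)
#'
#' Same paired-t latency rule as [encoding_latency()], applied to decoding
#' accuracy time courses (rows = sessions or session x array replicates).
#' @inheritParams response_latency
#' @return See [response_latency()].
#' @export
decoding_latency <- function(timecourses, bin_centers_s,
                             baseline_window = c(-1.5, -0.5), alpha = 0.05,
                             min_consecutive = 1L, search_from = -Inf) {
  response_latency(timecourses, bin_centers_s, baseline_window, alpha,
                   min_consecutive, search_from)
}
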