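# Binned spike-count tensors: construction from spike times, rebinning of
# the generator's base grid into sliding windows, and subsetting helpers.
# Encoding uses 50-ms bins advanced in 10-ms steps; decoding 20-ms bins in
# 20-ms steps; both time-locked to cue onset with half-open bins
# [start, start + width).

#' Construct a binned spike tensor
#'
#' Low-level constructor; most users get tensors from [generate_session()]
#' (10-ms base grid), [bin_spikes()] or [bin_tensor()].
#'
#' @param counts trials x neurons x bins array of non-negative counts.
#' @param bin_width_ms,step_ms Bin width and step (ms).
#' @param window_s Analysis window (s, relative to the alignment event).
#' @param bin_starts_s Bin start times (s); bins are `[start, start+width)`.
#' @param neurons data.frame of neuron metadata (`neuron_id`, `array_id`,
#'   `array_number`, `hemisphere`, ...).
#' @param trial_id Trial identifiers, length `dim(counts)[1]`.
#' @param alignment Name of the alignment event.
#' @return Object of class `spike_tensor`.
#' @export
new_spike_tensor <- function(counts, bin_width_ms, step_ms, window_s,
                             bin_starts_s, neurons, trial_id,
                             alignment = "cue_onset") {
  stopifnot(length(dim(counts)) == 3L,
            dim(counts)[1] == length(trial_id),
            dim(counts)[2] == nrow(neurons),
            dim(counts)[3] == length(bin_starts_s),
            all(counts >= 0))
  if (length(bin_starts_s) > 1 && any(diff(bin_starts_s) <= 0)) {
    stop("bin start times must be strictly increasing")
  }
  structure(list(
    counts = counts,
    bin_width_ms = bin_width_ms,
    step_ms = step_ms,
    window_s = window_s,
    bin_starts_s = bin_starts_s,
    bin_centers_s = bin_starts_s + bin_width_ms / 2000,
    neurons = neurons,
    trial_id = trial_id,
    alignment = alignment
  ), class = "spike_tensor")
}

#' @export
print.spike_tensor <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "spike_tensor: %d trials x %d neurons x %d bins (%g-ms bins, %g-ms steps, window %g..%g s from %s)\n",
    d[1], d[2], d[3], x$bin_width_ms, x$step_ms,
    x$window_s[1], x$window_s[2], x$alignment))
  invisible(x)
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Bin spike times into a sliding-window count tensor
#'
#' Counts spikes in sliding windows `[start, start + width)` advanced in
#' `step_ms` increments across `window_s`, time-locked to the alignment
#' event (spike times must already be relative to it, in ms). Width and step
#' must be commensurate (both multiples of their greatest common divisor,
#' which defines the internal fine grid).
#'
#' @param spike_times data.frame with `trial_id`, `neuron_id`, `time_ms`
#'   (relative to the alignment event).
#' @param trial_id Vector of all trial ids (trials with no spikes included).
#' @param neurons Neuron metadata data.frame (all neurons, spiking or not).
#' @param bin_width_ms,step_ms Window width and step in ms.
#' @param window_s Window in seconds, e.g. `c(-1.5, 1.5)`.
#' @param alignment Alignment-event name (metadata).
#' @return A `spike_tensor`.
#' @export
bin_spikes <- function(spike_times, trial_id, neurons,
                       bin_width_ms = 50, step_ms = 10,
                       window_s = c(-1.5, 1.5), alignment = "cue_onset") {
  if (bin_width_ms <= 0 || step_ms <= 0) stop("bin width and step must be > 0")
  if (diff(window_s) <= 0) stop("empty analysis window")
  base <- gcd2(bin_width_ms, step_ms)
  w0 <- window_s[1] * 1000; w1 <- window_s[2] * 1000
  n_fine <- round((w1 - w0) / base)
  starts <- seq(w0, by = step_ms,
                length.out = floor((w1 - w0 - bin_width_ms) / step_ms) + 1)
  n_bins <- length(starts)
  n_trials <- length(trial_id)
  n_neurons <- nrow(neurons)

  # fine-grid counts, then sliding sums of width/base consecutive fine bins
  keep <- spike_times$time_ms >= w0 & spike_times$time_ms < w1
  st <- spike_times[keep, , drop = FALSE]
  ti <- match(st$trial_id, trial_id)
  ni <- match(st$neuron_id, neurons$neuron_id)
  if (anyNA(ti) || anyNA(ni)) stop("spike times reference unknown trial or neuron ids")
  fb <- floor((st$time_ms - w0) / base) + 1
  cell <- (fb - 1) * n_trials * n_neurons + (ni - 1) * n_trials + ti
  fine <- array(tabulate(cell, nbins = n_trials * n_neurons * n_fine),
                dim = c(n_trials, n_neurons, n_fine))

  k <- round(bin_width_ms / base)
  stride <- round(step_ms / base)
  counts <- array(0L, dim = c(n_trials, n_neurons, n_bins))
  csum <- array(0, dim = c(n_trials, n_neurons, n_fine + 1))
  csum[, , -1] <- aperm(apply(fine, c(1, 2), cumsum), c(2, 3, 1))
  for (b in seq_len(n_bins)) {
    i0 <- (b - 1) * stride
    counts[, , b] <- csum[, , i0 + k + 1] - csum[, , i0 + 1]
  }
  new_spike_tensor(counts, bin_width_ms, step_ms, window_s, starts / 1000,
                   neurons, trial_id, alignment)
}

#' Rebin a base-grid tensor into sliding windows
#'
#' Aggregates a non-overlapping base-grid tensor (e.g. the generator's 10-ms
#' grid) into sliding windows of `bin_width_ms` advanced by `step_ms`. Both
#' must be multiples of the base bin width, and the requested window must be
#' covered by (and aligned with) the base grid.
#'
#' @param tensor Base `spike_tensor` with `bin_width_ms == step_ms`.
#' @param bin_width_ms,step_ms Target width/step in ms.
#' @param window_s Target window (defaults to the tensor's).
#' @return A `spike_tensor` on the new grid.
#' @export
bin_tensor <- function(tensor, bin_width_ms, step_ms,
                       window_s = tensor$window_s) {
  stopifnot(inherits(tensor, "spike_tensor"))
  base <- tensor$bin_width_ms
  if (tensor$step_ms != base) stop("input tensor must be a non-overlapping base grid")
  if (bin_width_ms %% base != 0 || step_ms %% base != 0) {
    stop("target width and step must be multiples of the base bin (",
         base, " ms)")
  }
  w0 <- window_s[1] * 1000; w1 <- window_s[2] * 1000
  base_starts <- round(tensor$bin_starts_s * 1000, 6)
  if (!any(abs(base_starts - w0) < 1e-6)) {
    stop("requested window start does not align with the base grid")
  }
  starts <- seq(w0, by = step_ms,
                length.out = floor((w1 - w0 - bin_width_ms) / step_ms) + 1)
  k <- bin_width_ms / base
  d <- dim(tensor$counts)
  counts <- array(0L, dim = c(d[1], d[2], length(starts)))
  for (b in seq_along(starts)) {
    i0 <- which(abs(base_starts - starts[b]) < 1e-6)
    if (length(i0) != 1L || i0 + k - 1 > d[3]) {
      stop("requested window exceeds the base grid")
    }
    sl <- tensor$counts[, , i0:(i0 + k - 1), drop = FALSE]
    counts[, , b] <- rowSums(sl, dims = 2)
  }
  new_spike_tensor(counts, bin_width_ms, step_ms, window_s, starts / 1000,
                   tensor$neurons, tensor$trial_id, tensor$alignment)
}

#' Subset a spike tensor by trials and/or neurons
#'
#' @param tensor A `spike_tensor`.
#' @param trials Logical or integer index over trials (optional).
#' @param neurons Logical or integer index over neuron rows (optional).
#' @return A `spike_tensor`.
#' @export
subset_tensor <- function(tensor, trials = NULL, neurons = NULL) {
  stopifnot(inherits(tensor, "spike_tensor"))
  ti <- if (is.null(trials)) seq_along(tensor$trial_id) else trials
  ni <- if (is.null(neurons)) seq_len(nrow(tensor$neurons)) else neurons
  new_spike_tensor(tensor$counts[ti, ni, , drop = FALSE],
                   tensor$bin_width_ms, tensor$step_ms, tensor$window_s,
                   tensor$bin_starts_s,
                   tensor$neurons[ni, , drop = FALSE],
                   tensor$trial_id[ti], tensor$alignment)
}

# Convert a base-grid tensor to spike times, placing each spike uniformly at
# random within its bin. Used for the spike-times export format.
tensor_to_spike_times <- function(tensor) {
  stopifnot(inherits(tensor, "spike_tensor"),
            tensor$bin_width_ms == tensor$step_ms)
  idx <- which(tensor$counts > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(trial_id = integer(), neuron_id = integer(),
                      time_ms = numeric()))
  }
  n <- tensor$counts[idx]
  rep_idx <- idx[rep.int(seq_len(nrow(idx)), n), , drop = FALSE]
  starts_ms <- tensor$bin_starts_s * 1000
  tm <- starts_ms[rep_idx[, 3]] +
    stats::runif(nrow(rep_idx), 0, tensor$bin_width_ms)
  out <- data.frame(
    trial_id = tensor$trial_id[rep_idx[, 1]],
    neuron_id = tensor$neurons$neuron_id[rep_idx[, 2]],
    time_ms = tm)
  out[order(out$trial_id, out$neuron_id, out$time_ms), ]
}
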