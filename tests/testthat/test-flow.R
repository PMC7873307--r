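# Information-flow regression: design/OLS oracles, nestedness, fVar
# arithmetic, direction recovery on coupled posterior series, kernel
# localization, permutation null at zero gain, ordinal-distance counts,
# cross-domain flow, and the learning-trajectory comparison.

test_that("flow coefficients equal the normal-equations oracle on a toy", {
  set.seed(81)
  out <- matrix(rnorm(2 * 15), 2, 15)
  ins <- list(L2 = matrix(rnorm(2 * 15), 2, 15))
  fit <- fit_flow_model(out, ins, self_lags = 1:2, cross_lags = 0:2)
  # hand-built design: observations pooled over trials, lags within trial
  rows <- list(); ys <- c()
  for (tr in 1:2) for (t in 3:15) {
    rows[[length(rows) + 1L]] <- c(1, out[tr, t - 1], out[tr, t - 2],
                                   ins$L2[tr, t - 0], ins$L2[tr, t - 1],
                                   ins$L2[tr, t - 2])
    ys <- c(ys, out[tr, t])
  }
  X <- do.call(rbind, rows)
  want <- as.vector(ols_oracle(X, ys))
  # reorder oracle rows: implementation pools trial-major per bin
  expect_equal(unname(fit$coefficients), want, tolerance = 1e-9)
  sse <- sum((ys - X %*% want)^2)
  expect_equal(fit$variance_explained, 1 - sse / sum((ys - mean(ys))^2),
               tolerance = 1e-9)
})

test_that("an exact lagged copy is explained with kernel mass at the true lag", {
  set.seed(82)
  src <- lpfcflow:::ar1_noise(10, 80, 1, 0.5)
  out <- lpfcflow:::lag_shift(src, 3)
  # self-lags of an exact lagged copy duplicate the cross-lags, so the
  # design is genuinely collinear: the pivoted-least-squares path engages
  expect_warning(
    fit <- fit_flow_model(out, list(L2 = src), self_lags = 1:5,
                          cross_lags = 0:5),
    "rank-deficient")
  expect_gt(fit$variance_explained, 0.99)
  cross <- fit$kernels[fit$kernels$input == "L2", ]
  expect_equal(cross$lag[which.max(abs(cross$coef))], 3)
})

test_that("independent white-noise series yield near-zero cross kernels", {
  set.seed(83)
  out <- matrix(rnorm(30 * 100), 30, 100)
  ins <- list(L2 = matrix(rnorm(30 * 100), 30, 100),
              R2 = matrix(rnorm(30 * 100), 30, 100))
  fit <- fit_flow_model(out, ins)
  expect_lt(fit$variance_explained, 0.02)
  cross <- fit$kernels$coef[fit$kernels$input != "self"]
  expect_lt(max(abs(cross)), 0.1)
})

test_that("partial models are nested: Var_partial <= Var_full always", {
  for (seed in 1:5) {
    post <- simulate_posterior_network(
      n_trials = 20, n_bins = 60, n_numbers = 2,
      coupling = list(list(src_number = 2, tgt_number = 1, lag_bins = 2,
                           gain = if (seed %% 2) 0.8 else 0)),
      seed = seed)
    for (out_id in names(post)) {
      ins <- post[setdiff(names(post), out_id)]
      full <- fit_flow_model(post[[out_id]], ins)
      for (dn in setdiff(1:2, lpfcflow:::parse_array_number(out_id))) {
        part <- fit_partial_model(post[[out_id]], ins, dn,
                                  output_id = out_id)
        expect_lte(part$variance_explained,
                   full$variance_explained + 1e-10)
        fv <- flow_strength(full, part)
        expect_gte(fv, -1e-10)
        expect_lte(fv, 1)
      }
    }
  }
})

test_that("fVar arithmetic and degenerate cases", {
  expect_equal(flow_strength(0.4, 0.3), 0.25)
  expect_equal(flow_strength(0.4, 0.4), 0)
  expect_equal(flow_strength(0.4, 0), 1)
  expect_warning(fv <- flow_strength(0, 0.1), "not positive")
  expect_true(is.na(fv))
})

test_that("delta posterior equals elementwise subtraction of predictions", {
  set.seed(84)
  post <- simulate_posterior_network(
    n_trials = 15, n_bins = 60,
    coupling = list(list(src_number = 2, tgt_number = 1, lag_bins = 3,
                         gain = 1)),
    seed = 84)
  ins <- post[c("R1", "L2", "R2")]
  full <- fit_flow_model(post$L1, ins)
  part <- fit_partial_model(post$L1, ins, 2, output_id = "L1")
  dp <- delta_posterior(full, part)
  expect_equal(dp$delta, colMeans(full$fitted - part$fitted))
  expect_equal(dp$bin, 11:60)
  # dropping the planted driver produces a nonzero contribution
  expect_gt(mean(abs(dp$delta)), 0)
})

test_that("dropping rules: own number rejected, empty input set rejected", {
  post <- simulate_posterior_network(n_trials = 10, n_bins = 40, seed = 85)
  ins <- post[c("R1", "L2", "R2")]
  expect_error(fit_partial_model(post$L1, ins, 1, output_id = "L1"), "own")
  expect_error(
    fit_partial_model(post$L1, ins["L2"], 2, output_id = "L1", mode = "both"),
    "no input arrays")
  expect_error(fit_partial_model(post$L1, ins, 4, output_id = "L1"),
               "no input array has number")
})

test_that("planted direction is recovered on coupled posterior series", {
  wins <- 0L
  n_rep <- 15L
  for (r in seq_len(n_rep)) {
    post <- simulate_posterior_network(
      n_trials = 40, n_bins = 100,
      coupling = list(list(src_number = 2, tgt_number = 1, lag_bins = 3,
                           gain = 0.8)),
      seed = 100 + r)
    fv <- function(out_id, dn) {
      ins <- post[setdiff(names(post), out_id)]
      flow_strength(fit_flow_model(post[[out_id]], ins),
                    fit_partial_model(post[[out_id]], ins, dn,
                                      output_id = out_id))
    }
    truth <- mean(c(fv("L1", 2), fv("R1", 2)))   # flow 2 -> 1 planted
    rev <- mean(c(fv("L2", 1), fv("R2", 1)))
    if (truth > rev) wins <- wins + 1L
  }
  expect_gte(wins, n_rep - 1L)
})

test_that("time reversal flips the recovered dominant direction", {
  post <- simulate_posterior_network(
    n_trials = 40, n_bins = 100,
    coupling = list(list(src_number = 2, tgt_number = 1, lag_bins = 3,
                         gain = 0.8)),
    seed = 86)
  fv <- function(p, out_id, dn) {
    ins <- p[setdiff(names(p), out_id)]
    flow_strength(fit_flow_model(p[[out_id]], ins),
                  fit_partial_model(p[[out_id]], ins, dn,
                                    output_id = out_id))
  }
  fwd <- mean(c(fv(post, "L1", 2), fv(post, "R1", 2))) -
    mean(c(fv(post, "L2", 1), fv(post, "R2", 1)))
  rev_post <- lapply(post, function(m) m[, rev(seq_len(ncol(m)))])
  bwd <- mean(c(fv(rev_post, "L1", 2), fv(rev_post, "R1", 2))) -
    mean(c(fv(rev_post, "L2", 1), fv(rev_post, "R2", 1)))
  expect_gt(fwd, 0)
  expect_lt(bwd, 0)
})

test_that("cross-kernel argmax matches the planted lag at high SNR", {
  hits <- 0L
  for (r in 1:10) {
    post <- simulate_posterior_network(
      n_trials = 40, n_bins = 100,
      coupling = list(list(src_number = 2, tgt_number = 1, lag_bins = 3,
                           gain = 1.5)),
      seed = 200 + r)
    full <- fit_flow_model(post$L1, post[c("R1", "L2", "R2")])
    k <- full$kernels[full$kernels$input == "L2", ]
    if (abs(k$lag[which.max(k$coef)] - 3) <= 1) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("zero-gain fVar is indistinguishable from its permutation null", {
  set.seed(87)
  n_sig <- 0L
  for (r in 1:8) {
    post <- simulate_posterior_network(n_trials = 25, n_bins = 60,
                                       seed = 300 + r)
    p <- perm_fvar_p(post$L1, post[c("R1", "L2", "R2")], 2, "L1",
                     n_perm = 39)
    if (p < 0.05) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 2L)
})

test_that("ordinal-distance groups carry the combinatorial pair counts", {
  set.seed(88)
  post4 <- simulate_posterior_network(n_trials = 20, n_bins = 50,
                                      n_numbers = 4, seed = 88)
  trials <- data.frame(session_id = "S1",
                       block_type = rep("What", 20),
                       trial_index_in_block = 1:20)
  fs <- flow_session(list(action = post4), trials,
                     domain_pairs = data.frame(out_domain = "action",
                                               in_domain = "action"),
                     block_types = "What", min_trials = 10)
  expect_s3_class(fs, "flow_summary")
  expect_equal(fs$distance, fs$in_number - fs$out_number)
  os <- ordinal_distance_summary(fs)
  # 8 outputs (2 hemispheres x 4 numbers): |d|=1 -> 3 ordered number pairs
  # per direction, |d|=2 -> 2, |d|=3 -> 1; x2 output hemispheres
  counts <- setNames(os$n, os$distance)
  expect_equal(unname(counts[c("-3", "-2", "-1", "1", "2", "3")]),
               c(2, 4, 6, 6, 4, 2))
  expect_true(all(fs$var_partial <= fs$var_full + 1e-10))
})

test_that("cross-domain flow recovers a planted object-to-action direction", {
  set.seed(89)
  n_tr <- 50; n_bins <- 80
  ids <- c("L3", "L4", "R3", "R4")
  mk <- function() lpfcflow:::ar1_noise(n_tr, n_bins, 1, 0.5)
  obj <- sapply(ids, function(i) mk(), simplify = FALSE)
  act <- sapply(ids, function(i) mk(), simplify = FALSE)
  # object latent of array 4 drives action latent of array 3 at lag 3
  act$L3 <- act$L3 + 1.2 * lpfcflow:::lag_shift(obj$L4, 3)
  act$R3 <- act$R3 + 1.2 * lpfcflow:::lag_shift(obj$R4, 3)
  posts <- list(action = lapply(act, plogis), object = lapply(obj, plogis))
  trials <- data.frame(session_id = "S1", block_type = rep("What", n_tr),
                       trial_index_in_block = seq_len(n_tr))
  fs <- cross_domain_flow(posts, trials, "object_to_action",
                          block_types = "What", min_trials = 10)
  f43 <- mean(fs$fvar[fs$out_number == 3 & fs$in_number == 4])
  f34 <- mean(fs$fvar[fs$out_number == 4 & fs$in_number == 3])
  expect_gt(f43, f34)
  ct <- vl_cdl_contrast(fs)
  expect_gt(ct$diff_4to3_minus_3to4, 0)
  # the strictly-lagged variant preserves the direction ordering
  fs_lag <- cross_domain_flow(posts, trials, "object_to_action",
                              block_types = "What", min_trials = 10,
                              cross_lags = 1:10)
  expect_gt(mean(fs_lag$fvar[fs_lag$out_number == 3 & fs_lag$in_number == 4]),
            mean(fs_lag$fvar[fs_lag$out_number == 4 & fs_lag$in_number == 3]))
})

test_that("learning-trajectory p-values match a brute-force paired t oracle", {
  set.seed(90)
  sessions <- lapply(1:4, function(s) {
    trials <- make_flow_trials(n_blocks_per_type = 2, n_trials = 30,
                               session_id = paste0("S", s))
    gate <- trials$block_type == "What" & trials$trial_index_in_block >= 16
    make_gated_session(trials, gate, gain = 2, n_bins = 60)
  })
  lt <- learning_trajectory_flow(sessions, window = 10, step = 5,
                                 outputs = "L1", drop_numbers = 2,
                                 min_trials = 10)
  # oracle for one window: recompute per-session fVar means and the paired t
  w <- lt[lt$window_start == 21, ]
  per_sess <- sapply(sessions, function(s) {
    sel <- s$trials$trial_index_in_block >= 21 &
      s$trials$trial_index_in_block <= 30
    fs <- flow_session(s$posteriors, s$trials, outputs = "L1",
                       drop_numbers = 2, trial_subset = sel,
                       min_trials = 10)
    c(mean(fs$fvar[fs$block_type == "What"]),
      mean(fs$fvar[fs$block_type == "Where"]))
  })
  want <- t.test(per_sess[1, ], per_sess[2, ], paired = TRUE)$p.value
  expect_equal(w$p, want, tolerance = 1e-12)
  # coupling gated on after trial 15 in What blocks: late windows separate,
  # the earliest window does not
  expect_gt(lt$mean_What[lt$window_start == 21],
            lt$mean_Where[lt$window_start == 21])
  expect_lt(w$p, 0.05)
  expect_gt(lt$p[lt$window_start == 1], 0.05)
})
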