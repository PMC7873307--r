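# Sliding-window ANOVA, fraction-significant time courses, latency
# detection, co-occurrence, and the group-level factorial ANOVA.

# small tensor with directly constructed Poisson counts
make_counts_tensor <- function(counts, bin_width_ms = 50, step_ms = 50,
                               t0 = 0) {
  d <- dim(counts)
  neurons <- data.frame(neuron_id = seq_len(d[2]), array_id = "L1",
                        array_number = 1L, hemisphere = "L",
                        region = "rdlPFC")
  starts <- t0 + seq(0, by = step_ms, length.out = d[3]) / 1000
  new_spike_tensor(counts, bin_width_ms, step_ms,
                   c(starts[1], starts[d[3]] + bin_width_ms / 1000),
                   starts, neurons, seq_len(d[1]))
}

test_that("per-factor p-values match per-neuron lm drop-term oracles", {
  set.seed(61)
  n <- 60
  fac <- data.frame(chosen_object = sample(c("A", "B"), n, TRUE),
                    chosen_action = sample(c("left", "right"), n, TRUE),
                    reward = rbinom(n, 1, 0.5),
                    value = runif(n))
  counts <- array(rpois(n * 3 * 2, 4), dim = c(n, 3, 2))
  emap <- sliding_anova(make_counts_tensor(counts), fac)
  for (ni in 1:3) for (b in 1:2) {
    y <- counts[, ni, b]
    full <- lm(y ~ factor(chosen_object) + factor(chosen_action) +
                 reward + value, data = cbind(fac, y = y))
    for (fn in c("chosen_object", "chosen_action", "reward", "value")) {
      red <- update(full, stats::reformulate(
        setdiff(c("factor(chosen_object)", "factor(chosen_action)",
                  "reward", "value"),
                if (fn %in% c("chosen_object", "chosen_action"))
                  paste0("factor(", fn, ")") else fn),
        response = "y"))
      want <- anova(red, full)$`Pr(>F)`[2]
      got <- emap$p[emap$neuron_id == ni & emap$factor == fn &
                      abs(emap$bin_center_s -
                            attr(emap, "bin_centers_s")[b]) < 1e-9]
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("planted action tuning is detected and object stays at false-positive rate", {
  set.seed(62)
  n <- 300
  fac <- data.frame(chosen_object = sample(c("A", "B"), n, TRUE),
                    chosen_action = sample(c("left", "right"), n, TRUE),
                    reward = rbinom(n, 1, 0.5),
                    value = runif(n))
  n_bins <- 20
  lam <- outer(ifelse(fac$chosen_action == "left", 6, 2), rep(1, n_bins))
  counts <- array(rpois(n * n_bins, lam), dim = c(n, 1, n_bins))
  emap <- sliding_anova(make_counts_tensor(counts), fac)
  act <- emap[emap$factor == "chosen_action", ]
  obj <- emap[emap$factor == "chosen_object", ]
  expect_gte(mean(act$significant), 0.9)
  expect_lte(mean(obj$significant), 0.25)
})

test_that("null false-positive rate sits near alpha", {
  set.seed(63)
  n <- 200
  fac <- data.frame(chosen_object = sample(c("A", "B"), n, TRUE),
                    chosen_action = sample(c("left", "right"), n, TRUE),
                    reward = rbinom(n, 1, 0.5),
                    value = runif(n))
  counts <- array(rpois(n * 20 * 15, 4), dim = c(n, 20, 15))
  emap <- sliding_anova(make_counts_tensor(counts), fac)
  fpr <- mean(emap$significant)
  # 20 neurons x 15 independent bins x 4 factors
  expect_gt(fpr, 0.03)
  expect_lt(fpr, 0.075)
})

test_that("a constant factor yields missing p-values, not 1", {
  set.seed(64)
  n <- 40
  fac <- data.frame(chosen_object = rep("A", n),
                    chosen_action = sample(c("left", "right"), n, TRUE),
                    reward = rbinom(n, 1, 0.5),
                    value = runif(n))
  counts <- array(rpois(n * 2 * 3, 4), dim = c(n, 2, 3))
  emap <- sliding_anova(make_counts_tensor(counts), fac)
  expect_true(all(is.na(emap$p[emap$factor == "chosen_object"])))
  expect_false(anyNA(emap$p[emap$factor == "chosen_action"]))
})

test_that("fraction significant is 100% when every neuron is significant", {
  set.seed(65)
  n <- 120
  fac <- data.frame(chosen_action = sample(c("left", "right"), n, TRUE),
                    value = runif(n))
  # strong tuning in every neuron; bins sit post-cue so all are task-related
  counts <- array(rpois(n * 4 * 8, ifelse(fac$chosen_action == "left", 10, 1)),
                  dim = c(n, 4, 8))
  emap <- sliding_anova(make_counts_tensor(counts), fac)
  fs <- fraction_significant(emap)
  expect_true(all(fs$pct[fs$factor == "chosen_action"] == 100))
})

test_that("latency detection recovers a planted onset and is shift-equivariant", {
  set.seed(66)
  centers <- seq(-1.475, 1.475, by = 0.01)
  make_tc <- function(onset_s, n_sessions = 6, amp = 30) {
    base <- matrix(rnorm(n_sessions * length(centers), 10, 1.2),
                   n_sessions, length(centers))
    bump <- amp * pmin(pmax((centers - onset_s) / 0.15, 0), 1)
    sweep(base, 2, bump, "+")
  }
  # the literal first-significant-bin rule is noise-limited over ~300 bins,
  # so recovery tests engage the consecutive-bins guard the detector offers
  lat <- response_latency(make_tc(0.15), centers, min_consecutive = 3)
  expect_lt(abs(as.numeric(lat) - 0.15), 0.03)
  lat_shift <- response_latency(make_tc(0.25), centers, min_consecutive = 3)
  expect_lt(abs((as.numeric(lat_shift) - as.numeric(lat)) - 0.1), 0.03)
  # flat null: no latency
  flat <- matrix(rnorm(6 * length(centers), 10, 1.2), 6, length(centers))
  expect_true(is.na(response_latency(flat, centers, alpha = 0.001,
                                     min_consecutive = 3)))
  # stronger modulation is detected no later
  lat_strong <- response_latency(make_tc(0.15, amp = 60), centers,
                                 min_consecutive = 3)
  expect_lte(as.numeric(lat_strong), as.numeric(lat) + 0.011)
})

test_that("latency detection needs replicates and a baseline", {
  centers <- seq(-1.475, 1.475, by = 0.01)
  expect_error(response_latency(matrix(1, 1, length(centers)), centers),
               ">= 2")
  expect_error(response_latency(matrix(1, 3, 5), c(1, 2, 3, 4, 5) / 10),
               "baseline")
})

test_that("co-occurrence matches marginals for identical and disjoint conditions", {
  flags <- cbind(a = c(TRUE, TRUE, FALSE, FALSE, TRUE),
                 b = c(TRUE, TRUE, FALSE, FALSE, TRUE),
                 c = c(FALSE, FALSE, TRUE, TRUE, FALSE))
  cc <- cooccurrence_counts(flags)
  self_a <- cc$pairs[cc$pairs$cond_a == "a" & cc$pairs$cond_b == "a", ]
  expect_equal(self_a$p_both, 0.6)               # self pair = marginal
  ab <- cc$pairs[cc$pairs$cond_a == "a" & cc$pairs$cond_b == "b", ]
  expect_equal(ab$p_both, min(ab$p_a, ab$p_b))   # fully overlapping
  ac <- cc$pairs[cc$pairs$cond_a == "a" & cc$pairs$cond_b == "c", ]
  expect_equal(ac$p_both, 0)                     # disjoint
  expect_error(cooccurrence_counts(list(a = c(TRUE, FALSE), b = TRUE)),
               "mismatched")
})

test_that("independently planted conditions co-occur at the product of marginals", {
  set.seed(67)
  n <- 4000
  flags <- cbind(x = runif(n) < 0.4, y = runif(n) < 0.3)
  cc <- cooccurrence_counts(flags)
  xy <- cc$pairs[cc$pairs$cond_a == "x" & cc$pairs$cond_b == "y", ]
  expect_lt(abs(xy$p_both - xy$p_a * xy$p_b), 3 * sqrt(0.12 / n))
})

test_that("group ANOVA matches hand-computed balanced sums of squares", {
  grid <- expand.grid(hemisphere = c("L", "R"), block_type = c("What", "Where"),
                      domain = c("action", "object"), array_number = 1:4,
                      session = 1:3)
  set.seed(68)
  grid$y <- rnorm(nrow(grid)) + 2 * (grid$array_number == 4)
  tab <- group_anova(grid, "y")
  # balanced design: main-effect SS = n_per_level * sum (level mean - grand)^2
  grand <- mean(grid$y)
  for (f in c("hemisphere", "block_type", "domain", "array_number")) {
    means <- tapply(grid$y, grid[[f]], mean)
    want <- sum(table(grid[[f]]) * (means - grand)^2)
    expect_equal(tab$sum_sq[tab$term == f], want, tolerance = 1e-9)
  }
  # planted array effect dominates
  f_arr <- tab$F[tab$term == "array_number"]
  others <- tab$F[tab$term %in% c("hemisphere", "block_type", "domain")]
  expect_gt(f_arr, 10 * max(others))
  expect_lt(tab$p[tab$term == "array_number"], 1e-6)
})

test_that("aliased group-ANOVA designs raise an explicit error", {
  grid <- expand.grid(hemisphere = c("L", "R"), block_type = c("What", "Where"),
                      array_number = 1:4, session = 1:2)
  grid$domain <- grid$block_type  # perfectly confounded
  grid$y <- rnorm(nrow(grid))
  expect_error(group_anova(grid, "y"), "alias")
})

test_that("null group-ANOVA F values are consistent with a permutation oracle", {
  grid <- expand.grid(hemisphere = c("L", "R"), block_type = c("What", "Where"),
                      domain = c("action", "object"), array_number = 1:4,
                      session = 1:4)
  set.seed(69)
  grid$y <- rnorm(nrow(grid))
  obs <- group_anova(grid, "y")
  f_obs <- obs$F[obs$term == "array_number"]
  null_f <- replicate(200, {
    g <- grid; g$y <- sample(g$y)
    tab <- group_anova(g, "y")
    tab$F[tab$term == "array_number"]
  })
  # observed F is an unremarkable draw from the permutation null
  expect_gt(mean(null_f >= f_obs), 0.025)
})
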