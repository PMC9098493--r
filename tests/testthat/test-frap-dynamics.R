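# FRAP double normalization, recovery fitting and light-cycle trajectories.

test_that("four-step normalization reproduces hand-computed values", {
  tr <- frap_trace(times = 0:2, roi = c(100, 30, 60),
                   reference = c(100, 90, 95), background = 10,
                   prebleach_index = 1)
  norm <- normalize_frap(tr)
  # I_c1 = [90,20,50]; R_c1 = [90,80,85]; I_c2 = [1, .25, 50/85]; /I_c2(1)
  expect_equal(norm$intensity, c(1, 0.25, 50 / 85))
  expect_identical(norm$intensity[1], 1)
})

test_that("normalization is exactly scale-invariant and anchored at pre-bleach", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    B <- stats::runif(1, 0, 20)
    ref <- B + stats::runif(n, 5, 100)
    roi <- B + stats::runif(n, 1, 100)
    p <- sample(n, 1)
    tr <- frap_trace(seq_len(n), roi, ref, B, prebleach_index = p)
    norm <- normalize_frap(tr)
    expect_identical(norm$intensity[p], 1)
    s <- stats::runif(1, 0.1, 50)
    tr2 <- frap_trace(seq_len(n), roi * s, ref * s, B * s,
                      prebleach_index = p)
    expect_equal(normalize_frap(tr2)$intensity, norm$intensity,
                 tolerance = 1e-12)
  }
})

test_that("normalization rejects traces that dip to background", {
  tr <- frap_trace(0:3, c(50, 20, 30, 40), c(50, 45, 5, 48), background = 10)
  expect_error(normalize_frap(tr), "index 3", class = "domain_error")
  tr2 <- frap_trace(0:2, c(10, 30, 40), c(50, 45, 48), background = 10)
  expect_error(normalize_frap(tr2), class = "domain_error")
})

test_that("recovery fit: noiseless round trip, flat curve, half-time rule", {
  tr <- generate_frap_trace(frap_truth(mobile_fraction = 0.8, rate = 0.1,
                                       n_timepoints = 100L, dt = 1,
                                       reference_fade = 0.002))
  fit <- fit_recovery(normalize_frap(tr$trace))
  expect_equal(fit$mobile_fraction, 0.8, tolerance = 0.01)
  expect_equal(fit$rate, 0.1, tolerance = 0.01)
  expect_equal(fit$half_time, log(2) / fit$rate)

  flat <- structure(list(times = 0:19, intensity = c(1, rep(0.4, 19)),
                         prebleach_index = 1L), class = "normalized_frap")
  ffit <- fit_recovery(flat)
  expect_equal(ffit$mobile_fraction, 0)
  expect_error(fit_recovery(structure(list(times = 0:3,
                                           intensity = c(1, .2, .3, .4),
                                           prebleach_index = 1L),
                                      class = "normalized_frap")),
               class = "invalid_trace")
})

test_that("A and k are recovered within 5% from noisy traces (median of 50)", {
  errs <- t(vapply(1:50, function(s) {
    tr <- generate_frap_trace(frap_truth(mobile_fraction = 0.8, rate = 0.1,
                                         noise_sd = 0.01,
                                         n_timepoints = 100L, seed = s))
    fit <- fit_recovery(normalize_frap(tr$trace))
    c(abs(fit$mobile_fraction - 0.8) / 0.8, abs(fit$rate - 0.1) / 0.1)
  }, numeric(2)))
  expect_lt(median(errs[, 1]), 0.05)
  expect_lt(median(errs[, 2]), 0.05)
})

test_that("cycle trajectory tracks assembly/disassembly and phases", {
  sched <- light_schedule(rep(600, 4), rep(c("on", "off"), 2))
  sc <- test_scene(n = 3, radius = 4, noise_sd = 20)
  st <- generate_cycle_stack(sched, sc, k_on = 1 / 60, k_off = 1 / 50,
                             fold_max = 5, residual_fraction_per_cycle = 0,
                             frame_interval = 60, seed = 9L)
  traj <- cycle_trajectory(st$frames, st$truth$time_s, sched)
  expect_identical(traj$state, st$truth$state)
  expect_identical(traj$cycle, st$truth$cycle)
  # complete disassembly: end-of-off ratios back to ~1
  for (cy in 1:2) {
    off <- traj[traj$cycle == cy & traj$state == "off", ]
    expect_equal(off$partition_ratio[nrow(off)], 1, tolerance = 0.1)
  }
  # on-phase: measured trajectory rises with the monotone truth (rank test)
  on1 <- traj[traj$cycle == 1 & traj$state == "on", ]
  expect_gt(stats::cor(on1$frame, on1$partition_ratio, method = "spearman"),
            0.8)
  # measured values track the analytic truth
  expect_lt(median(abs(traj$partition_ratio - st$truth$partition_ratio) /
                     st$truth$partition_ratio), 0.05)
  expect_error(cycle_trajectory(st$frames, st$truth$time_s + 1e5, sched),
               class = "outside_schedule")
})

test_that("constant uniform frames give all-1 ratios", {
  frames <- replicate(4, matrix(500, 32, 32), simplify = FALSE)
  sched <- light_schedule(c(600, 600), c("on", "off"))
  traj <- cycle_trajectory(frames, c(0, 300, 600, 900), sched)
  expect_true(all(traj$partition_ratio == 1))
  expect_identical(traj$n, rep(0L, 4))
})

test_that("reversibility index: limits and residual recovery", {
  mk <- function(pr_on, pr_off) data.frame(
    frame = 1:6, time_s = 1:6, cycle = 1L,
    state = rep(c("on", "off"), each = 3),
    partition_ratio = c(rep(pr_on, 3), rep(pr_off, 3)), n = 3L)
  expect_equal(reversibility_index(mk(3, 1)), 0)
  expect_equal(reversibility_index(mk(3, 3)), 1)
  expect_error(reversibility_index(mk(1, 1)), class = "undefined_index")
  expect_error(reversibility_index(mk(2, 1), cycle = 5),
               class = "invalid_argument")

  # generator with residual 0.5: index ~ 0.5 (fast kinetics, near-noiseless)
  sched <- light_schedule(rep(600, 2), c("on", "off"))
  sc <- test_scene(n = 3, noise_sd = 5)
  st <- generate_cycle_stack(sched, sc, k_on = 1 / 40, k_off = 1 / 40,
                             residual_fraction_per_cycle = 0.5,
                             frame_interval = 60, seed = 4L)
  traj <- cycle_trajectory(st$frames, st$truth$time_s, sched)
  truth_idx <- reversibility_index(st$truth)
  expect_equal(reversibility_index(traj), truth_idx, tolerance = 0.1)
})
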