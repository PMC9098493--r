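# Synthetic generators: ground-truth consistency, seeded determinism,
# degenerate cases.

test_that("noiseless scene renders the exact analytic pixel values", {
  # condensate-free nucleus: every within-nucleus pixel is nucleoplasm_level
  sc0 <- test_scene(n = 0, noise_sd = 0)
  res0 <- generate_condensate_image(sc0)
  nuc <- disk_mask_oracle(sc0$dim, sc0$nucleus_center, sc0$nucleus_radius)
  expect_identical(res0$masks$nucleus, nuc)
  expect_true(all(res0$image[nuc] == sc0$nucleoplasm_level))
  expect_true(all(res0$image[!nuc] == sc0$background_level))

  # 3 disjoint fold-5 disks: within-nucleus pixel sum matches the analytic
  # identity level * (nucleus_count + (fold-1) * condensate_count)
  sc <- test_scene(n = 3, fold = 5, noise_sd = 0)
  res <- generate_condensate_image(sc)
  cond_count <- 0L
  for (i in seq_len(nrow(sc$condensates)))
    cond_count <- cond_count + sum(disk_mask_oracle(
      sc$dim, c(sc$condensates$row[i], sc$condensates$col[i]),
      sc$condensates$radius[i]))
  expect_equal(sum(res$image[nuc]),
               sc$nucleoplasm_level * (sum(nuc) + 4 * cond_count))
})

test_that("scene generation is seeded-deterministic and leaves the RNG alone", {
  sc <- test_scene(n = 3, noise_sd = 50, seed = 42L)
  a <- generate_condensate_image(sc)$image
  set.seed(7); probe1 <- rnorm(1)
  b <- generate_condensate_image(sc)$image
  expect_identical(a, b)
  # global stream untouched by the seeded generator
  set.seed(7); expect_identical(rnorm(1), probe1)
})

test_that("invalid scenes are rejected", {
  expect_error(scene_truth(nucleus_radius = -3), class = "invalid_scene")
  expect_error(
    scene_truth(condensates = data.frame(row = 64, col = 110, radius = 8,
                                         fold = 5)),
    class = "invalid_scene")  # pokes outside the nucleus disk
  expect_error(
    scene_truth(condensates = data.frame(row = 64, col = 64, radius = 3,
                                         fold = 0.5)),
    class = "invalid_scene")  # de-enrichment not allowed
  expect_error(scene_truth(noise_sd = -1), class = "invalid_argument")
})

test_that("hexanediol flag scales enrichment toward 1", {
  sc <- test_scene(n = 1, fold = 5, noise_sd = 0)
  sc$hexanediol <- 0.5
  res <- generate_condensate_image(sc)
  cond <- res$masks$condensate > 0L
  expect_equal(unique(res$image[cond]), sc$nucleoplasm_level * 3) # 1+0.5*4
  sc$hexanediol <- 0
  res0 <- generate_condensate_image(sc)
  expect_equal(unique(res0$image[res0$masks$condensate > 0L]),
               sc$nucleoplasm_level)                               # dissolved
})

test_that("FRAP generator satisfies its closed-form identities", {
  # full recovery limit: A = 1, long time -> normalized intensity -> 1
  tr <- generate_frap_trace(frap_truth(mobile_fraction = 1, rate = 0.1,
                                       n_timepoints = 400L, dt = 1))
  norm <- normalize_frap(tr$trace)
  expect_equal(tail(norm$intensity, 1), 1, tolerance = 1e-8)
  expect_equal(norm$intensity, tr$truth$normalized_ideal, tolerance = 1e-12)

  # seeded determinism
  t1 <- generate_frap_trace(frap_truth(noise_sd = 0.01, seed = 11L))
  t2 <- generate_frap_trace(frap_truth(noise_sd = 0.01, seed = 11L))
  expect_identical(t1$trace$roi, t2$trace$roi)

  expect_error(frap_truth(bleach_depth = 0), class = "invalid_argument")
  expect_error(frap_truth(n_timepoints = 2), class = "invalid_argument")
})

test_that("noiseless FRAP trace round-trips through the recovery fit", {
  tr <- generate_frap_trace(frap_truth(mobile_fraction = 0.8, rate = 0.1,
                                       n_timepoints = 100L, dt = 1))
  fit <- fit_recovery(normalize_frap(tr$trace))
  expect_equal(fit$mobile_fraction, 0.8, tolerance = 0.01)
  expect_equal(fit$rate, 0.1, tolerance = 0.01)
})

test_that("cycle-stack truth follows the first-order assembly/disassembly rule", {
  sched <- light_schedule(rep(600, 4), rep(c("on", "off"), 2))
  sc <- test_scene(n = 3, noise_sd = 0)

  # residual 0, slow-enough cycle: truth ratio returns to ~1 at each off end
  st0 <- generate_cycle_stack(sched, sc, k_off = 1 / 50,
                              residual_fraction_per_cycle = 0)
  off_ends <- vapply(1:2, function(cy) {
    tr <- st0$truth[st0$truth$cycle == cy & st0$truth$state == "off", ]
    tr$partition_ratio[nrow(tr)]
  }, numeric(1))
  expect_true(all(abs(off_ends - 1) < 0.01))

  # residual 1: off-phase fold stays at the lights-off value
  st1 <- generate_cycle_stack(sched, sc, residual_fraction_per_cycle = 1)
  off1 <- st1$truth[st1$truth$cycle == 1 & st1$truth$state == "off", ]
  expect_equal(diff(range(off1$fold)), 0, tolerance = 1e-12)

  # residual 0.5: end-of-dark ratio strictly between 1 and the light plateau
  st5 <- generate_cycle_stack(sched, sc, k_on = 1 / 30, k_off = 1 / 30,
                              residual_fraction_per_cycle = 0.5)
  tr5 <- st5$truth
  on_end <- tr5[tr5$cycle == 1 & tr5$state == "on", ]
  off_end <- tr5[tr5$cycle == 1 & tr5$state == "off", ]
  pr_on <- on_end$partition_ratio[nrow(on_end)]
  pr_off <- off_end$partition_ratio[nrow(off_end)]
  expect_gt(pr_off, 1)
  expect_lt(pr_off, pr_on)
  # fold-space check of the update rule itself
  f_on <- on_end$fold[nrow(on_end)]
  expect_equal(off_end$fold[nrow(off_end)],
               1 + 0.5 * (f_on - 1) +
                 ((f_on) - (1 + 0.5 * (f_on - 1))) * exp(-600 / 30),
               tolerance = 1e-6)

  expect_error(generate_cycle_stack(light_schedule(600, "on"), sc,
                                    residual_fraction_per_cycle = 2),
               class = "invalid_argument")
})

test_that("luminescence generator: constant limit, cosine amplitude, determinism", {
  flat <- generate_luminescence_trace(mesor = 500, amplitude = 0)
  expect_true(all(flat$counts == 500))

  lt <- generate_luminescence_trace(mesor = 1000, amplitude = 0.3,
                                    period = 24, damping = 0)
  # (max-min)/2 over one full period recovers mesor * amplitude
  expect_equal(pulse_amplitude(lt$times, lt$counts[, 1], c(0, 24)),
               300, tolerance = 0.01 * 300)

  a <- generate_luminescence_trace(noise_sd = 20, seed = 5L)
  b <- generate_luminescence_trace(noise_sd = 20, seed = 5L)
  expect_identical(a$counts, b$counts)
  expect_error(generate_luminescence_trace(period = 0),
               class = "invalid_argument")
})

test_that("Ct tables invert the percent-input equations", {
  tab <- generate_ct_table(enrichments = c(TBS = 8, MC = 1))
  res <- chip_enrichment(tab)
  expect_equal(res$ip_over_input, res$true_enrichment)   # exact, noiseless

  noisy <- generate_ct_table(enrichments = c(TBS = 8), noise_sd = 0.1,
                             n_replicates = 100L, seed = 3L)
  rec <- chip_enrichment(noisy)$ip_over_input
  expect_equal(mean(rec), 8, tolerance = 0.10 * 8)

  expect_error(generate_ct_table(enrichments = c(x = -1)),
               class = "invalid_argument")
})
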