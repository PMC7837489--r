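# synthetic_data: swim simulator, avoidance simulator, qPCR plates, recovery

test_that("simulator is seed-reproducible and order-independent", {
  cfg <- sim_config(seed = 3, frame_rate = 20)
  sched <- build_schedule(data.frame(condition = c("white", "dark"),
                                     duration_s = c(60, 60)))
  t1 <- simulate_trajectory(cfg, sched, subject_index = 2)
  t2 <- simulate_trajectory(cfg, sched, subject_index = 2)
  expect_identical(t1$x_mm, t2$x_mm)
  expect_identical(t1$y_mm, t2$y_mm)
  t3 <- simulate_trajectory(cfg, sched, subject_index = 3)
  expect_false(identical(t1$x_mm, t3$x_mm))

  ev1 <- simulate_avoidance_trial(cfg, trial_plan(), subject_index = 4)
  ev2 <- simulate_avoidance_trial(cfg, trial_plan(), subject_index = 4)
  expect_identical(ev1, ev2)
})

test_that("zero rest-to-move rate means zero distance", {
  cfg <- sim_config(seed = 5, frame_rate = 20,
                    swim = list(rate_on = c(dark = 0, white = 0, blue = 0,
                                            green = 0, red = 0)))
  sched <- build_schedule(data.frame(condition = "white", duration_s = 120))
  tr <- simulate_trajectory(cfg, sched)
  expect_equal(attr(tr, "path_length_mm"), 0)
  expect_true(all(distance_series(tr, 10)$distance_mm == 0))
})

test_that("measured distance matches the closed-form swim expectation", {
  # symmetric rates -> occupancy 1/2, many bouts -> tight Monte-Carlo error;
  # huge arena so wall bounces cannot truncate steps
  cfg <- sim_config(seed = 6, frame_rate = 30, arena_mm = c(1e5, 1e5),
                    swim = list(rate_on = c(dark = 5, white = 5, blue = 5,
                                            green = 5, red = 5),
                                rate_off = 5))
  sched <- build_schedule(data.frame(condition = "white", duration_s = 120))
  n <- 24
  per <- vapply(seq_len(n), function(i) {
    tr <- simulate_trajectory(cfg, sched, subject_index = i)
    d <- sum(distance_series(tr, 10)$distance_mm)
    # conservation: binned total equals the simulated path length (no walls)
    expect_equal(d, attr(tr, "path_length_mm"), tolerance = 1e-9)
    d
  }, numeric(1))
  expected <- swim_expectations(cfg, "white")$distance_rate_mm_s * 120
  se <- sd(per) / sqrt(n)
  expect_lt(abs(mean(per) - expected), 3 * se + 1e-9)
})

test_that("move-state occupancy converges to r_on / (r_on + r_off)", {
  cfg <- sim_config(seed = 7, frame_rate = 10,
                    swim = list(rate_on = c(dark = 0.2, white = 0.6, blue = 0.6,
                                            green = 0.6, red = 0.6),
                                rate_off = 0.8))
  sched <- build_schedule(data.frame(condition = "dark", duration_s = 600))
  n <- 24
  occ <- vapply(seq_len(n), function(i)
    attr(simulate_trajectory(cfg, sched, subject_index = i),
         "moving_time_s") / 600, numeric(1))
  want <- swim_expectations(cfg, "dark")$occupancy
  expect_lt(abs(mean(occ) - want), 3 * sd(occ) / sqrt(n))
})

test_that("genotype multiplier raises activity in every condition", {
  cfg <- sim_config(seed = 8)
  for (cond in c("dark", "white")) {
    wt <- swim_expectations(cfg, cond, "wt")
    mu <- swim_expectations(cfg, cond, "mutant")
    expect_equal(mu$occupancy, wt$occupancy)   # default multiplier is 1
  }
  cfg2 <- sim_config(seed = 8, genotype = list(activity_multiplier = 1.5))
  expect_gt(swim_expectations(cfg2, "dark", "mutant")$occupancy,
            swim_expectations(cfg2, "dark", "wt")$occupancy)
})

test_that("avoidance probabilities are a proper categorical model", {
  cfg <- sim_config()
  pr <- avoidance_probs(cfg, c(5, 10, 20, 30, 40, 60, 80), k = 0)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_equal(rowSums(pr), rep(1, 7))
  expect_true(all(diff(pr$p_avoid) > 0))       # avoidance grows with size
  expect_true(all(diff(pr$p_approach) < 0))    # approach declines with size

  # steep slope limit: step tuning at theta0
  steep <- sim_config(avoidance = list(slope = 200))
  av <- steep$avoidance
  hi <- avoidance_probs(steep, 80, k = 2)
  lo <- avoidance_probs(steep, 5, k = 0)
  expect_equal(hi$p_avoid, av$max_avoid * av$habituation^2, tolerance = 1e-6)
  expect_equal(lo$p_approach, av$max_approach, tolerance = 1e-6)

  # habituation only attenuates avoidance
  pr_k <- avoidance_probs(cfg, 60, k = 3)
  expect_equal(pr_k$p_avoid,
               avoidance_probs(cfg, 60, 0)$p_avoid * cfg$avoidance$habituation^3)
  expect_equal(pr_k$p_approach, avoidance_probs(cfg, 60, 0)$p_approach)
})

test_that("without habituation, presentation order does not matter", {
  cfg <- sim_config(avoidance = list(habituation = 1))
  asc <- expected_avoidance(cfg, trial_plan())
  shuf <- expected_avoidance(cfg, trial_plan(order_mode = "pseudo_random",
                                             seed = 31))
  expect_equal(asc, shuf)
  # with habituation, shuffling shifts the expected curve
  cfg2 <- sim_config(avoidance = list(habituation = 0.8))
  asc2 <- expected_avoidance(cfg2, trial_plan())
  shuf2 <- expected_avoidance(cfg2, trial_plan(order_mode = "pseudo_random",
                                               seed = 31))
  expect_false(isTRUE(all.equal(asc2$expected_ai, shuf2$expected_ai)))
})

test_that("cohort mean AI converges to the closed-form expectation", {
  cfg <- sim_config(seed = 21)
  plan <- trial_plan()
  n <- 100
  ev <- do.call(rbind, lapply(seq_len(n), function(i)
    simulate_avoidance_trial(cfg, plan, paste0("f", i), "wt", i)))
  tc <- tuning_curve(ev)
  want <- expected_avoidance(cfg, plan, "wt")
  expect_equal(tc$size_deg, want$size_deg)
  se <- ifelse(tc$sem > 0, tc$sem, 1 / sqrt(n))
  expect_true(all(abs(tc$mean_ai - want$expected_ai) < 3 * se))
})

test_that("qPCR plates recover the configured fold change", {
  cfg0 <- sim_config(seed = 17, qpcr = list(noise_sd = 0, bio_sd_log2 = 0))
  expr <- data.frame(group = c("wt", "mutant"), gene = "sst1b",
                     expression = c(1, 0.5))
  plate <- simulate_qpcr(cfg0, expr, n_per_group = 3)
  # zero noise: duplicates identical, ddCt exactly +1 for the mutant
  by_rep <- split(plate$ct, paste(plate$sample_id, plate$gene))
  expect_true(all(vapply(by_rep, function(v) diff(range(v)) == 0, logical(1))))
  f <- fold_change(relative_expression(simulate_qpcr(cfg0, expr, 3)), "wt")
  expect_equal(unique(f$fold_change[f$group == "mutant"]), 0.5)

  # with noise: log2 fold recovery is unbiased over replicate plates
  cfg <- sim_config(seed = 18)
  lf <- vapply(seq_len(500), function(i) {
    p <- simulate_qpcr(sim_config(seed = 18 + i), expr, n_per_group = 4)
    fc <- fold_change(relative_expression(p), "wt")
    mean(log2(fc$fold_change[fc$group == "mutant"]))
  }, numeric(1))
  se <- sd(lf) / sqrt(length(lf))
  expect_lt(abs(mean(lf) - log2(0.5)), 3 * se)
})

test_that("recovery_experiment estimates ratio and power sensibly", {
  short <- build_schedule(data.frame(condition = c("white", "dark"),
                                     duration_s = c(1800, 1800)),
                          repeats = 1, acclimation_s = 300)
  cfg <- sim_config(seed = 9, frame_rate = 5)
  r <- recovery_experiment(cfg, n_cohorts = 20, n_per_group = 8,
                           multiplier = 1.3, schedule = short)
  expect_equal(r$true_ratio,
               (1.3 * 0.04 / (1.3 * 0.04 + 1)) / (0.04 / 1.04))
  expect_lt(abs(r$ratio_estimate - r$true_ratio), 0.1)
  expect_gte(r$power, 0)

  # power grows with group size (small multiplier so it is not saturated)
  r_small <- recovery_experiment(cfg, n_cohorts = 25, n_per_group = 3,
                                 multiplier = 1.15, schedule = short)
  r_big <- recovery_experiment(cfg, n_cohorts = 25, n_per_group = 24,
                               multiplier = 1.15, schedule = short)
  expect_gte(r_big$power, r_small$power)
})
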