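test_that("default cohort matches the study design: 10 RYGB + 7 OAGB, two periods", {
  coh <- generate_cohort(sim_config(days = 1, seed = 3))
  tt <- cohort_truth(coh)
  counts <- table(tt$group, tt$period)
  expect_equal(unname(counts["RYGB", "pre"]), 10)
  expect_equal(unname(counts["RYGB", "post"]), 10)
  expect_equal(unname(counts["OAGB", "pre"]), 7)
  expect_equal(unname(counts["OAGB", "post"]), 7)
  # every trace has the configured length
  expect_true(all(vapply(coh$patients, function(p)
    length(p$trace$time), 0L) == 96L))
  # reported meals correspond one-to-one with true times
  expect_true(all(vapply(coh$patients, function(p)
    nrow(p$meals) == length(p$true_times), TRUE)))
})

test_that("cohort generation is deterministic given the seed", {
  cfg <- sim_config(n_patients_per_group = c(RYGB = 2, OAGB = 2), days = 1,
                    seed = 11)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  coh3 <- generate_cohort(cfg, seed = 12)
  expect_false(identical(generate_cohort(cfg), coh3))
})

test_that("degenerate hierarchy: zero between-patient spread returns the group means", {
  cfg <- sim_config(n_patients_per_group = c(RYGB = 3), days = 1,
                    beta_rel_sd = 0, alpha_log_sd = 0, baseline_sd = 0,
                    group_beta_mean = rbind(RYGB = c(pre = 0.05, post = 0.08)),
                    group_alpha_mean = rbind(RYGB = c(pre = 20, post = 18)),
                    seed = 2)
  tt <- cohort_truth(generate_cohort(cfg))
  expect_equal(tt$beta[tt$period == "pre"], rep(0.05, 3))
  expect_equal(tt$beta[tt$period == "post"], rep(0.08, 3))
  expect_equal(tt$alpha[tt$period == "post"], rep(18, 3))
})

test_that("config invariants are validated", {
  expect_error(sim_config(days = 0), "days")
  expect_error(sim_config(sample_interval = 17), "integer number")
  expect_error(sim_config(carb_range = c(60, 10)), "low")
  expect_error(sim_config(baseline_mean = -1), "positive")
  expect_error(sim_config(noise_sd = -0.1), ">= 0")
})

test_that("simulated trace is baseline plus carb-scaled bumps", {
  grid <- seq(0, 1440 - 15, by = 15)
  pp <- patient_params(0.086, 19.6, 5.3, 0, offsets = 0)
  # no meals, no noise: constant at baseline
  flat <- simulate_trace(patient_params(0.086, 19.6, 5.3, 0),
                         data.frame(time = numeric(), carbs = numeric()),
                         grid)
  expect_equal(flat$glucose, rep(5.3, length(grid)))
  # one 30 g meal: peak excess = beta * carbs at the meal time
  tr <- simulate_trace(pp, data.frame(time = 600, carbs = 30), grid)
  excess <- tr$glucose - 5.3
  expect_equal(max(excess), 0.086 * 30, tolerance = 1e-12)
  expect_equal(grid[which.max(excess)], 600)
  expect_error(simulate_trace(pp, data.frame(time = 600, carbs = 30),
                              numeric()), "empty")
})

test_that("observation noise has the configured spread", {
  grid <- seq(0, 10000 * 15 - 1, by = 15)[1:10000]
  pp <- patient_params(0.05, 20, 5.3, 0.3)
  tr <- simulate_trace(pp, data.frame(time = numeric(), carbs = numeric()),
                       grid, seed = 99)
  expect_equal(sd(tr$glucose - 5.3), 0.3, tolerance = 0.05 * 0.3)
})

test_that("meal-time jitter: identity at sd 0, seeded, correct spread", {
  tt <- c(100, 300, 700)
  expect_identical(jitter_meal_times(tt, 0), tt)
  expect_identical(jitter_meal_times(tt, 10, seed = 5),
                   jitter_meal_times(tt, 10, seed = 5))
  expect_error(jitter_meal_times(tt, -1), "non-negative")
  big <- jitter_meal_times(seq_len(10000) * 500, 15, seed = 7)
  expect_equal(sd(big - seq_len(10000) * 500), 15, tolerance = 0.05 * 15)
})

test_that("superposition: coincident meals sum their carbohydrates", {
  grid <- seq(0, 1440 - 15, by = 15)
  pp2 <- patient_params(0.06, 22, 5.0, 0, offsets = c(0, 0))
  pp1 <- patient_params(0.06, 22, 5.0, 0, offsets = 0)
  two <- simulate_trace(pp2, data.frame(time = c(480, 480), carbs = c(20, 35)),
                        grid)
  one <- simulate_trace(pp1, data.frame(time = 480, carbs = 55), grid)
  expect_equal(two$glucose, one$glucose, tolerance = 1e-12)
})

test_that("noise-free simulation agrees with the model mean curve pointwise", {
  for (s in 1:3) {
    fx <- make_dataset(noise = 0, seed = s, days = 2)
    expect_equal(fx$dataset$glucose,
                 predict_mean(fx$params,
                              data.frame(time = fx$true_times,
                                         carbs = fx$dataset$meals$carbs),
                              fx$dataset$times),
                 tolerance = 1e-12)
  }
})

test_that("cohort fixture files round-trip through the readers", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(sim_config(n_patients_per_group = c(RYGB = 2),
                                    days = 1, report_jitter_sd = 0, seed = 8))
  paths <- write_cohort(coh, dir)
  expect_true(all(file.exists(paths)))
  traces <- read_cgm_csv(paths["cgm"])
  expect_length(traces, 4)  # 2 patients x 2 periods
  expect_equal(traces[["RYGB01.pre"]]$glucose,
               coh$patients[["RYGB01.pre"]]$trace$glucose,
               tolerance = 1e-9)
  truth_lines <- readLines(paths["truth"])
  expect_true(any(grepl("^RYGB01.pre.beta = ", truth_lines)))
})
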