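# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# one patient-period dataset with known generating parameters
make_dataset <- function(beta = 0.08, alpha = 20, baseline = 5.2,
                         noise = 0.3, days = 3, meals_per_day = 4,
                         jitter = 0, seed = 1, patient_id = "P1",
                         interval = 15) {
  set.seed(seed)
  grid <- seq(0, days * 1440 - interval, by = interval)
  tt <- unlist(lapply(seq_len(days) - 1, function(d)
    d * 1440 + sort(stats::runif(meals_per_day, 7 * 60, 21 * 60))))
  carbs <- stats::runif(length(tt), 20, 60)
  pp <- patient_params(beta, alpha, baseline, max(noise, 1e-12),
                       offsets = rep(0, length(tt)))
  mu <- predict_mean(pp, data.frame(time = tt, carbs = carbs), grid)
  y <- mu + if (noise > 0) stats::rnorm(length(grid), 0, noise) else 0
  reported <- jitter_meal_times(tt, jitter)
  list(dataset = structure(list(patient_id = patient_id, period = "pre",
                                times = grid, glucose = y,
                                meals = data.frame(time = reported,
                                                   carbs = carbs),
                                days = days, window_start = NULL),
                           class = "analysis_dataset"),
       true_times = tt, params = pp)
}

# random small instance for density-oracle checks
random_instance <- function(seed) {
  set.seed(seed)
  n_meals <- sample(1:3, 1)
  n_obs <- sample(5:15, 1)
  times <- sort(stats::runif(n_obs, 0, 600))
  meals <- data.frame(time = stats::runif(n_meals, 0, 600),
                      carbs = stats::runif(n_meals, 5, 80))
  params <- patient_params(beta = stats::runif(1, 0.01, 0.12),
                           alpha = stats::runif(1, 10, 40),
                           baseline = stats::runif(1, 4, 7),
                           noise_sd = stats::runif(1, 0.1, 0.8),
                           offsets = stats::runif(n_meals, -30, 30))
  mu <- predict_mean(params, meals, times)
  glucose <- mu + stats::rnorm(n_obs, 0, 0.5)
  glucose[sample(n_obs, 1)] <- NA  # readers must skip missing samples
  group <- group_params(beta_g = stats::runif(1, 0.02, 0.1),
                        alpha_g = stats::runif(1, 15, 30),
                        sd_beta = stats::runif(1, 0.005, 0.05),
                        sd_alpha = stats::runif(1, 0.1, 0.6),
                        jitter_sd = stats::runif(1, 5, 25))
  dataset <- structure(list(patient_id = "X", period = "pre",
                            times = times, glucose = glucose,
                            meals = meals, days = 1, window_start = NULL),
                       class = "analysis_dataset")
  list(params = params, group = group, dataset = dataset)
}

# a cgm_fit shell around given draws, for summary/curve unit tests
make_fake_fit <- function(draws_matrix, chains = 1) {
  nm <- colnames(draws_matrix)
  structure(list(draws = rep(list(draws_matrix), chains),
                 diagnostics = data.frame(parameter = nm,
                                          rhat = NA_real_, ess = NA_real_),
                 patients = unique(stats::na.omit(
                   sub("^[^\\[]+\\[([^],]+).*$", "\\1",
                       nm[grepl("\\[", nm)]))),
                 control = mcmc_control(chains = chains,
                                        iter = max(1L, nrow(draws_matrix)),
                                        on_fail = "none"),
                 converged = TRUE),
            class = "cgm_fit")
}

fast_control <- function(...) {
  mcmc_control(chains = 2, warmup = 400, iter = 400, on_fail = "none", ...)
}
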