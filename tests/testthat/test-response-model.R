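test_that("response basis is a unit-peak symmetric bump with the stated width", {
  expect_equal(response_basis(60, 60, 20), 1.0)
  expect_equal(response_basis(80, 60, 20), exp(-0.5))
  for (x in c(1, 7.5, 33, 120))
    expect_equal(response_basis(60 + x, 60, 17),
                 response_basis(60 - x, 60, 17))
  expect_error(response_basis(0, 0, 0), "alpha")
  expect_error(response_basis(0, 0, -5), "alpha")
})

test_that("mean curve is baseline plus linear carb-scaled bumps", {
  grid <- seq(0, 720, by = 5)
  p0 <- patient_params(0.086, 19.6, 5.3, 0.3)
  expect_equal(predict_mean(p0, data.frame(time = numeric(),
                                           carbs = numeric()), grid),
               rep(5.3, length(grid)))
  p1 <- patient_params(0.086, 19.6, 5.3, 0.3, offsets = 0)
  meals <- data.frame(time = 360, carbs = 30)
  mu <- predict_mean(p1, meals, grid)
  expect_equal(max(mu - 5.3), 0.086 * 30)
  # linear in carbs: doubling doubles the excess pointwise
  mu2 <- predict_mean(p1, data.frame(time = 360, carbs = 60), grid)
  expect_equal(mu2 - 5.3, 2 * (mu - 5.3), tolerance = 1e-12)
  # offset count must match meal count
  expect_error(predict_mean(p1, data.frame(time = c(100, 300),
                                           carbs = c(10, 10)), grid),
               "offsets")
})

test_that("increasing one meal's carbs never lowers the curve", {
  set.seed(42)
  for (k in 1:10) {
    grid <- seq(0, 1440, by = 15)
    m <- data.frame(time = runif(3, 0, 1440), carbs = runif(3, 5, 50))
    p <- patient_params(runif(1, 0.02, 0.1), runif(1, 12, 30), 5,
                        0.3, offsets = rnorm(3, 0, 10))
    m2 <- m
    j <- sample(3, 1)
    m2$carbs[j] <- m2$carbs[j] + runif(1, 1, 30)
    expect_true(all(predict_mean(p, m2, grid) >= predict_mean(p, m, grid)))
  }
})

test_that("log-likelihood matches its closed form and a brute-force oracle", {
  # zero residuals: -(N/2) log(2 pi sigma^2)
  fx <- make_dataset(noise = 0, seed = 4)
  pp <- fx$params
  pp$offsets <- fx$true_times - fx$dataset$meals$time
  N <- length(fx$dataset$times)
  expect_equal(log_likelihood(pp, fx$dataset),
               -(N / 2) * log(2 * pi * pp$noise_sd^2))
  # brute-force pointwise oracle on random instances
  for (s in 1:25) {
    inst <- random_instance(s)
    keep <- !is.na(inst$dataset$glucose)
    oracle <- 0
    for (i in which(keep)) {
      mu_i <- inst$params$baseline
      for (m in seq_len(nrow(inst$dataset$meals)))
        mu_i <- mu_i + inst$params$beta * inst$dataset$meals$carbs[m] *
          exp(-(inst$dataset$times[i] - inst$dataset$meals$time[m] -
                  inst$params$offsets[m])^2 / (2 * inst$params$alpha^2))
      r <- inst$dataset$glucose[i] - mu_i
      oracle <- oracle - 0.5 * log(2 * pi * inst$params$noise_sd^2) -
        r^2 / (2 * inst$params$noise_sd^2)
    }
    expect_equal(log_likelihood(inst$params, inst$dataset), oracle,
                 tolerance = 1e-9)
  }
  # enlarging one residual strictly decreases the value
  inst <- random_instance(99)
  worse <- inst$dataset
  i <- which(!is.na(worse$glucose))[1]
  worse$glucose[i] <- worse$glucose[i] + 5
  expect_lt(log_likelihood(inst$params, worse),
            log_likelihood(inst$params, inst$dataset))
  bad <- inst$params; bad$noise_sd <- 0
  expect_error(log_likelihood(bad, inst$dataset), "noise_sd")
})

test_that("log-posterior equals likelihood plus independently coded priors", {
  prior <- prior_config()
  for (s in 1:25) {
    inst <- random_instance(s + 500)
    g <- inst$group; p <- inst$params
    jit <- g$jitter_sd
    prior_oracle <-
      dnorm(p$beta, g$beta_g, g$sd_beta, log = TRUE) -
        pnorm(g$beta_g / g$sd_beta, log.p = TRUE) +
      dlnorm(p$alpha, log(g$alpha_g), g$sd_alpha, log = TRUE) +
      dnorm(p$baseline, prior$baseline_loc, prior$baseline_scale, log = TRUE) -
        pnorm(prior$baseline_loc / prior$baseline_scale, log.p = TRUE) +
      log(2) + dnorm(p$noise_sd, 0, prior$noise_scale, log = TRUE) +
      sum(dnorm(p$offsets, 0, jit, log = TRUE) -
            log(pnorm(prior$offset_max / jit) -
                  pnorm(-prior$offset_max / jit))) +
      dnorm(g$beta_g, prior$beta_g_loc, prior$beta_g_scale, log = TRUE) -
        pnorm(prior$beta_g_loc / prior$beta_g_scale, log.p = TRUE) +
      dlnorm(g$alpha_g, log(prior$alpha_g_loc), prior$alpha_g_scale,
             log = TRUE) +
      log(2) + dnorm(g$sd_beta, 0, prior$sd_beta_scale, log = TRUE) +
      log(2) + dnorm(g$sd_alpha, 0, prior$sd_alpha_scale, log = TRUE)
    expect_equal(log_posterior(inst$params, inst$group, prior, inst$dataset),
                 log_likelihood(inst$params, inst$dataset) + prior_oracle,
                 tolerance = 1e-9)
  }
})

test_that("log-posterior support handling: -Inf sentinel and offset mode at zero", {
  inst <- random_instance(7)
  prior <- prior_config()
  bad <- inst$params; bad$beta <- -0.01
  expect_identical(log_posterior(bad, inst$group, prior, inst$dataset), -Inf)
  bad <- inst$params; bad$offsets[1] <- 1000
  expect_identical(log_posterior(bad, inst$group, prior, inst$dataset), -Inf)
  # zero offsets maximize the offset-prior term (likelihood held fixed by
  # comparing pure prior contributions)
  lp0 <- log_posterior(inst$params, inst$group, prior, inst$dataset)
  shifted <- inst$params
  shifted$offsets <- inst$params$offsets * 0
  lp_zero <- log_posterior(shifted, inst$group, prior, inst$dataset)
  prior_term <- function(off) sum(dnorm(off, 0, inst$group$jitter_sd,
                                        log = TRUE))
  expect_gte(prior_term(shifted$offsets), prior_term(inst$params$offsets))
  expect_true(is.finite(lp0) && is.finite(lp_zero))
})

test_that("posterior summaries follow the fixed quantile rule", {
  m <- cbind("beta_g" = rep(2.5, 100), "beta[P1]" = as.numeric(1:100))
  fit <- make_fake_fit(m)
  s <- summarize_posterior(fit)
  expect_equal(nrow(s), 2)
  expect_equal(s$mean[s$parameter == "beta_g"], 2.5)
  expect_equal(s$q2.5[s$parameter == "beta_g"], 2.5)
  expect_equal(s$q97.5[s$parameter == "beta_g"], 2.5)
  # draws 1..100 under type-7 interpolation
  expect_equal(s$q2.5[s$parameter == "beta[P1]"], 3.475)
  expect_equal(s$q97.5[s$parameter == "beta[P1]"], 97.525)
  expect_equal(s$patient, c(NA, "P1"))
})

test_that("summary has one row per patient per parameter", {
  ids <- sprintf("P%02d", 1:10)
  nm <- c("beta_g", "alpha_g", "sd_beta", "sd_alpha",
          as.vector(vapply(ids, function(id)
            sprintf(c("beta[%s]", "alpha[%s]", "baseline[%s]", "sigma[%s]"),
                    id), character(4))))
  m <- matrix(rnorm(20 * length(nm)), 20, dimnames = list(NULL, nm))
  s <- summarize_posterior(make_fake_fit(m))
  expect_equal(sum(grepl("^beta\\[", s$parameter)), 10)
  expect_true(all(s$q2.5 <= s$mean & s$mean <= s$q97.5))
  expect_error(summarize_posterior(make_fake_fit(m[0, , drop = FALSE])),
               "draws")
})

test_that("variance explained matches its formula and edge cases", {
  obs <- c(5, 6, 4, 7, 5.5)
  expect_equal(variance_explained(obs, obs), 100)
  expect_equal(variance_explained(obs, rep(mean(obs), 5)), 0)
  set.seed(31)
  for (k in 1:10) {
    o <- rnorm(20, 5, 1); f <- o + rnorm(20, 0, 0.7)
    expect_equal(variance_explained(o, f),
                 max(0, 100 * (1 - var(o - f) / var(o))), tolerance = 1e-9)
  }
  expect_error(variance_explained(rep(5, 4), rep(5, 4)), "zero variance")
  expect_error(variance_explained(1:3, 1:4), "equal length")
})

test_that("population curve reduces to closed forms at point-mass posteriors", {
  pm <- function(beta, alpha) make_fake_fit(
    cbind(beta_g = rep(beta, 50), alpha_g = rep(alpha, 50)))
  grid <- seq(-200, 200, by = 0.5)
  hi <- population_response_curve(pm(0.086, 19.6), carbs = 1, grid = grid)
  lo <- population_response_curve(pm(0.046, 22.8), carbs = 1, grid = grid)
  # peak at t=0 equals beta_g
  expect_equal(hi$mean[grid == 0], 0.086)
  expect_equal(lo$mean[grid == 0], 0.046)
  expect_gt(hi$mean[grid == 0], lo$mean[grid == 0])
  # areas behave like beta * alpha * sqrt(2 pi)
  area <- function(cv) sum(cv$mean) * 0.5
  expect_equal(area(hi), 0.086 * 19.6 * sqrt(2 * pi), tolerance = 1e-3)
  expect_equal(area(hi) / area(lo),
               (0.086 * 19.6) / (0.046 * 22.8), tolerance = 1e-3)
  expect_error(population_response_curve(pm(0.05, 20), carbs = -1), "carbs")
})
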