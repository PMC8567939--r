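#' Simulation configuration for a synthetic CGM cohort
#'
#' Defines the study design the generator emulates: two surgery groups
#' (RYGB, n = 10; OAGB, n = 7), each patient measured in a `pre` and a
#' `post` period, with a 3-day food diary and a 15-minute CGM grid per
#' period. Group-level response means default to the estimated
#' pre/post-operative values for the two procedures: beta (mmol/l per g)
#' 0.046 -> 0.086 in RYGB and 0.034 -> 0.088 in OAGB; alpha (minutes)
#' 22.80 -> 19.60 and 20.56 -> 18.33.
#'
#' @param n_patients_per_group Named integer vector, patients per group.
#' @param days Recording days per period.
#' @param sample_interval CGM sampling interval, minutes; must divide a
#'   day into an integer number of samples.
#' @param meals_per_day Meals per diary day.
#' @param carb_range Length-2 numeric, grams: meal carbs are uniform in
#'   this range.
#' @param group_beta_mean,group_alpha_mean Matrices (groups x periods
#'   `pre`,`post`) of group mean beta (mmol/l/g) and alpha (min).
#' @param baseline_mean,baseline_sd Between-meal baseline distribution,
#'   mmol/l.
#' @param noise_sd Observation noise sd, mmol/l.
#' @param report_jitter_sd Sd (minutes) of Gaussian reporting error added
#'   to true meal times.
#' @param beta_rel_sd Between-patient sd of beta as a fraction of the
#'   group mean (truncated-at-zero normal).
#' @param alpha_log_sd Between-patient sd of log alpha.
#' @param clip_floor Sensor floor, mmol/l: simulated values are clipped
#'   from below to mimic the device range.
#' @param waking Length-2 numeric, minutes from midnight: meals are
#'   placed inside this daily window.
#' @param min_gap Minimum spacing between meals, minutes.
#' @param seed Integer seed making the cohort reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients_per_group = c(RYGB = 10, OAGB = 7),
                       days = 3, sample_interval = 15, meals_per_day = 5,
                       carb_range = c(10, 60),
                       group_beta_mean = rbind(RYGB = c(pre = 0.046, post = 0.086),
                                               OAGB = c(pre = 0.034, post = 0.088)),
                       group_alpha_mean = rbind(RYGB = c(pre = 22.80, post = 19.60),
                                                OAGB = c(pre = 20.56, post = 18.33)),
                       baseline_mean = 5.3, baseline_sd = 0.4,
                       noise_sd = 0.3, report_jitter_sd = 15,
                       beta_rel_sd = 0.3, alpha_log_sd = 0.15,
                       clip_floor = 2.2,
                       waking = c(7 * 60, 21 * 60), min_gap = 90,
                       seed = 1L) {
  n_patients_per_group <- unlist(n_patients_per_group)
  if (is.null(names(n_patients_per_group)) ||
      any(!nzchar(names(n_patients_per_group))))
    stop("`n_patients_per_group` must be named by group label", call. = FALSE)
  if (any(n_patients_per_group < 1))
    stop("each group needs at least one patient", call. = FALSE)
  carb_range <- unlist(carb_range)
  waking <- unlist(waking)
  if (days < 1) stop("`days` must be >= 1", call. = FALSE)
  if (1440 %% sample_interval != 0)
    stop("`sample_interval` must divide 24 h into an integer number of samples",
         call. = FALSE)
  if (carb_range[1] > carb_range[2])
    stop("`carb_range` low must be <= high", call. = FALSE)
  pos <- c(sample_interval, meals_per_day, unlist(group_beta_mean),
           unlist(group_alpha_mean), baseline_mean)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("scale parameters must be strictly positive", call. = FALSE)
  if (noise_sd < 0 || report_jitter_sd < 0 || beta_rel_sd < 0 ||
      alpha_log_sd < 0 || baseline_sd < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  if ((meals_per_day - 1) * min_gap >= diff(waking))
    stop("waking window too short for `meals_per_day` at `min_gap`",
         call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

#' Gaussian reporting error on meal times
#'
#' Adds independent Normal(0, `sd`^2) noise to each true meal time,
#' emulating the error in self-reported diary timings. The output order
#' is as drawn (jitter can reorder meals).
#'
#' @param true_times Numeric vector of true meal times (minutes).
#' @param sd Reporting error sd, minutes (>= 0).
#' @param seed Optional integer seed.
#' @return Numeric vector of reported times.
#' @export
jitter_meal_times <- function(true_times, sd, seed = NULL) {
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0)
    stop("`sd` must be a single non-negative number", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  true_times + stats::rnorm(length(true_times), 0, sd)
}

#' Simulate one CGM trace from known parameters
#'
#' Forward model: glucose at time t is the patient's constant baseline
#' plus one Gaussian response bump per meal, scaled by beta times the
#' meal's carbohydrate grams, plus iid Normal(0, `params$noise_sd`^2)
#' observation noise, clipped below at the sensor floor. With
#' `noise_sd = 0` the trace is the exact mean curve.
#'
#' @param params A [patient_params()] object; `params$offsets` are
#'   applied to the meal times as in [predict_mean()].
#' @param meals Data frame with `time` (true meal times, minutes) and
#'   `carbs` (grams).
#' @param grid Strictly increasing numeric vector of sample times
#'   (minutes).
#' @param seed Optional integer seed.
#' @param patient_id,period Labels for the returned trace.
#' @param clip_floor Sensor floor, mmol/l.
#' @param origin Timestamp of `grid = 0`.
#' @return A [glucose_trace()].
#' @export
simulate_trace <- function(params, meals, grid, seed = NULL,
                           patient_id = "sim", period = "pre",
                           clip_floor = 2.2, origin = .cgm_origin()) {
  if (length(grid) == 0) stop("empty time grid", call. = FALSE)
  if (any(diff(grid) <= 0)) stop("`grid` must be strictly increasing", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mu <- predict_mean(params, meals, grid)
  y <- if (params$noise_sd > 0)
    mu + stats::rnorm(length(grid), 0, params$noise_sd) else mu
  y <- pmax(y, clip_floor)
  glucose_trace(patient_id, period, grid, y, nominal_interval = diff(grid[1:2]),
                origin = origin)
}

# k meal times uniform in [waking] with pairwise gaps >= min_gap:
# uniform order statistics on the gap-shrunk window, then re-inflated.
.draw_meal_times <- function(k, waking, min_gap) {
  w <- diff(waking) - (k - 1) * min_gap
  sort(stats::runif(k, 0, w)) + waking[1] + (seq_len(k) - 1) * min_gap
}

.rnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
  x
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws per-patient parameters around the configured group means
#' (truncated-normal beta, log-normal alpha, normal baseline), places
#' meals uniformly inside waking hours with a minimum gap, simulates the
#' CGM trace per patient-period via [simulate_trace()], and jitters the
#' true meal times into reported diary times via [jitter_meal_times()].
#' The true parameters and true meal times are retained, so parameter
#' recovery can be scored exactly.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer overriding `config$seed`.
#' @return An object of class `cgm_cohort`: list with `config` and
#'   `patients`, one entry per patient-period carrying `patient_id`,
#'   `group`, `period`, true `params` ([patient_params()], with `offsets`
#'   equal to true minus reported time), `true_times`, reported `meals`,
#'   and the simulated `trace`.
#' @seealso [cohort_datasets()], [cohort_truth()], [write_cohort()]
#' @export
generate_cohort <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(if (is.null(seed)) config$seed else seed)
  grid <- seq(0, config$days * 1440 - config$sample_interval,
              by = config$sample_interval)
  patients <- list()
  for (g in names(config$n_patients_per_group)) {
    ng <- config$n_patients_per_group[[g]]
    for (i in seq_len(ng)) {
      pid <- sprintf("%s%02d", g, i)
      for (per in c("pre", "post")) {
        bm <- config$group_beta_mean[g, per]
        am <- config$group_alpha_mean[g, per]
        beta <- .rnorm_pos(1, bm, config$beta_rel_sd * bm)
        alpha <- stats::rlnorm(1, log(am), config$alpha_log_sd)
        baseline <- .rnorm_pos(1, config$baseline_mean, config$baseline_sd)
        true_times <- unlist(lapply(seq_len(config$days) - 1, function(d)
          d * 1440 + .draw_meal_times(config$meals_per_day, config$waking,
                                      config$min_gap)))
        carbs <- stats::runif(length(true_times), config$carb_range[1],
                              config$carb_range[2])
        reported <- jitter_meal_times(true_times, config$report_jitter_sd)
        # latent offsets satisfy true = reported + offset
        params <- patient_params(beta, alpha, baseline, config$noise_sd,
                                 offsets = true_times - reported)
        origin <- .cgm_origin() + if (per == "post") 30 * 86400 else 0
        trace <- simulate_trace(params, data.frame(time = true_times,
                                                   carbs = carbs),
                                grid, patient_id = pid, period = per,
                                clip_floor = config$clip_floor,
                                origin = origin)
        patients[[paste(pid, per, sep = ".")]] <-
          list(patient_id = pid, group = g, period = per, params = params,
               true_times = true_times,
               meals = data.frame(time = reported, carbs = carbs),
               trace = trace)
      }
    }
  }
  structure(list(config = config, patients = patients), class = "cgm_cohort")
}

#' @export
print.cgm_cohort <- function(x, ...) {
  pid <- vapply(x$patients, `[[`, "", "patient_id")
  grp <- vapply(x$patients, `[[`, "", "group")
  cat("<cgm_cohort>", length(unique(pid)), "patients (",
      paste(sprintf("%s: %d", unique(grp),
                    vapply(unique(grp), function(g)
                      length(unique(pid[grp == g])), 0L)), collapse = ", "),
      ") x 2 periods,", x$config$days, "days at",
      x$config$sample_interval, "min\n")
  invisible(x)
}

#' Ground-truth parameter table of a synthetic cohort
#'
#' @param cohort A [generate_cohort()] result.
#' @return Data frame: patient_id, group, period, true beta, alpha,
#'   baseline, noise_sd.
#' @export
cohort_truth <- function(cohort) {
  do.call(rbind, lapply(cohort$patients, function(p)
    data.frame(patient_id = p$patient_id, group = p$group, period = p$period,
               beta = p$params$beta, alpha = p$params$alpha,
               baseline = p$params$baseline, noise_sd = p$params$noise_sd,
               row.names = NULL)))
}

#' Analysis datasets for one group and period of a cohort
#'
#' Packages the simulated traces and reported diaries into the
#' `analysis_dataset` form that [fit_response_model()] consumes (one per
#' patient), without a round trip through CSV files.
#'
#' @param cohort A [generate_cohort()] result.
#' @param group Group label, e.g. `"RYGB"`.
#' @param period `"pre"` or `"post"`.
#' @return Named list of `analysis_dataset` objects.
#' @export
cohort_datasets <- function(cohort, group, period) {
  sel <- Filter(function(p) p$group == group && p$period == period,
                cohort$patients)
  if (!length(sel)) stop("no patients for ", group, "/", period, call. = FALSE)
  out <- lapply(sel, function(p)
    structure(list(patient_id = p$patient_id, period = p$period,
                   times = p$trace$time, glucose = p$trace$glucose,
                   meals = p$meals, days = cohort$config$days,
                   window_start = p$trace$origin),
              class = "analysis_dataset"))
  names(out) <- vapply(sel, `[[`, "", "patient_id")
  out
}

#' Write a synthetic cohort to fixture files
#'
#' Writes the CGM CSV, the diary CSV and a plain-text ground-truth
#' sidecar (`key = value` lines) into a directory.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cgm <- file.path(dir, "cgm.csv")
  diary <- file.path(dir, "diary.csv")
  truth <- file.path(dir, "truth.txt")
  write_cgm_csv(lapply(cohort$patients, `[[`, "trace"), cgm)
  rows <- do.call(rbind, lapply(cohort$patients, function(p) {
    data.frame(patient_id = p$patient_id, period = p$period,
               timestamp = .fmt_ts(p$trace$origin, p$meals$time),
               item = "meal", carbs_g = p$meals$carbs)
  }))
  utils::write.csv(rows, diary, row.names = FALSE, quote = FALSE)
  tt <- cohort_truth(cohort)
  lines <- unlist(lapply(seq_len(nrow(tt)), function(i)
    sprintf("%s.%s.%s = %.10g", tt$patient_id[i], tt$period[i],
            c("beta", "alpha", "baseline"),
            c(tt$beta[i], tt$alpha[i], tt$baseline[i]))))
  writeLines(c(sprintf("seed = %d", cohort$config$seed), lines), truth)
  invisible(c(cgm = cgm, diary = diary, truth = truth))
}
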