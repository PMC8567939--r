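#' Patient-level parameter set
#'
#' Container for one patient-period's model parameters: the response
#' height per carbohydrate gram `beta` (mmol/l per g, >= 0), the response
#' length-scale `alpha` (minutes, > 0), the constant between-meal
#' `baseline` (mmol/l, > 0), the observation `noise_sd` (mmol/l, > 0) and
#' one latent meal-time offset per meal (`offsets`, minutes; the latent
#' meal time is reported time + offset).
#'
#' @param beta,alpha,baseline,noise_sd Scalars as described above.
#' @param offsets Numeric vector of per-meal offsets (minutes); default
#'   none (use `rep(0, n_meals)` for a meals-at-reported-times curve).
#' @return An object of class `patient_params`.
#' @export
patient_params <- function(beta, alpha, baseline, noise_sd = 0.3,
                           offsets = numeric()) {
  stopifnot(is.numeric(beta), is.numeric(alpha), is.numeric(baseline),
            is.numeric(noise_sd), is.numeric(offsets))
  structure(list(beta = beta, alpha = alpha, baseline = baseline,
                 noise_sd = noise_sd, offsets = offsets),
            class = "patient_params")
}

#' Group-level (population) parameter set
#'
#' Population mean response height `beta_g` and length-scale `alpha_g`,
#' between-patient spreads `sd_beta` (sd of the truncated-normal beta
#' hierarchy, mmol/l/g) and `sd_alpha` (sd of log alpha), and the prior
#' sd of the latent meal-time offsets `jitter_sd` (minutes).
#'
#' @param beta_g,alpha_g,sd_beta,sd_alpha,jitter_sd Scalars, positive.
#' @return An object of class `group_params`.
#' @export
group_params <- function(beta_g, alpha_g, sd_beta, sd_alpha,
                         jitter_sd = 20) {
  structure(list(beta_g = beta_g, alpha_g = alpha_g, sd_beta = sd_beta,
                 sd_alpha = sd_alpha, jitter_sd = jitter_sd),
            class = "group_params")
}

#' Prior configuration for the hierarchical model
#'
#' Weakly informative defaults centred on the magnitudes CGM data show in
#' non-diabetic adults: population response height `beta_g` ~
#' Normal(0.05, 0.05^2) truncated at zero (mmol/l per g), population
#' length-scale `alpha_g` ~ LogNormal(log 20, 0.5^2) minutes, baselines ~
#' Normal(5.3, 1.0^2) mmol/l truncated at zero, observation noise sd ~
#' half-Normal(1.0) mmol/l, between-patient spreads `sd_beta` ~
#' half-Normal(0.05) and `sd_alpha` (on log alpha) ~ half-Normal(0.5).
#' Latent meal-time offsets have prior Normal(0, `jitter_sd`^2) truncated
#' to +/- `offset_max` minutes.
#'
#' @param beta_g_loc,beta_g_scale Truncated-normal hyperprior for `beta_g`.
#' @param alpha_g_loc,alpha_g_scale Log-normal hyperprior for `alpha_g`:
#'   median (minutes) and sd on the log scale.
#' @param baseline_loc,baseline_scale Truncated-normal prior for baselines.
#' @param noise_scale Half-normal scale for the observation noise sd.
#' @param sd_beta_scale,sd_alpha_scale Half-normal scales for the
#'   between-patient spreads.
#' @param jitter_sd Prior sd (minutes) of the latent meal-time offsets;
#'   `0` fixes all offsets at zero (meals at reported times).
#' @param offset_max Hard truncation (minutes) for the offsets.
#' @return An object of class `prior_config`.
#' @export
prior_config <- function(beta_g_loc = 0.05, beta_g_scale = 0.05,
                         alpha_g_loc = 20, alpha_g_scale = 0.5,
                         baseline_loc = 5.3, baseline_scale = 1.0,
                         noise_scale = 1.0,
                         sd_beta_scale = 0.05, sd_alpha_scale = 0.5,
                         jitter_sd = 20, offset_max = 60) {
  scales <- c(beta_g_scale, alpha_g_scale, baseline_scale, noise_scale,
              sd_beta_scale, sd_alpha_scale, offset_max)
  if (any(!is.finite(scales)) || any(scales <= 0))
    stop("prior scales must be positive and finite", call. = FALSE)
  if (jitter_sd < 0) stop("`jitter_sd` must be >= 0", call. = FALSE)
  structure(list(beta_g_loc = beta_g_loc, beta_g_scale = beta_g_scale,
                 alpha_g_loc = alpha_g_loc, alpha_g_scale = alpha_g_scale,
                 baseline_loc = baseline_loc, baseline_scale = baseline_scale,
                 noise_scale = noise_scale,
                 sd_beta_scale = sd_beta_scale, sd_alpha_scale = sd_alpha_scale,
                 jitter_sd = jitter_sd, offset_max = offset_max),
            class = "prior_config")
}

#' Gaussian observation log-likelihood of one patient-period
#'
#' Sum over the non-missing CGM samples of the Normal log-density of
#' (observed - predicted mean) with sd `params$noise_sd`. Missing samples
#' (NA glucose) are excluded, never imputed.
#'
#' @param params A [patient_params()] object.
#' @param dataset An analysis dataset as produced by [align_period()] or
#'   [cohort_datasets()]: a list with `times`, `glucose` and `meals`.
#' @return The log-likelihood (scalar).
#' @export
log_likelihood <- function(params, dataset) {
  if (!is.numeric(params$noise_sd) || params$noise_sd <= 0)
    stop("`noise_sd` must be > 0", call. = FALSE)
  keep <- !is.na(dataset$glucose)
  if (!any(keep))
    stop("dataset has no non-missing glucose samples", call. = FALSE)
  mu <- predict_mean(params, dataset$meals, dataset$times[keep])
  sum(stats::dnorm(dataset$glucose[keep], mu, params$noise_sd, log = TRUE))
}

# log density of Normal(loc, scale) truncated to x >= 0
ldnorm_pos <- function(x, loc, scale) {
  if (x < 0) return(-Inf)
  stats::dnorm(x, loc, scale, log = TRUE) -
    stats::pnorm(loc / scale, log.p = TRUE)
}

# log density of half-Normal(scale) on x >= 0
ldhalfnorm <- function(x, scale) {
  if (x < 0) return(-Inf)
  log(2) + stats::dnorm(x, 0, scale, log = TRUE)
}

#' Hierarchical log-posterior density (unnormalized in the data)
#'
#' `log_likelihood(params, dataset)` plus the hierarchical log-priors:
#' `beta_p` ~ Normal(beta_g, sd_beta^2) truncated at 0; `log alpha_p` ~
#' Normal(log alpha_g, sd_alpha^2); `baseline_p` ~ Normal truncated at 0;
#' `noise_sd_p` ~ half-Normal; each offset ~ Normal(0, jitter_sd^2)
#' truncated to +/- `offset_max`; plus the hyperpriors of
#' [prior_config()] on the group parameters. Densities are over the
#' natural (untransformed) parameters. Parameters outside their support
#' return `-Inf` rather than raising an error.
#'
#' @inheritParams log_likelihood
#' @param group A [group_params()] object.
#' @param prior A [prior_config()] object.
#' @return The log-posterior density (scalar; `-Inf` out of support).
#' @export
log_posterior <- function(params, group, prior, dataset) {
  jit <- group$jitter_sd
  if (is.null(jit)) jit <- prior$jitter_sd
  # support checks -> -Inf sentinel
  if (params$beta < 0 || params$alpha <= 0 || params$baseline <= 0 ||
      params$noise_sd <= 0 || group$beta_g < 0 || group$alpha_g <= 0 ||
      group$sd_beta <= 0 || group$sd_alpha <= 0 ||
      any(abs(params$offsets) > prior$offset_max))
    return(-Inf)
  if (jit == 0 && any(params$offsets != 0)) return(-Inf)

  ll <- log_likelihood(params, dataset)

  lp <- ldnorm_pos(params$beta, group$beta_g, group$sd_beta) +
    stats::dlnorm(params$alpha, log(group$alpha_g), group$sd_alpha, log = TRUE) +
    ldnorm_pos(params$baseline, prior$baseline_loc, prior$baseline_scale) +
    ldhalfnorm(params$noise_sd, prior$noise_scale)
  if (jit > 0 && length(params$offsets)) {
    znorm <- log(stats::pnorm(prior$offset_max / jit) -
                   stats::pnorm(-prior$offset_max / jit))
    lp <- lp + sum(stats::dnorm(params$offsets, 0, jit, log = TRUE) - znorm)
  }
  hyper <- ldnorm_pos(group$beta_g, prior$beta_g_loc, prior$beta_g_scale) +
    stats::dlnorm(group$alpha_g, log(prior$alpha_g_loc), prior$alpha_g_scale,
                  log = TRUE) +
    ldhalfnorm(group$sd_beta, prior$sd_beta_scale) +
    ldhalfnorm(group$sd_alpha, prior$sd_alpha_scale)
  ll + lp + hyper
}

#' Variance explained by the fitted curve, in percent
#'
#' `100 * (1 - Var(observed - fitted) / Var(observed))`, clipped below at
#' zero, computed over non-missing pairs. This is the per-trace "R
#' squared" of the glycemic summary table.
#'
#' @param observed,fitted Numeric vectors of equal length; NAs in either
#'   drop the pair.
#' @return Percentage in \[0, 100\].
#' @export
variance_explained <- function(observed, fitted) {
  if (length(observed) != length(fitted))
    stop("`observed` and `fitted` must have equal length", call. = FALSE)
  keep <- !is.na(observed) & !is.na(fitted)
  if (sum(keep) < 2L) stop("need at least 2 non-missing samples", call. = FALSE)
  vo <- stats::var(observed[keep])
  if (vo == 0) stop("observed trace has zero variance", call. = FALSE)
  max(0, 100 * (1 - stats::var(observed[keep] - fitted[keep]) / vo))
}
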