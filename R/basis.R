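#' Unit-peak Gaussian meal-response basis
#'
#' The building block of the response model: a bell-shaped bump of unit
#' height centred at the meal time \eqn{\tau} with length-scale
#' \eqn{\alpha} (minutes),
#' \deqn{k(t; \tau, \alpha) = \exp\{-(t-\tau)^2 / (2\alpha^2)\}.}
#' The bump is symmetric in \eqn{t-\tau} and attains its maximum of 1 at
#' \eqn{t = \tau}; smaller \eqn{\alpha} means faster glucose clearance.
#'
#' @param t Numeric vector of evaluation times (minutes).
#' @param tau Meal time (minutes), scalar or vector recycled against `t`.
#' @param alpha Length-scale (minutes), strictly positive.
#' @return Numeric vector in (0, 1], same length as `t`.
#' @examples
#' response_basis(0:120, tau = 60, alpha = 20)
#' @export
response_basis <- function(t, tau, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("`alpha` must be a single positive number", call. = FALSE)
  exp(-((t - tau)^2) / (2 * alpha^2))
}

#' Posterior-mean style prediction of the glucose curve
#'
#' Evaluates the model's mean function
#' \deqn{\mu(t) = b_p + \sum_m \beta_p c_m k(t; \tau_m, \alpha_p)}
#' for one patient: a constant baseline plus one carbohydrate-scaled
#' Gaussian bump per meal. Meal times are the *latent* (offset-corrected)
#' times \eqn{\tau_m = r_m + \delta_m}.
#'
#' @param params A [patient_params()] object (or compatible list) with
#'   fields `beta`, `alpha`, `baseline` and `offsets`.
#' @param meals Data frame (or list) with numeric fields `time` (reported
#'   meal times, minutes) and `carbs` (grams, non-negative).
#' @param times Numeric vector: grid of evaluation times (minutes).
#' @return Numeric vector of glucose values (mmol/l), one per grid point.
#' @seealso [response_basis()], [simulate_trace()]
#' @export
predict_mean <- function(params, meals, times) {
  meals <- as_meal_frame(meals)
  m <- nrow(meals)
  offsets <- params$offsets
  if (is.null(offsets)) offsets <- rep(0, m)
  if (length(offsets) != m)
    stop("number of offsets (", length(offsets),
         ") does not match number of meals (", m, ")", call. = FALSE)
  if (any(meals$carbs < 0)) stop("carbohydrate amounts must be >= 0", call. = FALSE)
  mu <- rep(params$baseline, length(times))
  if (m == 0L) return(mu)
  tau <- meals$time + offsets
  for (j in seq_len(m)) {
    mu <- mu + params$beta * meals$carbs[j] *
      response_basis(times, tau[j], params$alpha)
  }
  mu
}

# Coerce the accepted meal representations to a minimal data.frame.
as_meal_frame <- function(meals) {
  if (is.null(meals)) return(data.frame(time = numeric(), carbs = numeric()))
  if (is.list(meals) && !is.data.frame(meals))
    meals <- data.frame(time = meals$time, carbs = meals$carbs)
  if (!all(c("time", "carbs") %in% names(meals)))
    stop("meals need `time` and `carbs` columns", call. = FALSE)
  meals[c("time", "carbs")]
}
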