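# CSV dialects (modelled on flash-glucose-monitor exports):
#   CGM:   patient_id,period,timestamp,glucose_mmol_l
#   diary: patient_id,period,timestamp,item,carbs_g[,energy_kcal,protein_g,fat_g]
# ISO-8601 timestamps, UTC. Internally time is numeric minutes; timestamps
# exist only at the I/O boundary.

.cgm_origin <- function() as.POSIXct("2021-03-01 00:00:00", tz = "UTC")

.fmt_ts <- function(origin, minutes) {
  format(origin + round(minutes * 60), "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

.parse_ts <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

#' Construct a CGM glucose trace
#'
#' @param patient_id Character scalar.
#' @param period `"pre"` or `"post"`.
#' @param time Numeric vector, minutes from the trace origin, strictly
#'   increasing.
#' @param glucose Numeric vector (mmol/l); `NA` marks a missing sample.
#'   Non-missing values must be positive and finite.
#' @param nominal_interval Nominal sampling interval in minutes.
#' @param origin POSIXct timestamp of `time = 0`.
#' @return An object of class `glucose_trace`.
#' @export
glucose_trace <- function(patient_id, period, time, glucose,
                          nominal_interval = 15, origin = .cgm_origin()) {
  period <- match.arg(period, c("pre", "post"))
  if (length(time) != length(glucose))
    stop("`time` and `glucose` lengths differ", call. = FALSE)
  if (length(time) && any(diff(time) <= 0))
    stop("trace timestamps must be strictly increasing", call. = FALSE)
  ok <- is.na(glucose) | (is.finite(glucose) & glucose > 0)
  if (!all(ok))
    stop("glucose values must be positive and finite (or NA for missing)",
         call. = FALSE)
  structure(list(patient_id = as.character(patient_id), period = period,
                 time = as.numeric(time), glucose = as.numeric(glucose),
                 nominal_interval = nominal_interval, origin = origin),
            class = "glucose_trace")
}

#' @export
print.glucose_trace <- function(x, ...) {
  cat(sprintf("<glucose_trace> patient %s, period %s: %d samples (%d missing), %g-min grid\n",
              x$patient_id, x$period, length(x$time), sum(is.na(x$glucose)),
              x$nominal_interval))
  invisible(x)
}

#' Write CGM traces to CSV
#'
#' @param traces A `glucose_trace` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cgm_csv <- function(traces, path) {
  if (inherits(traces, "glucose_trace")) traces <- list(traces)
  rows <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(patient_id = tr$patient_id, period = tr$period,
               timestamp = .fmt_ts(tr$origin, tr$time),
               glucose_mmol_l = ifelse(is.na(tr$glucose), "",
                                       formatC(tr$glucose, digits = 10,
                                               format = "g")))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read CGM traces from CSV
#'
#' One trace per patient-period. Rows whose glucose does not parse as a
#' positive number become missing samples and are counted in the read
#' report (attribute `"report"`: parsed / missing / total row counts).
#' Non-monotone timestamps within a patient-period raise a validation
#' error naming the offending row.
#'
#' @param path CSV file in the documented CGM dialect.
#' @param nominal_interval Nominal sampling interval (minutes) recorded
#'   on each trace.
#' @return Named list of [glucose_trace()] objects (names
#'   `"<patient>.<period>"`), with a `"report"` attribute.
#' @export
read_cgm_csv <- function(path, nominal_interval = 15) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("patient_id", "period", "timestamp", "glucose_mmol_l")
  if (!all(need %in% names(df)))
    stop("CGM file is missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  ts <- .parse_ts(df$timestamp)
  if (anyNA(ts))
    stop("unparseable timestamp at row ", which(is.na(ts))[1], call. = FALSE)
  g <- suppressWarnings(as.numeric(df$glucose_mmol_l))
  g[!is.na(g) & (!is.finite(g) | g <= 0)] <- NA
  n_missing <- sum(is.na(g))
  key <- paste(df$patient_id, df$period, sep = ".")
  out <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    tk <- ts[idx]
    bad <- which(diff(as.numeric(tk)) <= 0)
    if (length(bad))
      stop("non-monotone timestamp for ", k, " at file row ",
           idx[bad[1] + 1] + 1L, call. = FALSE)
    origin <- tk[1]
    out[[k]] <- glucose_trace(df$patient_id[idx[1]], df$period[idx[1]],
                              time = as.numeric(tk - origin, units = "mins"),
                              glucose = g[idx],
                              nominal_interval = nominal_interval,
                              origin = origin)
  }
  attr(out, "report") <- list(rows = nrow(df), parsed = nrow(df) - n_missing,
                              missing = n_missing)
  out
}

#' Write a food diary to CSV
#'
#' @param diary Data frame with columns `patient_id`, `period`, `time`
#'   (minutes from `origin`), `item` (optional), `carbs` (grams).
#' @param path Output file.
#' @param origin POSIXct timestamp of `time = 0`.
#' @return `path`, invisibly.
#' @export
write_food_diary <- function(diary, path, origin = .cgm_origin()) {
  rows <- data.frame(patient_id = diary$patient_id, period = diary$period,
                     timestamp = .fmt_ts(origin, diary$time),
                     item = if (is.null(diary$item)) "meal" else diary$item,
                     carbs_g = diary$carbs)
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a food diary from CSV
#'
#' Records are sorted by (patient, period, time). Diary lines are foods;
#' the model's unit is a meal, so lines of one patient-period falling
#' within `merge_window` minutes of the first line of a cluster are
#' merged into a single meal with summed carbohydrates, timed at the
#' first line. A negative carbohydrate value is a validation error. The
#' `"report"` attribute counts input, merged and output rows.
#'
#' @param path CSV file in the documented diary dialect.
#' @param merge_window Merge window in minutes (default 15).
#' @return Data frame of meal records (class `meal_diary`): `patient_id`,
#'   `period`, `time` (minutes from the diary origin), `carbs` (g), with
#'   attributes `"origin"` and `"report"`.
#' @export
read_food_diary <- function(path, merge_window = 15) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "period", "timestamp", "carbs_g")
  if (!all(need %in% names(df)))
    stop("diary file is missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$carbs_g) | df$carbs_g < 0))
    stop("negative or non-numeric carbohydrate value at row ",
         which(!is.finite(df$carbs_g) | df$carbs_g < 0)[1], call. = FALSE)
  ts <- .parse_ts(df$timestamp)
  if (anyNA(ts))
    stop("unparseable timestamp at row ", which(is.na(ts))[1], call. = FALSE)
  origin <- min(ts)
  df$time <- as.numeric(ts - origin, units = "mins")
  df <- df[order(df$patient_id, df$period, df$time), ]
  out <- list(); merged <- 0L
  for (k in unique(paste(df$patient_id, df$period, sep = "\r"))) {
    sub <- df[paste(df$patient_id, df$period, sep = "\r") == k, ]
    i <- 1L
    while (i <= nrow(sub)) {
      j <- i
      while (j < nrow(sub) && sub$time[j + 1] - sub$time[i] <= merge_window)
        j <- j + 1L
      merged <- merged + (j - i)
      out[[length(out) + 1L]] <- data.frame(
        patient_id = sub$patient_id[i], period = sub$period[i],
        time = sub$time[i], carbs = sum(sub$carbs_g[i:j]))
      i <- j + 1L
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "origin") <- origin
  attr(res, "report") <- list(rows = nrow(df), merged = merged,
                              meals = nrow(res))
  class(res) <- c("meal_diary", "data.frame")
  res
}

#' Align one patient-period trace with its diary window
#'
#' Restricts the CGM trace to the diary's recording window (midnight of
#' the first diary day, `days` days long) and puts trace and meals on a
#' common minutes-from-window-start axis. Meals up to `carry_in` minutes
#' *before* the window start are retained, since their glucose responses
#' can overlap the window; earlier or later meals are dropped.
#'
#' @param trace A [glucose_trace()].
#' @param meals Meal records for the same patient and period (rows of a
#'   [read_food_diary()] result, or any data frame with `time` in minutes
#'   from the diary origin and `carbs`).
#' @param days Window length in days (default 3).
#' @param carry_in Carry-in allowance before window start, minutes.
#' @param meal_origin POSIXct origin of the meal `time` axis; defaults to
#'   the diary's `"origin"` attribute or the trace origin.
#' @param window_start POSIXct start of the diary window; defaults to
#'   midnight of the first diary day.
#' @return An `analysis_dataset`: list with `patient_id`, `period`,
#'   `times`, `glucose`, `meals` (data frame `time`, `carbs`), `days`,
#'   `window_start` (POSIXct).
#' @export
align_period <- function(trace, meals, days = 3, carry_in = 180,
                         meal_origin = NULL, window_start = NULL) {
  if (is.null(meal_origin))
    meal_origin <- attr(meals, "origin", exact = TRUE)
  if (is.null(meal_origin)) meal_origin <- trace$origin
  if (nrow(meals) == 0) stop("no meal records supplied", call. = FALSE)
  # absolute meal times, then a window starting at midnight of the first
  # diary day unless anchored explicitly
  abs_meal <- meal_origin + meals$time * 60
  day0 <- if (is.null(window_start)) trunc(min(abs_meal), units = "days")
          else window_start
  win_len <- days * 1440
  meal_min <- as.numeric(abs_meal - day0, units = "mins")
  keep_meal <- meal_min >= -carry_in & meal_min < win_len
  trace_min <- trace$time + as.numeric(trace$origin - day0, units = "mins")
  keep_tr <- trace_min >= 0 & trace_min < win_len
  if (!any(keep_tr))
    stop("trace and diary window do not overlap for patient ",
         trace$patient_id, call. = FALSE)
  structure(list(patient_id = trace$patient_id, period = trace$period,
                 times = trace_min[keep_tr], glucose = trace$glucose[keep_tr],
                 meals = data.frame(time = meal_min[keep_meal],
                                    carbs = meals$carbs[keep_meal]),
                 days = days, window_start = day0),
            class = "analysis_dataset")
}

#' @export
print.analysis_dataset <- function(x, ...) {
  cat(sprintf("<analysis_dataset> patient %s/%s: %d samples over %g days, %d meals\n",
              x$patient_id, x$period, length(x$times), x$days, nrow(x$meals)))
  invisible(x)
}
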