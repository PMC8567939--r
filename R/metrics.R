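#' Time in glycemic bands
#'
#' Percentage of wear time spent in each glucose band. Bands are built
#' from the `edges` as `(-Inf, e1), [e1, e2), ..., [ek, Inf)` — half-open
#' on the right, so a sample exactly at 4.0 mmol/l counts as `[4, 5)`,
#' not as hypoglycaemic. Percentages are over non-missing samples only
#' and sum to 100.
#'
#' @param trace A [glucose_trace()], or a numeric vector of glucose
#'   values.
#' @param edges Strictly increasing band edges, mmol/l. The default
#'   reproduces the five reporting bands `<4`, `[4,5)`, `[5,6)`, `[6,7)`,
#'   `>=7`.
#' @return Named numeric vector of percentages, one per band.
#' @export
time_in_bands <- function(trace, edges = c(4, 5, 6, 7)) {
  g <- if (inherits(trace, "glucose_trace")) trace$glucose else trace
  g <- g[!is.na(g)]
  if (!length(g)) stop("no non-missing samples", call. = FALSE)
  if (any(diff(edges) <= 0))
    stop("`edges` must be strictly increasing", call. = FALSE)
  cuts <- cut(g, breaks = c(-Inf, edges, Inf), right = FALSE)
  lab <- c(paste0("<", edges[1]),
           if (length(edges) > 1)
             sprintf("[%g,%g)", edges[-length(edges)], edges[-1]),
           paste0(">=", edges[length(edges)]))
  stats::setNames(100 * as.numeric(table(cuts)) / length(g), lab)
}

#' Per-trace glycemic summary
#'
#' Mean, min and max glucose, coefficient of variation (100 * sd / mean
#' with the n-1 sd), and time-in-band percentages, all over non-missing
#' samples of the raw observations (never the fitted curve).
#'
#' @param trace A [glucose_trace()] or numeric vector.
#' @param edges Band edges passed to [time_in_bands()].
#' @return An object of class `glycemic_summary`: list with `mean`,
#'   `min`, `max`, `cv` (percent), `time_in_band` (named percentages),
#'   `n` (non-missing sample count).
#' @export
trace_summary <- function(trace, edges = c(4, 5, 6, 7)) {
  g <- if (inherits(trace, "glucose_trace")) trace$glucose else trace
  g <- g[!is.na(g)]
  if (length(g) < 2L) stop("need at least 2 non-missing samples", call. = FALSE)
  structure(list(mean = mean(g), min = min(g), max = max(g),
                 cv = 100 * stats::sd(g) / mean(g),
                 time_in_band = time_in_bands(g, edges), n = length(g)),
            class = "glycemic_summary")
}

#' @export
print.glycemic_summary <- function(x, ...) {
  cat(sprintf("glucose mean %.2f, min %.2f, max %.2f mmol/l; CV %.1f%% (n=%d)\n",
              x$mean, x$min, x$max, x$cv, x$n))
  print(round(x$time_in_band, 1))
  invisible(x)
}

#' Normalized aggregated glucose histogram
#'
#' Pools the samples of all individuals of one group-period and bins
#' them; heights are densities, so sum(height * bin_width) = 1. The
#' histogram is pooled (every sample counts once), not averaged per
#' patient.
#'
#' @param traces A list of [glucose_trace()] objects (or numeric
#'   vectors), or a single one.
#' @param bin_width Bin width, mmol/l (default 0.25).
#' @return Data frame: `bin_left`, `bin_right`, `density`.
#' @export
aggregate_histogram <- function(traces, bin_width = 0.25) {
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("`bin_width` must be positive", call. = FALSE)
  if (inherits(traces, "glucose_trace") || is.numeric(traces))
    traces <- list(traces)
  g <- unlist(lapply(traces, function(tr)
    if (inherits(tr, "glucose_trace")) tr$glucose else tr))
  g <- g[!is.na(g)]
  if (!length(g)) stop("no non-missing samples", call. = FALSE)
  lo <- floor(min(g) / bin_width) * bin_width
  hi <- ceiling(max(g) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  counts <- table(cut(g, breaks = breaks, right = FALSE,
                      include.lowest = TRUE))
  data.frame(bin_left = breaks[-length(breaks)], bin_right = breaks[-1],
             density = as.numeric(counts) / (length(g) * bin_width))
}
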