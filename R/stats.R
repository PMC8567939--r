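# Comparison battery: within-group paired t-tests, between-group Welch
# t / Mann-Whitney U / chi-squared, and the degree-of-change contrast
# (Welch t on per-patient pre->post deltas). All tests two-sided; raw
# p-values, no multiplicity correction.

.test_result <- function(method, statistic, p_value, n, degenerate = FALSE) {
  structure(list(method = method, statistic = unname(statistic),
                 p_value = unname(p_value), n = n, degenerate = degenerate),
            class = "cgm_test")
}

#' @export
print.cgm_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)%s\n", x$method,
              x$statistic, x$p_value, paste(x$n, collapse = ", "),
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}

#' Within-group pre/post paired t-test
#'
#' Two-sided paired t-test on the per-patient differences (post - pre).
#' Zero-variance differences (including post identical to pre) are
#' flagged as degenerate: the result carries `degenerate = TRUE` and
#' `p = 1` for identical vectors or `p = NA` otherwise, rather than a
#' spurious `p = 0`.
#'
#' @param pre,post Per-patient values, paired by position; length >= 2.
#' @return A `cgm_test` result: `method`, `statistic`, `p_value`, `n`,
#'   `degenerate`.
#' @export
paired_change_test <- function(pre, post) {
  if (length(pre) != length(post))
    stop("`pre` and `post` must be paired (equal length)", call. = FALSE)
  if (length(pre) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- post - pre
  if (stats::sd(d) == 0) {
    return(.test_result("paired-t", statistic = 0,
                        p_value = if (all(d == 0)) 1 else NA_real_,
                        n = length(pre), degenerate = TRUE))
  }
  tt <- stats::t.test(post, pre, paired = TRUE)
  .test_result("paired-t", tt$statistic, tt$p.value, length(pre))
}

#' Between-group difference test
#'
#' Two-sided comparison of two independent samples by the requested
#' method: Welch's unequal-variance t-test (`"t"`), the Mann-Whitney
#' U-test (`"u"`; the reported statistic is U for the first group), or
#' the chi-squared test (`"chisq"`; inputs are then category labels and
#' the test runs on the a x b contingency table).
#'
#' @param a,b Values (or labels, for `"chisq"`) of the two groups.
#' @param method `"t"`, `"u"` or `"chisq"`.
#' @return A `cgm_test` result.
#' @export
group_difference_test <- function(a, b, method = c("t", "u", "chisq")) {
  method <- match.arg(method)
  n <- c(length(a), length(b))
  if (any(n < 2L)) stop("each group needs at least 2 values", call. = FALSE)
  if (method == "t") {
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      return(.test_result("independent-t", 0,
                          if (mean(a) == mean(b)) 1 else NA_real_, n,
                          degenerate = TRUE))
    tt <- stats::t.test(a, b, var.equal = FALSE)
    .test_result("independent-t", tt$statistic, tt$p.value, n)
  } else if (method == "u") {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE))
    .test_result("mann-whitney-u", wt$statistic, wt$p.value, n)
  } else {
    tab <- table(factor(c(rep("a", n[1]), rep("b", n[2]))), c(a, b))
    ct <- suppressWarnings(stats::chisq.test(tab))
    .test_result("chi-squared", ct$statistic, ct$p.value, n)
  }
}

#' Degree-of-change test between groups
#'
#' Computes per-patient deltas (post - pre) within each group, then
#' compares the two delta sets with Welch's two-sample t-test. This is
#' the "degree of change" column of the group comparison table.
#'
#' @param pre_a,post_a Paired values of group A.
#' @param pre_b,post_b Paired values of group B.
#' @return A `cgm_test` result.
#' @export
change_difference_test <- function(pre_a, post_a, pre_b, post_b) {
  if (length(pre_a) != length(post_a) || length(pre_b) != length(post_b))
    stop("periods must be paired within each group", call. = FALSE)
  if (length(pre_a) < 2L || length(pre_b) < 2L)
    stop("each group needs at least 2 patients", call. = FALSE)
  group_difference_test(post_a - pre_a, post_b - pre_b, method = "t")
}

#' Group summary and comparison table
#'
#' Builds the per-metric comparison table: mean and sd per group-period,
#' the within-group paired t-test p-value per group, and (with two
#' groups) the between-group p-values pre, post and for the degree of
#' change.
#'
#' @param values Long-format data frame with columns `patient_id`,
#'   `group`, `period` (`"pre"`/`"post"`), `metric`, `value`; every
#'   patient must have both periods for each of its metrics.
#' @param between_method Method for the between-group period
#'   comparisons: `"t"` (default) or `"u"`.
#' @return Data frame of class `group_table`: one row per metric x
#'   group with `mean_pre`, `sd_pre`, `mean_post`, `sd_post`,
#'   `p_within`, and (attached to the first group's rows) `p_pre`,
#'   `p_post`, `p_change`; `NA` where a comparison is not available.
#' @export
build_group_table <- function(values, between_method = "t") {
  need <- c("patient_id", "group", "period", "metric", "value")
  if (!all(need %in% names(values)))
    stop("`values` needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  groups <- unique(values$group)
  rows <- list()
  for (met in unique(values$metric)) {
    vm <- values[values$metric == met, ]
    per_group <- list()
    for (g in groups) {
      vg <- vm[vm$group == g, ]
      pre <- vg[vg$period == "pre", ]
      post <- vg[vg$period == "post", ]
      ids <- sort(unique(vg$patient_id))
      miss <- ids[!(ids %in% pre$patient_id) | !(ids %in% post$patient_id)]
      if (length(miss))
        stop("patient ", miss[1], " is missing a period for metric ", met,
             call. = FALSE)
      x_pre <- pre$value[match(ids, pre$patient_id)]
      x_post <- post$value[match(ids, post$patient_id)]
      per_group[[g]] <- list(pre = x_pre, post = x_post)
      p_within <- if (length(ids) >= 2)
        paired_change_test(x_pre, x_post)$p_value else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        metric = met, group = g,
        mean_pre = mean(x_pre), sd_pre = stats::sd(x_pre),
        mean_post = mean(x_post), sd_post = stats::sd(x_post),
        p_within = p_within, p_pre = NA_real_, p_post = NA_real_,
        p_change = NA_real_, stringsAsFactors = FALSE)
    }
    if (length(groups) == 2) {
      a <- per_group[[groups[1]]]; b <- per_group[[groups[2]]]
      i <- length(rows) - 1L  # first group's row for this metric
      rows[[i]]$p_pre <-
        group_difference_test(a$pre, b$pre, between_method)$p_value
      rows[[i]]$p_post <-
        group_difference_test(a$post, b$post, between_method)$p_value
      rows[[i]]$p_change <-
        change_difference_test(a$pre, a$post, b$pre, b$post)$p_value
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("group_table", "data.frame")
  out
}
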