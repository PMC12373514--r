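# Baseline-severity checks: does the baseline total predict outcome?
#
# Two analyses: (1) correlation of the baseline total with relative
# improvement 1 - (timepoint total / baseline total) at end of treatment and
# at follow-up; (2) a Mann-Whitney comparison of baseline totals between the
# subjects whose total fell further between end of treatment and follow-up
# (improved) and those whose total rose (worsened).

#' Correlation of baseline severity with relative improvement
#'
#' @param cohort A [caps_cohort()].
#' @param arm Arm filter as in [normalize_cohort()].
#' @param timepoint `"post"` or `"fup"`: improvement is
#'   `1 - timepoint_total / baseline_total`.
#' @param method `"spearman"` or `"pearson"` (the analysis is reported with
#'   both; the field convention is ambiguous).
#' @return A `correlation_result` (see [correlate()]).
#' @export
baseline_outcome_correlation <- function(cohort,
                                         arm = c("active", "sham", "all"),
                                         timepoint = c("post", "fup"),
                                         method = c("spearman", "pearson")) {
  arm <- match.arg(arm)
  timepoint <- match.arg(timepoint)
  method <- match.arg(method)
  out <- suppressMessages(normalize_cohort(cohort, arm))
  ratio <- if (timepoint == "post") out$post_ratio else out$fup_ratio
  df <- as.data.frame(cohort)
  if (arm != "all") df <- df[df$arm == arm, , drop = FALSE]
  baseline <- df$total_pre[match(out$participant_id, df$participant_id)]
  correlate(baseline, 1 - ratio, method)
}

#' Split baseline totals by follow-up trajectory
#'
#' IMPROVED: follow-up total strictly below the posttreatment total;
#' WORSENED: strictly above. Exact ties (follow-up equal to posttreatment)
#' are assigned to WORSENED — the conservative choice for a claimed
#' improvement effect — and reported, never silently.
#'
#' @param cohort A [caps_cohort()].
#' @param arm Arm filter.
#' @return A list: `improved` and `worsened` (baseline totals), `tie_ids`
#'   (participant ids of exact ties, counted in `worsened`), and
#'   `degenerate` (TRUE when either group is empty, in which case the
#'   two-group comparison is not meaningful).
#' @export
split_by_fup_trajectory <- function(cohort, arm = c("active", "sham", "all")) {
  stopifnot(inherits(cohort, "caps_cohort"))
  arm <- match.arg(arm)
  df <- as.data.frame(cohort)
  if (arm != "all") df <- df[df$arm == arm, , drop = FALSE]
  keep <- !is.na(df$total_pre) & !is.na(df$total_post) & !is.na(df$total_fup)
  df <- df[keep, , drop = FALSE]
  improved <- df$total_fup < df$total_post
  ties <- df$total_fup == df$total_post
  if (any(ties))
    message(sprintf("split_by_fup_trajectory: %d exact tie(s) (fup == post) assigned to WORSENED",
                    sum(ties)))
  list(improved = df$total_pre[improved],
       worsened = df$total_pre[!improved],
       tie_ids = df$participant_id[ties],
       degenerate = sum(improved) == 0 || sum(!improved) == 0)
}

#' Mann-Whitney U test
#'
#' The U statistic is computed from pooled mid-ranks
#' (`U = R1 - n1 (n1 + 1) / 2`). When both groups have at most 12
#' observations and the pooled values are tie-free, the two-sided p-value is
#' EXACT (the full null distribution of U under random group assignment);
#' otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param group1,group2 Numeric vectors (nonempty).
#' @return An object of class `mann_whitney_result`: `U` (for `group1`),
#'   `n1`, `n2`, `p_two_sided`, `mode` (`"EXACT"` or `"NORMAL_APPROX"`).
#' @export
mann_whitney <- function(group1, group2) {
  group1 <- group1[is.finite(group1)]
  group2 <- group2[is.finite(group2)]
  n1 <- length(group1); n2 <- length(group2)
  stopifnot(n1 >= 1, n2 >= 1)
  pooled <- c(group1, group2)
  rk <- rank(pooled)  # mid-ranks
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (n1 <= 12 && n2 <= 12 && !ties) {
    mode <- "EXACT"
    # two-sided: doubled smaller tail of the exact U distribution
    p <- 2 * min(stats::pwilcox(U, n1, n2),
                 1 - stats::pwilcox(U - 1, n1, n2))
    p <- min(1, p)
  } else {
    mode <- "NORMAL_APPROX"
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tab <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tab^3 - tab) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  structure(list(U = U, n1 = n1, n2 = n2, p_two_sided = p, mode = mode),
            class = "mann_whitney_result")
}

#' @export
print.mann_whitney_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney: U = %g (n1 = %d, n2 = %d), two-sided p = %.4g [%s]\n",
              x$U, x$n1, x$n2, x$p_two_sided, x$mode))
  invisible(x)
}

#' Full baseline-severity analysis
#'
#' Bundles the baseline-vs-improvement correlations (both timepoints, both
#' methods) and the Mann-Whitney comparison of baseline totals between the
#' follow-up improved and worsened groups.
#'
#' @param cohort A [caps_cohort()].
#' @param arm Arm filter.
#' @return A list: `correlations` (data frame: timepoint, method, n, r,
#'   p_asymptotic), `split` (group sizes, tie count, degenerate flag) and
#'   `mann_whitney` (a `mann_whitney_result`, or `NULL` when a group is
#'   empty).
#' @export
baseline_severity_analysis <- function(cohort,
                                       arm = c("active", "sham", "all")) {
  arm <- match.arg(arm)
  rows <- list()
  for (tp in c("post", "fup")) {
    for (m in c("spearman", "pearson")) {
      cr <- baseline_outcome_correlation(cohort, arm, tp, m)
      rows[[length(rows) + 1]] <- data.frame(
        timepoint = toupper(tp), method = cr$method, n = cr$n,
        r = if (isTRUE(cr$undefined)) NA_real_ else cr$r,
        p_asymptotic = cr$p_asymptotic, stringsAsFactors = FALSE)
    }
  }
  sp <- suppressMessages(split_by_fup_trajectory(cohort, arm))
  mw <- if (length(sp$improved) >= 1 && length(sp$worsened) >= 1)
    mann_whitney(sp$improved, sp$worsened) else NULL
  list(correlations = do.call(rbind, rows),
       split = list(n_improved = length(sp$improved),
                    n_worsened = length(sp$worsened),
                    n_ties = length(sp$tie_ids),
                    degenerate = length(sp$improved) == 0 ||
                      length(sp$worsened) == 0),
       mann_whitney = mw)
}
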