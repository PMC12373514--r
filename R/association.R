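# Cluster-wise association analyses.
#
# Each CAPS-5 cluster's change ratio (cluster post/pre, cluster fup/pre) is
# correlated with the total-score change ratio at three comparisons:
#   (a) POST_VS_POST_TOTAL        cluster post/pre  vs  total post/pre
#   (b) FUP_VS_FUP_TOTAL          cluster fup/pre   vs  total fup/pre
#   (c) POSTCLUSTER_VS_FUP_TOTAL  cluster post/pre  vs  total fup/pre
# Spearman (mid-rank) is the headline method, Pearson is available alongside;
# inference is asymptotic (t-approximation) and by pairs bootstrap.

COMPARISONS <- c("POST_VS_POST_TOTAL", "FUP_VS_FUP_TOTAL",
                 "POSTCLUSTER_VS_FUP_TOTAL")

#' Per-cluster change ratios
#'
#' Computes post/pre and fup/pre ratios for each cluster subscore, per
#' participant. A cluster with a baseline score of 0 (possible for the
#' two-item avoidance cluster) is marked undefined (`NA`) for that subject
#' and excluded pairwise downstream; other clusters are unaffected.
#'
#' @param cohort A [caps_cohort()].
#' @param arm `"active"`, `"sham"` or `"all"`.
#' @return A data frame: `participant_id`, then `<cl>_post_ratio` and
#'   `<cl>_fup_ratio` for `cl` in B, C, D, E.
#' @export
cluster_ratios <- function(cohort, arm = c("active", "sham", "all")) {
  stopifnot(inherits(cohort, "caps_cohort"))
  arm <- match.arg(arm)
  df <- as.data.frame(cohort)
  if (arm != "all") df <- df[df$arm == arm, , drop = FALSE]
  keep <- !is.na(df$total_pre) & df$total_pre > 0 &
    !is.na(df$total_post) & !is.na(df$total_fup)
  df <- df[keep, , drop = FALSE]
  out <- data.frame(participant_id = df$participant_id,
                    stringsAsFactors = FALSE)
  n_undef <- 0L
  for (cl in CLUSTERS) {
    pre <- df[[paste0(cl, "_pre")]]
    ok <- !is.na(pre) & pre > 0
    n_undef <- n_undef + sum(!ok)
    out[[paste0(cl, "_post_ratio")]] <-
      ifelse(ok, df[[paste0(cl, "_post")]] / pre, NA_real_)
    out[[paste0(cl, "_fup_ratio")]] <-
      ifelse(ok, df[[paste0(cl, "_fup")]] / pre, NA_real_)
  }
  if (n_undef > 0)
    message(sprintf("cluster_ratios: %d cluster baseline(s) of 0 marked undefined (pairwise exclusion)",
                    n_undef))
  out
}

#' Correlation of paired values
#'
#' `method = "spearman"` is the Pearson product-moment correlation of
#' mid-ranks (average ranks on ties); `"pearson"` is the plain product-moment
#' coefficient. The two-sided asymptotic p-value uses the t-approximation
#' `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors; pairs with a missing member are dropped.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return An object of class `correlation_result`: `method`, `n`, `r`,
#'   `p_asymptotic`, and `undefined` (TRUE when either variable has zero
#'   variance, in which case `r` is `NA` rather than NaN-propagated).
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("correlate needs at least 3 complete pairs (got ", n, ")")
  base <- list(method = toupper(method), n = n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(c(base, list(r = NA_real_, p_asymptotic = NA_real_,
                                  undefined = TRUE)),
                     class = "correlation_result"))
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  structure(c(base, list(r = r, p_asymptotic = p, undefined = FALSE)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat(sprintf("%s correlation: undefined (zero variance), n = %d\n",
                x$method, x$n))
  } else {
    cat(sprintf("%s correlation: r = %.3f, n = %d, asymptotic p = %.3g\n",
                x$method, x$r, x$n, x$p_asymptotic))
    if (!is.null(x$p_bootstrap))
      cat(sprintf("  bootstrap p = %.3g, 95%% CI [%.3f, %.3f] (B = %d)\n",
                  x$p_bootstrap, x$ci95[1], x$ci95[2], x$B_bootstrap))
  }
  invisible(x)
}

#' Pairs-bootstrap inference for a correlation
#'
#' Resamples pairs with replacement `B` times; the 95% CI is the percentile
#' interval of the resampled coefficients and the bootstrap p-value is the
#' add-one-smoothed two-sided tail probability of 0 under the resampled
#' distribution: `p = min(1, 2 min((1 + #\{r* <= 0\}),
#' (1 + #\{r* >= 0\})) / (1 + B))`. Degenerate resamples (zero variance)
#' are dropped from the tally.
#'
#' @param x,y Paired values (pairs with a missing member dropped).
#' @param method As in [correlate()].
#' @param B Number of resamples (>= 100).
#' @param seed Integer seed; `NULL` uses the ambient RNG stream.
#' @return A list: `p_bootstrap`, `ci95` (length 2), `B`, `B_effective`,
#'   `seed`.
#' @export
bootstrap_inference <- function(x, y, method = c("spearman", "pearson"),
                                B = 1000, seed = NULL) {
  method <- match.arg(method)
  stopifnot(B >= 100)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stopifnot(n >= 3)
  use_ranks <- method == "spearman"
  with_seed_if(seed, {
    r_b <- vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- x[idx]; yb <- y[idx]
      if (stats::sd(xb) == 0 || stats::sd(yb) == 0) return(NA_real_)
      if (use_ranks) stats::cor(rank(xb), rank(yb)) else stats::cor(xb, yb)
    }, numeric(1))
    r_b <- r_b[!is.na(r_b)]
    Beff <- length(r_b)
    if (Beff == 0) stop("all bootstrap resamples degenerate")
    ci <- unname(stats::quantile(r_b, c(0.025, 0.975)))
    p <- min(1, 2 * min(1 + sum(r_b <= 0), 1 + sum(r_b >= 0)) / (1 + Beff))
    list(p_bootstrap = p, ci95 = ci, B = B, B_effective = Beff, seed = seed)
  })
}

correlate_full <- function(x, y, method, B, seed) {
  res <- correlate(x, y, method)
  if (!isTRUE(res$undefined)) {
    bi <- bootstrap_inference(x, y, method, B = B, seed = seed)
    res$p_bootstrap <- bi$p_bootstrap
    res$ci95 <- bi$ci95
    res$B_bootstrap <- bi$B
  } else {
    res$p_bootstrap <- NA_real_
    res$ci95 <- c(NA_real_, NA_real_)
    res$B_bootstrap <- B
  }
  res
}

#' Cluster-vs-total association matrices at the three comparisons
#'
#' For each of the four clusters, correlates the cluster change ratio with
#' the total change ratio at each comparison (see the module header). The
#' follow-up total ratio in comparison (c) is fup/pre by default; set
#' `fup_total = "fup_over_post"` for the follow-up/posttreatment variant.
#'
#' @param cohort A [caps_cohort()].
#' @param arm Arm filter as in [normalize_cohort()].
#' @param method `"spearman"` or `"pearson"`.
#' @param B Bootstrap resamples per correlation.
#' @param seed Integer seed (each correlation gets a derived sub-seed);
#'   `NULL` uses the ambient stream.
#' @param fup_total `"fup_over_pre"` (default) or `"fup_over_post"`.
#' @return A list of three data frames (one per comparison tag), each with
#'   one row per cluster: `comparison`, `cluster`, `method`, `n`, `r`,
#'   `p_asymptotic`, `p_bootstrap`, `ci_lo`, `ci_hi`.
#' @export
association_matrices <- function(cohort, arm = c("active", "sham", "all"),
                                 method = c("spearman", "pearson"),
                                 B = 1000, seed = NULL,
                                 fup_total = c("fup_over_pre",
                                               "fup_over_post")) {
  arm <- match.arg(arm)
  method <- match.arg(method)
  fup_total <- match.arg(fup_total)
  out_norm <- suppressMessages(normalize_cohort(cohort, arm))
  ratios <- suppressMessages(cluster_ratios(cohort, arm))
  stopifnot(identical(out_norm$participant_id, ratios$participant_id))
  total_fup <- if (fup_total == "fup_over_pre") out_norm$fup_ratio
  else out_norm$fup_ratio / out_norm$post_ratio
  targets <- list(POST_VS_POST_TOTAL = list(cl = "post", tot = out_norm$post_ratio),
                  FUP_VS_FUP_TOTAL = list(cl = "fup", tot = out_norm$fup_ratio),
                  POSTCLUSTER_VS_FUP_TOTAL = list(cl = "post", tot = total_fup))
  res <- lapply(names(targets), function(tag) {
    tg <- targets[[tag]]
    rows <- lapply(seq_along(CLUSTERS), function(k) {
      cl <- CLUSTERS[k]
      x <- ratios[[paste0(cl, "_", tg$cl, "_ratio")]]
      sub_seed <- if (is.null(seed)) NULL
      else (seed + 97L * match(tag, COMPARISONS) + k) %% .Machine$integer.max
      cr <- correlate_full(x, tg$tot, method, B, sub_seed)
      data.frame(comparison = tag, cluster = cl, method = cr$method,
                 n = cr$n, r = if (isTRUE(cr$undefined)) NA_real_ else cr$r,
                 p_asymptotic = cr$p_asymptotic,
                 p_bootstrap = cr$p_bootstrap,
                 ci_lo = cr$ci95[1], ci_hi = cr$ci95[2],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  names(res) <- names(targets)
  res
}

#' Descriptive sham-arm responder counts
#'
#' @param cohort A [caps_cohort()].
#' @param improvement_pct Deep-response cut as a percentage; a sham subject is
#'   a deep responder if their post/pre total ratio is strictly below
#'   `1 - improvement_pct/100`.
#' @return A list: `n_sham` (analyzable sham records), `deep_responders`
#'   (post/pre below the cut), `cluster_C_improved` (avoidance subscore lower
#'   at POST than at PRE), `cluster_C_attenuated` (of those, avoidance higher
#'   at FUP than at POST).
#' @export
sham_threshold_count <- function(cohort, improvement_pct = 35) {
  stopifnot(inherits(cohort, "caps_cohort"))
  df <- as.data.frame(cohort)
  df <- df[df$arm == "sham", , drop = FALSE]
  if (nrow(df) == 0) stop("cohort has no sham records")
  keep <- !is.na(df$total_pre) & df$total_pre > 0 &
    !is.na(df$total_post) & !is.na(df$total_fup)
  df <- df[keep, , drop = FALSE]
  cut <- 1 - improvement_pct / 100
  post_ratio <- df$total_post / df$total_pre
  c_improved <- df$C_post < df$C_pre
  c_attenuated <- c_improved & df$C_fup > df$C_post
  list(n_sham = nrow(df),
       deep_responders = sum(post_ratio < cut),
       cluster_C_improved = sum(c_improved),
       cluster_C_attenuated = sum(c_attenuated))
}
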