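# Responder-threshold (elbow) analysis.
#
# Outcome totals at end of treatment and follow-up are normalized to the
# baseline total per participant. For each candidate ratio threshold t we ask:
# of the participants whose post/pre ratio falls strictly below t (improvement
# of more than 100*(1-t)%), what fraction improved further at follow-up
# (fup/pre strictly below post/pre)? The elbow threshold is the grid point at
# which this curve is maximally above a null reference, the pointwise mean of
# curves recomputed after shuffling follow-up ratios across participants (or,
# alternatively, a fixed diagonal reference). Significance is by a
# selection-aware permutation test: each shuffled replicate contributes its
# own maximal distance to the null distribution.

# Candidate ratio thresholds strictly between 0 and 1: a threshold of
# "0% improvement" (t = 1) is not an improvement threshold and its inclusion
# makes the diagonal elbow criterion degenerate (the full-sample point
# competes with the true elbow).
default_grid <- function(step = 0.05) round(seq(step, 1 - step, by = step), 10)

#' Baseline-normalize a cohort's outcome totals
#'
#' Computes per-participant post/pre and fup/pre ratios for the selected arm.
#' Records with a baseline total of 0 or a missing POST or FUP total are
#' excluded (complete-case) with the exclusion count reported via a message
#' and the `"n_excluded"` attribute, never silently.
#'
#' @param cohort A [caps_cohort()].
#' @param arm `"active"`, `"sham"` or `"all"`.
#' @return A data frame of class `normalized_outcomes`: `participant_id`,
#'   `arm`, `post_ratio`, `fup_ratio`, `improved_at_fup` (strict
#'   `fup_ratio < post_ratio`).
#' @export
normalize_cohort <- function(cohort, arm = c("active", "sham", "all")) {
  stopifnot(inherits(cohort, "caps_cohort"))
  arm <- match.arg(arm)
  df <- as.data.frame(cohort)
  if (arm != "all") df <- df[df$arm == arm, , drop = FALSE]
  n0 <- nrow(df)
  keep <- !is.na(df$total_pre) & df$total_pre > 0 &
    !is.na(df$total_post) & !is.na(df$total_fup)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0)
    stop("no records remain after exclusions (arm = ", arm, ")")
  if (n0 - nrow(df) > 0)
    message(sprintf("normalize_cohort: excluded %d of %d records (zero or missing baseline, or missing POST/FUP)",
                    n0 - nrow(df), n0))
  out <- data.frame(participant_id = df$participant_id, arm = df$arm,
                    post_ratio = df$total_post / df$total_pre,
                    fup_ratio = df$total_fup / df$total_pre,
                    stringsAsFactors = FALSE)
  out$improved_at_fup <- out$fup_ratio < out$post_ratio
  structure(out, class = c("normalized_outcomes", "data.frame"),
            n_excluded = n0 - nrow(df))
}

#' Construct normalized outcomes directly from ratios
#'
#' Test and simulation entry point: builds the same object
#' [normalize_cohort()] produces from already-computed ratios.
#'
#' @param post_ratio,fup_ratio Numeric vectors of equal length (finite,
#'   nonnegative).
#' @param participant_id,arm Optional labels.
#' @return A `normalized_outcomes` data frame.
#' @export
as_normalized_outcomes <- function(post_ratio, fup_ratio,
                                   participant_id = NULL, arm = "active") {
  stopifnot(length(post_ratio) == length(fup_ratio),
            all(is.finite(post_ratio)), all(is.finite(fup_ratio)),
            all(post_ratio >= 0), all(fup_ratio >= 0))
  n <- length(post_ratio)
  if (is.null(participant_id)) participant_id <- sprintf("S%03d", seq_len(n))
  out <- data.frame(participant_id = as.character(participant_id),
                    arm = rep_len(arm, n),
                    post_ratio = post_ratio, fup_ratio = fup_ratio,
                    improved_at_fup = fup_ratio < post_ratio,
                    stringsAsFactors = FALSE)
  structure(out, class = c("normalized_outcomes", "data.frame"),
            n_excluded = 0L)
}

#' Responder-fraction curve over a threshold grid
#'
#' For each threshold `t` on the grid, the subgroup is the set of outcomes
#' with `post_ratio < t` (strict: "improved by more than" the corresponding
#' percentage) and `f(t)` is the fraction of that subgroup with
#' `improved_at_fup`. `f(t)` is `NA` where the subgroup has fewer than
#' `n_min` members.
#'
#' @param outcomes A `normalized_outcomes` data frame.
#' @param grid Ascending thresholds in (0, 1]; default 0.05 to 0.95 by 0.05
#'   (thresholds strictly between 0 and 1).
#' @param n_min Minimum subgroup size for `f(t)` to be defined (default 3).
#' @return An object of class `responder_curve`: `grid`, `f`, `n`,
#'   `overall_rate` (the whole-sample improved-at-fup fraction) and `n_min`.
#' @export
responder_curve <- function(outcomes, grid = default_grid(), n_min = 3) {
  stopifnot(nrow(outcomes) >= 1, all(grid > 0), all(grid <= 1),
            !is.unsorted(grid, strictly = TRUE), n_min >= 1)
  member <- outer(outcomes$post_ratio, grid, `<`)      # n x T
  n_t <- colSums(member)
  hits <- as.vector(crossprod(member, outcomes$improved_at_fup))
  f <- ifelse(n_t >= n_min, hits / n_t, NA_real_)
  structure(list(grid = grid, f = f, n = as.integer(n_t),
                 overall_rate = mean(outcomes$improved_at_fup),
                 n_min = n_min),
            class = "responder_curve")
}

#' Permutation null for the responder curve
#'
#' Each replicate shuffles the `fup_ratio` values across participants (the
#' `post_ratio` values stay fixed), recomputes the improved-at-fup flags and
#' the responder curve. The pointwise mean of the replicate curves is the
#' null reference of the Methods-style elbow criterion; the replicate curves
#' are retained so the elbow step can form the selection-aware null
#' distribution of its distance statistic against either reference.
#'
#' Outcomes are sorted canonically by (post_ratio, fup_ratio) before the
#' shuffles are drawn, so results do not depend on input row order.
#'
#' @param outcomes A `normalized_outcomes` data frame.
#' @param grid,n_min As in [responder_curve()].
#' @param B Number of shuffles (default 1000).
#' @param seed Integer seed; `NULL` uses the ambient RNG stream.
#' @param perms Optional test hook: an integer matrix with one permutation of
#'   `1:nrow(outcomes)` per row, used instead of random shuffles (rows of
#'   [all_permutations()] give the exact permutation distribution).
#' @return An object of class `permutation_null`: `grid`, `B`, `n`,
#'   `f_rep` (grid x B matrix of replicate curves, `NA` below `n_min`),
#'   `mean_f`, `n_min`, `seed`.
#' @export
permutation_null <- function(outcomes, grid = default_grid(), B = 1000,
                             n_min = 3, seed = NULL, perms = NULL) {
  stopifnot(nrow(outcomes) >= 2)
  n <- nrow(outcomes)
  ord <- order(outcomes$post_ratio, outcomes$fup_ratio)
  post <- outcomes$post_ratio[ord]
  fup <- outcomes$fup_ratio[ord]
  if (!is.null(perms)) {
    perms <- as.matrix(perms)
    stopifnot(ncol(perms) == n)
    B <- nrow(perms)
  } else {
    stopifnot(B >= 1)
    perms <- with_seed_if(seed, {
      t(vapply(seq_len(B), function(b) sample.int(n), integer(n)))
    })
  }
  member <- outer(post, grid, `<`)                     # n x T
  n_t <- colSums(member)
  # improved flags under each shuffle: fup[perm] < post, as an n x B matrix
  improved <- matrix(fup[t(perms)], n, B) < post
  f_rep <- crossprod(member, improved)                 # T x B counts
  f_rep <- sweep(f_rep, 1, pmax(n_t, 1), `/`)
  f_rep[n_t < n_min, ] <- NA_real_
  mean_f <- rowMeans(f_rep)
  structure(list(grid = grid, B = B, n = as.integer(n_t), f_rep = f_rep,
                 mean_f = mean_f, n_min = n_min, seed = seed),
            class = "permutation_null")
}

#' Elbow threshold: maximal distance from the null reference
#'
#' The distance is the signed difference `D(t) = f_obs(t) - reference(t)`
#' (one-sided: the alternative is that deep responders improve further more
#' often than chance), evaluated where both curves are defined. The selected
#' threshold `t_star` is the grid point maximizing `D`, ties broken toward
#' the smallest `t` (the most conservative, largest improvement percentage).
#' The permutation p-value is add-one smoothed and selection-aware: each
#' shuffled replicate contributes the maximum of its own distance curve
#' against the same reference,
#' `p = (1 + #\{b : max_t D_b(t) >= D_obs\}) / (1 + B)`.
#'
#' @param curve A [responder_curve()].
#' @param null A [permutation_null()] on the same grid.
#' @param reference `"null_mean"` (distance from the mean shuffled curve) or
#'   `"diagonal"` (distance from a fixed reference). The responder fraction
#'   is conventionally plotted against the improvement fraction `1 - t`;
#'   the two references are the two readings of that plot's "fraction
#'   expected at random" dashed line. Note that under a planted-threshold
#'   world the distance from any flat reference (the null mean included) is
#'   constant in expectation for every `t` below the true threshold, so its
#'   argmax does not identify the threshold; the identity diagonal does.
#' @param diagonal For `reference = "diagonal"`: `"identity"` (the line of
#'   identity of the improvement-fraction plot, i.e. `f = 1 - t` on the
#'   ratio grid) or `"overall_rate"` (the whole-sample improved fraction).
#' @return An object of class `elbow_result`: `t_star`, `improvement_pct
#'   = 100 (1 - t_star)`, `D_obs`, `p_value`, `n_at_t_star`, `reference`,
#'   `B`, plus the evaluated `grid`, `f`, `ref` and `D` vectors.
#' @export
elbow_threshold <- function(curve, null, reference = c("null_mean", "diagonal"),
                            diagonal = c("identity", "overall_rate")) {
  stopifnot(inherits(curve, "responder_curve"),
            inherits(null, "permutation_null"))
  reference <- match.arg(reference)
  diagonal <- match.arg(diagonal)
  if (length(curve$grid) != length(null$grid) ||
      any(curve$grid != null$grid))
    stop("curve and null must share the same threshold grid")
  ref <- switch(reference,
                null_mean = null$mean_f,
                diagonal = if (diagonal == "identity") 1 - curve$grid
                else rep(curve$overall_rate, length(curve$grid)))
  defined <- !is.na(curve$f) & !is.na(ref)
  if (!any(defined))
    stop("no grid point with a defined responder fraction (all subgroups below n_min)")
  D <- curve$f - ref
  D[!defined] <- NA_real_
  i_star <- which.max(D)  # first index attaining the max = smallest t
  D_obs <- D[i_star]
  # replicate maxima against the same reference, same defined grid points
  D_b <- apply(null$f_rep[defined, , drop = FALSE] - ref[defined], 2, max)
  p <- (1 + sum(D_b >= D_obs)) / (1 + null$B)
  structure(list(t_star = curve$grid[i_star],
                 improvement_pct = 100 * (1 - curve$grid[i_star]),
                 D_obs = D_obs, p_value = p,
                 n_at_t_star = curve$n[i_star],
                 reference = reference,
                 diagonal = if (reference == "diagonal") diagonal else NA,
                 B = null$B, grid = curve$grid, f = curve$f, ref = ref, D = D),
            class = "elbow_result")
}

#' @export
print.elbow_result <- function(x, ...) {
  cat(sprintf("Elbow threshold: post/pre ratio t* = %.3f (%.0f%% improvement)\n",
              x$t_star, x$improvement_pct))
  cat(sprintf("  distance from %s reference D = %.4f (subgroup n = %d)\n",
              x$reference, x$D_obs, x$n_at_t_star))
  cat(sprintf("  permutation p = %.4g (B = %d shuffles)\n", x$p_value, x$B))
  invisible(x)
}

#' Serialize an elbow analysis to JSON
#'
#' @param result An `elbow_result`.
#' @param curve The [responder_curve()] it was computed from (optional).
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @export
elbow_json <- function(result, curve = NULL, path = NULL) {
  stopifnot(inherits(result, "elbow_result"))
  obj <- list(t_star = result$t_star,
              improvement_pct = result$improvement_pct,
              D_obs = result$D_obs, p_value = result$p_value,
              n_at_t_star = result$n_at_t_star,
              reference = result$reference, B = result$B,
              grid = result$grid, f = result$f, ref = result$ref)
  if (!is.null(curve)) obj$n <- curve$n
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
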