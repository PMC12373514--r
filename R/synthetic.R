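# Parametric planted-threshold cohort generator.
#
# The generator plants the statistical structure the threshold analysis looks
# for: in the active arm, the probability of further improvement between end
# of treatment and follow-up depends on whether the end-of-treatment ratio
# post/pre falls below a planted threshold theta. The sham arm is centered on
# no change, with a configurable number of planted deep responders whose
# improvement attenuates at follow-up.

#' Configuration for the planted-threshold cohort generator
#'
#' Defaults state the emulated trial: 28 completers per arm, baseline CAPS-5
#' totals approximately 43.8 +/- 9.1 truncated to 23-80 (the pooled
#' moderate-to-extreme severity range), and a planted sustained-response
#' threshold at a post/pre ratio of 0.65, i.e. 35% improvement.
#'
#' @param n_active,n_sham Arm sizes.
#' @param baseline_mean,baseline_sd,baseline_range Truncated-normal baseline
#'   total distribution (score points on the 0-80 scale).
#' @param theta Planted ratio threshold in (0,1): subjects with post/pre below
#'   `theta` sustain improvement with probability `p_sustain_below`, others
#'   with `p_sustain_above`.
#' @param p_sustain_below,p_sustain_above Sustain probabilities for the active
#'   arm, conditioned on post/pre vs `theta`.
#' @param sham_p_sustain Sustain probability applied uniformly in the sham arm
#'   (the threshold mechanism is a treatment property).
#' @param active_improvement_dist,sham_improvement_dist [dist_spec()]s for the
#'   post/pre ratio in each arm; active draws are truncated to (0, 1.2].
#' @param fup_step_dist [dist_spec()] for the magnitude of the further ratio
#'   change between post and follow-up.
#' @param cluster_weights Four nonnegative weights (B, C, D, E) for splitting
#'   totals into cluster subscores; normalized internally. Defaults to the
#'   item-count proportions 5:2:7:6.
#' @param cluster_jitter_sd Log-normal sd of the per-subject, per-timepoint
#'   jitter applied to `cluster_weights`, so cluster trajectories are not
#'   collinear with the total; 0 disables jitter.
#' @param sham_deep_responders Number of planted sham subjects with a deep
#'   (below-theta) response whose improvement attenuates at follow-up;
#'   default one per 28 sham subjects.
#' @param fup_driver_cluster `NULL`, or one of `"B","C","D","E"`: when set,
#'   the sustain decision is driven by that cluster's post/pre ratio instead
#'   of the total's.
#' @param seed Integer seed; `NULL` uses the ambient RNG stream.
#' @return An object of class `planted_config`.
#' @export
planted_config <- function(n_active = 28, n_sham = 28,
                           baseline_mean = 43.8, baseline_sd = 9.1,
                           baseline_range = c(23, 80),
                           theta = 0.65,
                           p_sustain_below = 0.9, p_sustain_above = 0.2,
                           sham_p_sustain = 0.15,
                           active_improvement_dist =
                             dist_spec("truncnorm", mean = 0.7, sd = 0.25,
                                       lower = 0.05, upper = 1.2),
                           sham_improvement_dist =
                             dist_spec("truncnorm", mean = 1.0, sd = 0.08,
                                       lower = 0.7, upper = 1.2),
                           fup_step_dist =
                             dist_spec("truncnorm", mean = 0.15, sd = 0.08,
                                       lower = 0.02, upper = 0.5),
                           cluster_weights = c(B = 5, C = 2, D = 7, E = 6),
                           cluster_jitter_sd = 0.15,
                           sham_deep_responders = round(n_sham / 28),
                           fup_driver_cluster = NULL,
                           seed = NULL) {
  stopifnot(n_active >= 0, n_sham >= 0,
            theta > 0, theta < 1,
            p_sustain_below >= 0, p_sustain_below <= 1,
            p_sustain_above >= 0, p_sustain_above <= 1,
            sham_p_sustain >= 0, sham_p_sustain <= 1,
            length(cluster_weights) == 4, all(cluster_weights >= 0),
            sum(cluster_weights) > 0, cluster_jitter_sd >= 0,
            length(baseline_range) == 2, baseline_range[1] < baseline_range[2])
  if (baseline_mean < baseline_range[1] || baseline_mean > baseline_range[2])
    stop("infeasible config: baseline_range excludes baseline_mean")
  if (!is.null(fup_driver_cluster))
    fup_driver_cluster <- match.arg(fup_driver_cluster, CLUSTERS)
  structure(list(n_active = n_active, n_sham = n_sham,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 baseline_range = baseline_range, theta = theta,
                 p_sustain_below = p_sustain_below,
                 p_sustain_above = p_sustain_above,
                 sham_p_sustain = sham_p_sustain,
                 active_improvement_dist = active_improvement_dist,
                 sham_improvement_dist = sham_improvement_dist,
                 fup_step_dist = fup_step_dist,
                 cluster_weights = cluster_weights / sum(cluster_weights),
                 cluster_jitter_sd = cluster_jitter_sd,
                 sham_deep_responders = sham_deep_responders,
                 fup_driver_cluster = fup_driver_cluster,
                 seed = seed),
            class = "planted_config")
}

# Split an integer total into the four cluster subscores by largest-remainder
# rounding of weight-proportional shares, respecting the per-cluster maxima
# (20/8/28/24) so the result always validates. Returns an integer vector of
# length 4 summing exactly to `total`.
decompose_total <- function(total, weights, caps = CLUSTER_MAX) {
  stopifnot(total >= 0, total <= sum(caps), all(weights >= 0))
  w <- weights / sum(weights)
  share <- total * w
  x <- floor(share)
  rem <- share - x
  deficit <- total - sum(x)
  if (deficit > 0) {
    ord <- order(rem, decreasing = TRUE)
    x[ord[seq_len(deficit)]] <- x[ord[seq_len(deficit)]] + 1
  }
  # cap enforcement: shift surplus units to the cluster furthest below target
  repeat {
    over <- which(x > caps)
    if (length(over) == 0) break
    k <- over[1]
    excess <- x[k] - caps[k]
    x[k] <- caps[k]
    for (u in seq_len(excess)) {
      slack <- which(x < caps)
      j <- slack[which.max(share[slack] - x[slack])]
      x[j] <- x[j] + 1
    }
  }
  as.integer(x)
}

# Decompose a vector of totals with per-row jittered weights; returns an
# n x 4 integer matrix with columns B, C, D, E.
decompose_totals <- function(totals, weights, jitter_sd) {
  n <- length(totals)
  out <- matrix(0L, n, 4, dimnames = list(NULL, CLUSTERS))
  for (i in seq_len(n)) {
    if (is.na(totals[i])) { out[i, ] <- NA_integer_; next }
    w <- weights
    if (jitter_sd > 0) w <- w * exp(stats::rnorm(4, 0, jitter_sd))
    out[i, ] <- decompose_total(totals[i], w)
  }
  out
}

#' Generate a cohort with a planted sustained-response threshold
#'
#' Baseline totals are drawn from the truncated-normal specification, end of
#' treatment totals via the arm's post/pre improvement distribution, and the
#' follow-up trajectory from the sustain probability appropriate to the arm
#' and to the subject's position relative to the planted threshold. Sustained
#' improvers get an integer follow-up total strictly below their posttreatment
#' total; all others get one at or above it, so the planted improved-at-fup
#' flag survives integer rounding exactly. Totals are decomposed into the four
#' cluster subscores by largest-remainder rounding, so generated cohorts
#' always pass [validate_cohort()].
#'
#' @param config A [planted_config()].
#' @return A [caps_cohort()]; metadata records the configuration. The
#'   attribute `"truth"` carries the per-subject planted quantities (ratio
#'   draws and sustain flags) for calibration experiments.
#' @export
generate_planted_cohort <- function(config) {
  stopifnot(inherits(config, "planted_config"))
  with_seed_if(config$seed, {
    arms <- c(rep("active", config$n_active), rep("sham", config$n_sham))
    n <- length(arms)
    ids <- sprintf("S%03d", seq_len(n))
    pre <- pmin(pmax(round(sample_dist(
      dist_spec("truncnorm", mean = config$baseline_mean,
                sd = config$baseline_sd,
                lower = config$baseline_range[1],
                upper = config$baseline_range[2]), n)),
      config$baseline_range[1]), config$baseline_range[2])
    post_ratio <- numeric(n)
    act <- arms == "active"
    post_ratio[act] <- sample_dist(config$active_improvement_dist, sum(act))
    post_ratio[!act] <- sample_dist(config$sham_improvement_dist, sum(!act))
    deep <- integer(0)
    if (config$sham_deep_responders > 0 && any(!act)) {
      deep <- utils::head(which(!act), config$sham_deep_responders)
      post_ratio[deep] <- stats::runif(length(deep), 0.4, config$theta - 0.05)
    }
    post <- pmin(pmax(round(post_ratio * pre), 1L), 80L)
    post_ratio_obs <- post / pre

    pre_cl <- decompose_totals(pre, config$cluster_weights,
                               config$cluster_jitter_sd)
    post_cl <- decompose_totals(post, config$cluster_weights,
                                config$cluster_jitter_sd)

    driver <- post_ratio_obs
    if (!is.null(config$fup_driver_cluster)) {
      k <- config$fup_driver_cluster
      dr <- post_cl[, k] / pre_cl[, k]
      driver <- ifelse(is.finite(dr), dr, post_ratio_obs)
    }
    p_sustain <- ifelse(act,
                        ifelse(driver < config$theta,
                               config$p_sustain_below, config$p_sustain_above),
                        config$sham_p_sustain)
    sustain <- stats::runif(n) < p_sustain
    sustain[deep] <- FALSE  # sham deep responders attenuate at follow-up
    step <- sample_dist(config$fup_step_dist, n)
    fup <- integer(n)
    up <- pmin(80L, pmax(post, round((post_ratio_obs + step) * pre)))
    down <- pmax(0L, pmin(post - 1L, round((post_ratio_obs - step) * pre)))
    fup[sustain] <- down[sustain]
    fup[!sustain] <- up[!sustain]
    fup_cl <- decompose_totals(fup, config$cluster_weights,
                               config$cluster_jitter_sd)

    rec <- data.frame(participant_id = ids, arm = arms,
                      total_pre = pre, B_pre = pre_cl[, "B"],
                      C_pre = pre_cl[, "C"], D_pre = pre_cl[, "D"],
                      E_pre = pre_cl[, "E"],
                      total_post = post, B_post = post_cl[, "B"],
                      C_post = post_cl[, "C"], D_post = post_cl[, "D"],
                      E_post = post_cl[, "E"],
                      total_fup = fup, B_fup = fup_cl[, "B"],
                      C_fup = fup_cl[, "C"], D_fup = fup_cl[, "D"],
                      E_fup = fup_cl[, "E"],
                      stringsAsFactors = FALSE)
    out <- caps_cohort(rec, metadata = list(
      generator = "planted", theta = config$theta, seed = config$seed))
    attr(out, "truth") <- data.frame(
      participant_id = ids, arm = arms, post_ratio = post_ratio_obs,
      driver_ratio = driver, sustain = sustain, stringsAsFactors = FALSE)
    out
  })
}
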