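# Mechanistic bistable (double-well) generator of treatment response.
#
# The latent symptom state x evolves in the quartic double-well potential
# U(x) = h (x^2 - 1)^2, with wells at x = -1 (healthy) and x = +1
# (pathological) separated by a barrier of height h at x = 0. Treatment is a
# constant bias d subtracted from the drift during the treatment phase only:
#
#   dx = [ -U'(x) - d * 1(treatment) ] dt + sigma dW,  U'(x) = 4 h x (x^2 - 1).
#
# A push strong enough to carry the state over the barrier lets it relax into
# the healthy well after treatment ends (sustained improvement); a weaker push
# moves the state partway up the barrier and it rolls back (transient
# improvement). The latent state maps affinely onto the 0-80 CAPS-5 scale.

#' Parameters of the bistable treatment-response simulator
#'
#' @param h Barrier height of the quartic potential (must be > 0). The
#'   deterministic saddle-node push is `8 h / (3 sqrt(3)) ~ 1.54 h`.
#' @param noise_sigma Diffusion amplitude (>= 0); 0 gives a deterministic
#'   integration.
#' @param push_d Treatment bias magnitude, applied only during the treatment
#'   phase.
#' @param t_treat,t_fup Durations of the treatment and post-treatment
#'   relaxation phases (simulator time units; the well relaxation time is
#'   `1/(8h)`). The default treatment phase is of the order of the
#'   barrier-transit time, so that treatment ends mid-transition and crossing
#'   subjects keep improving during follow-up — the phenomenon the model is
#'   for; `t_fup` defaults to 1.5 x `t_treat` (a 3-month follow-up after a
#'   60-day course). With the defaults the deterministic critical push is
#'   d* ~ 2.78 (vs the static saddle-node value 1.54).
#' @param dt Euler-Maruyama step. Must satisfy `dt <= 0.25 / h` (a quarter of
#'   the inverse well curvature `U''(+/-1) = 8h`); larger steps are rejected
#'   rather than allowed to diverge silently.
#' @param x0 Initial state (default +1, the pathological well).
#' @param caps_healthy,caps_sick Affine score map endpoints: latent -1 maps to
#'   `caps_healthy`, +1 to `caps_sick` (0-80 scale, `caps_sick > caps_healthy`).
#' @param measurement_noise_sd Score-scale measurement noise (points).
#' @param margin Terminal-well classification margin: HEALTHY iff final
#'   x < -margin, PATHOLOGICAL iff final x > +margin, else UNDECIDED.
#' @param seed Integer seed; `NULL` uses the ambient RNG stream.
#' @return An object of class `bistable_params`.
#' @export
bistable_params <- function(h = 1, noise_sigma = 0.1, push_d = 3,
                            t_treat = 0.6, t_fup = 0.9, dt = 0.01, x0 = 1,
                            caps_healthy = 10, caps_sick = 44,
                            measurement_noise_sd = 2, margin = 0.2,
                            seed = NULL) {
  stopifnot(h > 0, noise_sigma >= 0, dt > 0, t_treat >= 0, t_fup >= 0,
            caps_sick > caps_healthy, margin >= 0)
  if (dt > 0.25 / h)
    stop(sprintf(
      "dt = %g too large for stability: require dt <= 0.25/h = %g", dt,
      0.25 / h))
  structure(list(h = h, noise_sigma = noise_sigma, push_d = push_d,
                 t_treat = t_treat, t_fup = t_fup, dt = dt, x0 = x0,
                 caps_healthy = caps_healthy, caps_sick = caps_sick,
                 measurement_noise_sd = measurement_noise_sd,
                 margin = margin, seed = seed),
            class = "bistable_params")
}

# Vectorized Euler-Maruyama core: advances a vector of states through the
# treatment phase (bias d) then the follow-up phase (no bias). Returns the
# state at end of treatment and at final time.
integrate_wells <- function(x0, d, params) {
  h <- params$h; s <- params$noise_sigma; dt <- params$dt
  n1 <- round(params$t_treat / dt); n2 <- round(params$t_fup / dt)
  sq <- sqrt(dt)
  x <- x0
  step <- function(x, bias) {
    drift <- -4 * h * x * (x^2 - 1) - bias
    if (s > 0) x + drift * dt + s * sq * stats::rnorm(length(x))
    else x + drift * dt
  }
  for (i in seq_len(n1)) x <- step(x, d)
  x_treat <- x
  for (i in seq_len(n2)) x <- step(x, 0)
  list(x_treat = x_treat, x_final = x)
}

well_label <- function(x, margin) {
  ifelse(x < -margin, "HEALTHY", ifelse(x > margin, "PATHOLOGICAL",
                                        "UNDECIDED"))
}

#' Simulate one bistable treatment-response trajectory
#'
#' Euler-Maruyama integration of the biased double-well Langevin equation over
#' a treatment phase followed by an unbiased relaxation phase. With
#' `noise_sigma = 0` the integration is deterministic.
#'
#' @param params A [bistable_params()].
#' @return An object of class `bistable_trajectory`: `time`, `x`, `phase`
#'   (`"treatment"`/`"follow-up"`), and `terminal` in
#'   `{"HEALTHY","PATHOLOGICAL","UNDECIDED"}`.
#' @export
simulate_bistable_trajectory <- function(params) {
  stopifnot(inherits(params, "bistable_params"))
  with_seed_if(params$seed, {
    h <- params$h; s <- params$noise_sigma; dt <- params$dt
    n1 <- round(params$t_treat / dt); n2 <- round(params$t_fup / dt)
    x <- numeric(n1 + n2 + 1)
    x[1] <- params$x0
    sq <- sqrt(dt)
    for (i in seq_len(n1 + n2)) {
      bias <- if (i <= n1) params$push_d else 0
      drift <- -4 * h * x[i] * (x[i]^2 - 1) - bias
      x[i + 1] <- x[i] + drift * dt +
        (if (s > 0) s * sq * stats::rnorm(1) else 0)
    }
    structure(list(
      time = dt * (0:(n1 + n2)),
      x = x,
      phase = c(rep("treatment", n1 + 1), rep("follow-up", n2)),
      terminal = well_label(x[n1 + n2 + 1], params$margin),
      params = params), class = "bistable_trajectory")
  })
}

#' Map a latent bistable state to a CAPS-5 score
#'
#' Affine map of `clip(x, -1, +1)` from `[-1, +1]` onto
#' `[caps_healthy, caps_sick]`, plus optional measurement noise, rounded and
#' clipped to the 0-80 scale. The map is an artifact convention: no
#' quantitative link between the latent state and the clinical score is
#' claimed, only the ordering.
#'
#' @param x Latent state(s).
#' @param caps_healthy,caps_sick Score endpoints.
#' @param noise Optional vector of score-scale noise draws (default 0).
#' @return Integer score(s) in 0-80.
#' @export
map_state_to_caps <- function(x, caps_healthy, caps_sick, noise = 0) {
  stopifnot(caps_sick > caps_healthy)
  xc <- pmin(pmax(x, -1), 1)
  raw <- caps_healthy + (xc + 1) / 2 * (caps_sick - caps_healthy) + noise
  as.integer(pmin(pmax(round(raw), 0), 80))
}

#' Deterministic critical treatment push
#'
#' Locates, by bisection, the smallest push `d` for which the deterministic
#' (`noise_sigma = 0`) dynamics end in the healthy well after the treatment
#' and relaxation phases. For long treatment phases this approaches the
#' static saddle-node value `8 h / (3 sqrt(3))`; finite treatment duration
#' shifts it upward (the state must actually cross the barrier in time).
#'
#' @param params A [bistable_params()]; `noise_sigma` is ignored (forced to 0).
#' @param lower,upper Bracket for the bisection; `upper` must produce a
#'   healthy terminal state.
#' @param tol Bisection tolerance on d.
#' @return The critical push d* (numeric scalar).
#' @export
critical_push <- function(params, lower = 0, upper = 4 * params$h,
                          tol = 1e-4) {
  stopifnot(inherits(params, "bistable_params"))
  p <- params; p$noise_sigma <- 0
  healthy <- function(d)
    well_label(integrate_wells(p$x0, d, p)$x_final, p$margin) == "HEALTHY"
  if (healthy(lower)) return(lower)
  if (!healthy(upper)) stop("upper bracket does not induce a transition")
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (healthy(mid)) upper <- mid else lower <- mid
  }
  (lower + upper) / 2
}

#' Generate a cohort from the bistable simulator
#'
#' One latent trajectory per subject, with a subject-specific treatment push
#' drawn from `push_dist`. Baseline, end-of-treatment and follow-up scores are
#' the affine image of the latent state at the corresponding times plus
#' measurement noise; totals are decomposed into cluster subscores as in
#' [generate_planted_cohort()].
#'
#' @param params A [bistable_params()] shared by all subjects (its `push_d`
#'   is ignored in favor of draws from `push_dist`).
#' @param n Number of subjects (all labeled `active`; pair with a planted
#'   sham arm if a two-arm cohort is needed).
#' @param push_dist A [dist_spec()] for the per-subject push magnitude. The
#'   default spans roughly 0.5 to 1.2 times the critical push of the default
#'   dynamics, so the cohort mixes non-crossers with crossers that end
#'   treatment mid-descent (transient vs sustained responders).
#' @param cluster_weights,cluster_jitter_sd Cluster decomposition controls as
#'   in [planted_config()].
#' @param seed Integer seed; `NULL` uses the ambient RNG stream.
#' @return A [caps_cohort()] with attribute `"truth"`: per-subject push,
#'   latent states at POST and FUP times, and terminal well label.
#' @export
generate_bistable_cohort <- function(params, n,
                                     push_dist = dist_spec(
                                       "uniform", min = 1.4 * params$h,
                                       max = 3.35 * params$h),
                                     cluster_weights = c(B = 5, C = 2,
                                                         D = 7, E = 6),
                                     cluster_jitter_sd = 0.15,
                                     seed = NULL) {
  stopifnot(inherits(params, "bistable_params"), n >= 1)
  with_seed_if(seed, {
    pushes <- sample_dist(push_dist, n)
    st <- integrate_wells(rep(params$x0, n), pushes, params)
    noise <- function() stats::rnorm(n, 0, params$measurement_noise_sd)
    pre <- map_state_to_caps(rep(params$x0, n), params$caps_healthy,
                             params$caps_sick, noise())
    pre <- pmax(pre, 1L)  # guard: ratio analyses need a positive baseline
    post <- map_state_to_caps(st$x_treat, params$caps_healthy,
                              params$caps_sick, noise())
    fup <- map_state_to_caps(st$x_final, params$caps_healthy,
                             params$caps_sick, noise())
    w <- cluster_weights / sum(cluster_weights)
    pre_cl <- decompose_totals(pre, w, cluster_jitter_sd)
    post_cl <- decompose_totals(post, w, cluster_jitter_sd)
    fup_cl <- decompose_totals(fup, w, cluster_jitter_sd)
    ids <- sprintf("S%03d", seq_len(n))
    rec <- data.frame(participant_id = ids, arm = "active",
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
    out <- caps_cohort(rec, metadata = list(generator = "bistable",
                                            h = params$h, seed = seed))
    attr(out, "truth") <- data.frame(
      participant_id = ids, push = pushes, x_treat = st$x_treat,
      x_final = st$x_final,
      terminal = well_label(st$x_final, params$margin),
      stringsAsFactors = FALSE)
    out
  })
}
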