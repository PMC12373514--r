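# Pipeline orchestration: load or generate a cohort, validate, normalize,
# run the elbow, cluster-association and baseline-severity analyses, and
# bundle everything into a serializable run report.

SEVERITY_BANDS <- data.frame(
  band = c("Below moderate", "Moderate", "Severe", "Extreme"),
  lo = c(0, 23, 35, 51), hi = c(22, 34, 50, 80), stringsAsFactors = FALSE)

#' Pipeline configuration
#'
#' @param input_mode `"planted"` (parametric generator), `"bistable"`
#'   (mechanistic generator) or `"file"` (read a cohort table).
#' @param cohort_path Input path for `input_mode = "file"`.
#' @param planted A [planted_config()] for `"planted"` mode (default
#'   `planted_config()`; its seed is overridden by `seed`).
#' @param bistable A [bistable_params()] for `"bistable"` mode.
#' @param n_bistable,push_dist Cohort size and push distribution for
#'   `"bistable"` mode (see [generate_bistable_cohort()]).
#' @param arm Analysis arm (default `"active"`: the responder curve describes
#'   the treated arm; sham is summarized descriptively).
#' @param grid_step Threshold-grid step (default 0.05).
#' @param B_permutation,B_bootstrap Replicate counts.
#' @param n_min Minimum subgroup size for a defined responder fraction.
#' @param method Headline correlation method.
#' @param reference,diagonal Elbow reference (see [elbow_threshold()]).
#' @param seed Integer master seed; sub-seeds for generation, permutation and
#'   bootstrap are derived deterministically from it.
#' @param out_dir Output directory for [write_run_report()] (`NULL`: no
#'   files are written by [run_pipeline()] itself).
#' @return An object of class `run_config`.
#' @export
run_config <- function(input_mode = c("planted", "bistable", "file"),
                       cohort_path = NULL,
                       planted = planted_config(),
                       bistable = bistable_params(),
                       n_bistable = 28,
                       push_dist = NULL,
                       arm = "active",
                       grid_step = 0.05,
                       B_permutation = 1000,
                       B_bootstrap = 1000,
                       n_min = 3,
                       method = c("spearman", "pearson"),
                       reference = c("null_mean", "diagonal"),
                       diagonal = c("identity", "overall_rate"),
                       seed = 1,
                       out_dir = NULL) {
  input_mode <- match.arg(input_mode)
  method <- match.arg(method)
  reference <- match.arg(reference)
  diagonal <- match.arg(diagonal)
  if (input_mode == "file" && is.null(cohort_path))
    stop("input_mode = 'file' requires cohort_path")
  stopifnot(grid_step > 0, grid_step <= 0.5, B_permutation >= 1,
            B_bootstrap >= 100, n_min >= 1)
  structure(list(input_mode = input_mode, cohort_path = cohort_path,
                 planted = planted, bistable = bistable,
                 n_bistable = n_bistable, push_dist = push_dist,
                 arm = arm, grid_step = grid_step,
                 B_permutation = B_permutation, B_bootstrap = B_bootstrap,
                 n_min = n_min, method = method, reference = reference,
                 diagonal = diagonal, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

derive_seed <- function(seed, k) as.integer((seed + 10007L * k) %% 2147483647L)

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))
}

#' Summarize a cohort
#'
#' @param cohort A [caps_cohort()].
#' @return A list: per-arm n, baseline mean and SD of the total score, and
#'   counts per severity band (Moderate 23-34, Severe 35-50, Extreme 51-80).
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "caps_cohort"))
  df <- as.data.frame(cohort)
  per_arm <- lapply(c("active", "sham"), function(a) {
    sub <- df[df$arm == a, , drop = FALSE]
    b <- sub$total_pre[!is.na(sub$total_pre)]
    bands <- vapply(seq_len(nrow(SEVERITY_BANDS)), function(i)
      sum(b >= SEVERITY_BANDS$lo[i] & b <= SEVERITY_BANDS$hi[i]), integer(1))
    names(bands) <- SEVERITY_BANDS$band
    list(n = nrow(sub),
         baseline_mean = if (length(b)) mean(b) else NA_real_,
         baseline_sd = if (length(b) > 1) stats::sd(b) else NA_real_,
         severity_bands = as.list(bands))
  })
  names(per_arm) <- c("active", "sham")
  c(list(n_total = nrow(df)), per_arm)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load or generate the cohort; validate; summarize;
#' normalize to baseline; responder curve, permutation null and elbow
#' threshold; cluster-association matrices; baseline-severity analysis; sham
#' descriptive counts (when a sham arm is present). Any stage failure aborts
#' with a stage-labeled error. Identical config and seed reproduce every
#' number.
#'
#' @param config A [run_config()].
#' @return An object of class `run_report`; see [write_run_report()] for
#'   serialization.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- stage("input", switch(
    config$input_mode,
    planted = {
      pc <- config$planted
      pc$seed <- derive_seed(config$seed, 1L)
      generate_planted_cohort(pc)
    },
    bistable = {
      pd <- config$push_dist
      if (is.null(pd))
        pd <- dist_spec("uniform", min = 1.4 * config$bistable$h,
                        max = 3.35 * config$bistable$h)
      generate_bistable_cohort(config$bistable, config$n_bistable,
                               push_dist = pd,
                               seed = derive_seed(config$seed, 1L))
    },
    file = read_cohort(config$cohort_path)))
  validation <- stage("validate", validate_cohort(cohort))
  summary <- stage("summarize", summarize_cohort(cohort))
  grid <- default_grid(config$grid_step)
  outcomes <- stage("normalize",
                    suppressMessages(normalize_cohort(cohort, config$arm)))
  curve <- stage("responder_curve",
                 responder_curve(outcomes, grid, config$n_min))
  null <- stage("permutation_null",
                permutation_null(outcomes, grid, B = config$B_permutation,
                                 n_min = config$n_min,
                                 seed = derive_seed(config$seed, 2L)))
  elbow <- stage("elbow",
                 elbow_threshold(curve, null, config$reference,
                                 config$diagonal))
  assoc <- stage("associations",
                 association_matrices(cohort, config$arm, config$method,
                                      B = config$B_bootstrap,
                                      seed = derive_seed(config$seed, 3L)))
  severity <- stage("baseline_severity",
                    baseline_severity_analysis(cohort, config$arm))
  sham <- if (any(cohort$arm == "sham"))
    stage("sham_counts", sham_threshold_count(cohort)) else NULL
  structure(list(config = config, cohort = cohort,
                 validation = validation, summary = summary,
                 outcomes = outcomes, curve = curve, null = null,
                 elbow = elbow, associations = assoc,
                 baseline_severity = severity, sham_counts = sham,
                 n_excluded = attr(outcomes, "n_excluded")),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("== capsthresh run report ==\n")
  cat(sprintf("cohort: %d participants (%d active / %d sham), %d excluded from ratio analyses\n",
              x$summary$n_total, x$summary$active$n, x$summary$sham$n,
              x$n_excluded))
  cat(sprintf("validation: %s\n", if (x$validation$pass) "PASS" else "FAIL"))
  print(x$elbow)
  cat("strongest cluster association per comparison:\n")
  for (tag in names(x$associations)) {
    m <- x$associations[[tag]]
    i <- which.max(abs(m$r))
    cat(sprintf("  %-26s cluster %s: r = %.3f (p_boot = %.3g)\n",
                tag, m$cluster[i], m$r[i], m$p_bootstrap[i]))
  }
  if (!is.null(x$baseline_severity$mann_whitney)) {
    cat("baseline severity, improved vs worsened at follow-up: ")
    print(x$baseline_severity$mann_whitney)
  }
  invisible(x)
}

report_to_list <- function(report) {
  cfg <- report$config
  list(
    config = list(input_mode = cfg$input_mode, arm = cfg$arm,
                  grid_step = cfg$grid_step,
                  B_permutation = cfg$B_permutation,
                  B_bootstrap = cfg$B_bootstrap, n_min = cfg$n_min,
                  method = cfg$method, reference = cfg$reference,
                  diagonal = cfg$diagonal, seed = cfg$seed),
    cohort_summary = report$summary,
    n_excluded = report$n_excluded,
    validation = list(pass = report$validation$pass,
                      n_violations = nrow(report$validation$violations)),
    elbow = list(t_star = report$elbow$t_star,
                 improvement_pct = report$elbow$improvement_pct,
                 D_obs = report$elbow$D_obs,
                 p_value = report$elbow$p_value,
                 n_at_t_star = report$elbow$n_at_t_star,
                 reference = report$elbow$reference,
                 B = report$elbow$B,
                 grid = report$elbow$grid, f = report$elbow$f,
                 ref = report$elbow$ref),
    associations = report$associations,
    baseline_severity = list(
      correlations = report$baseline_severity$correlations,
      split = report$baseline_severity$split,
      mann_whitney = if (is.null(report$baseline_severity$mann_whitney)) NULL
      else unclass(report$baseline_severity$mann_whitney)),
    sham_counts = report$sham_counts)
}

#' Write a run report and its artifacts to a directory
#'
#' Writes `report.json` (the full analysis report), `cohort.csv` (the
#' analyzed cohort), `responder_curve.csv`, `associations.csv` and
#' `validation.json`. No timestamps are embedded: regenerating with the same
#' config and seed yields byte-identical files.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(jsonlite::toJSON(report_to_list(report), auto_unbox = TRUE,
                              digits = NA, pretty = TRUE, na = "null"),
             file.path(dir, "report.json"))
  write_cohort(report$cohort, file.path(dir, "cohort.csv"))
  utils::write.csv(
    data.frame(threshold = report$curve$grid, f = report$curve$f,
               n = report$curve$n, null_mean = report$null$mean_f),
    file.path(dir, "responder_curve.csv"), row.names = FALSE, na = "")
  utils::write.csv(do.call(rbind, report$associations),
                   file.path(dir, "associations.csv"), row.names = FALSE,
                   na = "")
  validation_report_json(report$validation, file.path(dir, "validation.json"))
  invisible(dir)
}
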