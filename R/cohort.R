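# CAPS-5 cohort container, delimited-text I/O and validation.
#
# The CAPS-5 total is the sum of 20 items rated 0-4, grouped into four symptom
# clusters: B intrusion (5 items, 0-20), C avoidance (2 items, 0-8),
# D negative cognition/mood (7 items, 0-28), E arousal/reactivity (6 items,
# 0-24). Totals range 0-80. A cohort stores the total and the four cluster
# subscores at three timepoints: baseline (pre), end of treatment (post) and
# 3-month follow-up (fup).

CLUSTERS <- c("B", "C", "D", "E")
CLUSTER_ITEMS <- c(B = 5L, C = 2L, D = 7L, E = 6L)
CLUSTER_MAX <- CLUSTER_ITEMS * 4L
TIMEPOINTS <- c("pre", "post", "fup")

# canonical header order: participant_id, arm, total_pre, B_pre, ..., E_fup
COHORT_COLUMNS <- c("participant_id", "arm",
                    unlist(lapply(TIMEPOINTS, function(tp)
                      paste0(c("total", CLUSTERS), "_", tp))))

ARM_ALIASES <- c(
  "active" = "active", "hbot" = "active", "treatment" = "active",
  "sham" = "sham", "control" = "sham", "placebo" = "sham"
)

score_cols <- function() setdiff(COHORT_COLUMNS, c("participant_id", "arm"))

#' Construct a CAPS-5 cohort
#'
#' @param records A data frame with the canonical cohort columns
#'   (`participant_id`, `arm`, then `total`/`B`/`C`/`D`/`E` at each of
#'   `pre`/`post`/`fup`, e.g. `total_pre`, `B_pre`, ...). Scores are integers;
#'   missing follow-up is `NA`.
#' @param metadata Free-form provenance list (source path, generator config).
#' @return An object of class `caps_cohort` (a data frame).
#' @seealso [read_cohort()], [validate_cohort()], [generate_planted_cohort()]
#' @export
caps_cohort <- function(records, metadata = list()) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing <- setdiff(COHORT_COLUMNS, names(records))
  if (length(missing) > 0)
    stop("missing cohort column(s): ", paste(missing, collapse = ", "))
  records <- records[, COHORT_COLUMNS]
  records$participant_id <- as.character(records$participant_id)
  records$arm <- canonical_arm(records$arm)
  for (col in score_cols()) {
    v <- records[[col]]
    if (is.character(v)) v[!nzchar(trimws(v))] <- NA
    v <- suppressWarnings(as.numeric(v))
    records[[col]] <- as.integer(round(v))
  }
  structure(records, class = c("caps_cohort", "data.frame"),
            metadata = metadata)
}

canonical_arm <- function(arm) {
  key <- tolower(trimws(as.character(arm)))
  mapped <- ARM_ALIASES[key]
  bad <- is.na(mapped) & !is.na(key)
  if (any(bad))
    stop("unknown arm label(s): ", paste(unique(key[bad]), collapse = ", "),
         " (accepted: ", paste(names(ARM_ALIASES), collapse = ", "), ")")
  unname(mapped)
}

#' @export
print.caps_cohort <- function(x, ...) {
  cat(sprintf("CAPS-5 cohort: %d participants (%d active, %d sham)\n",
              nrow(x), sum(x$arm == "active"), sum(x$arm == "sham")))
  meta <- attr(x, "metadata")
  if (!is.null(meta$source)) cat("source:", meta$source, "\n")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Read a cohort table from delimited text
#'
#' Expects a UTF-8 header row with the canonical column names. Arm labels are
#' mapped through an alias table on read (`HBOT`/`treatment` -> `active`,
#' `control`/`placebo` -> `sham`, case-insensitive). Empty cells are missing
#' values (complete-case exclusion happens downstream, never here). Cells that
#' are neither blank nor integer-valued raise an error naming every offending
#' cell, so malformed rows are reported rather than silently dropped.
#'
#' @param path Path to the file.
#' @param sep Field delimiter; `","` (default) or `"\t"`.
#' @return A [caps_cohort()] whose metadata records the source path.
#' @export
read_cohort <- function(path, sep = ",") {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""),
                           strip.white = TRUE, quote = "\"",
                           fileEncoding = "UTF-8")
  missing <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing) > 0)
    stop("cohort file ", path, " lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  bad <- character(0)
  for (col in score_cols()) {
    v <- raw[[col]]
    num <- suppressWarnings(as.numeric(v))
    not_num <- !is.na(v) & is.na(num)
    not_int <- !is.na(num) & num != round(num)
    for (i in which(not_num | not_int))
      bad <- c(bad, sprintf("row %d, column %s: '%s'", i, col, v[i]))
  }
  if (length(bad) > 0)
    stop("non-integer score cell(s) in ", path, ":\n  ",
         paste(bad, collapse = "\n  "))
  caps_cohort(raw, metadata = list(source = path))
}

#' Write a cohort table to delimited text
#'
#' Canonical arm labels (`active`/`sham`) are written; missing scores become
#' empty cells. `read_cohort(write_cohort(x, f))` reproduces every score field
#' exactly.
#'
#' @param cohort A [caps_cohort()].
#' @param path Output path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  stopifnot(inherits(cohort, "caps_cohort"))
  df <- as.data.frame(cohort)[, COHORT_COLUMNS, drop = FALSE]
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a cohort against the CAPS-5 scoring rules
#'
#' Checks every record against every rule and reports all violations (never
#' just the first; validation reports, it does not throw). Rules:
#' \describe{
#'   \item{`id-duplicate`}{participant ids unique within the cohort}
#'   \item{`total-range`}{totals within 0-80}
#'   \item{`cluster-B-range` ... `cluster-E-range`}{cluster subscores within
#'     item-count x 4 (20/8/28/24)}
#'   \item{`cluster-sum`}{total equals B+C+D+E at each timepoint}
#'   \item{`incomplete-timepoint`}{a timepoint has some but not all five
#'     scores present}
#'   \item{`pre-zero`}{baseline total of 0 (warning class): post/pre ratios
#'     are undefined, the record is excluded from ratio analyses downstream}
#' }
#'
#' @param cohort A [caps_cohort()].
#' @return A `validation_report`: list with `pass` (TRUE iff no violations)
#'   and a `violations` data frame (`record_id`, `rule`, `severity`,
#'   `message`).
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "caps_cohort"))
  v <- list()
  add <- function(id, rule, severity, message)
    v[[length(v) + 1]] <<- data.frame(record_id = id, rule = rule,
                                      severity = severity, message = message,
                                      stringsAsFactors = FALSE)
  dup <- cohort$participant_id[duplicated(cohort$participant_id)]
  for (id in unique(dup))
    add(id, "id-duplicate", "error", "participant_id occurs more than once")
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$participant_id[i]
    for (tp in TIMEPOINTS) {
      cols <- paste0(c("total", CLUSTERS), "_", tp)
      vals <- as.integer(cohort[i, cols])
      pres <- !is.na(vals)
      if (!any(pres)) next
      if (!all(pres)) {
        add(id, "incomplete-timepoint", "error",
            sprintf("timepoint %s has %d of 5 scores present", tp, sum(pres)))
        next
      }
      tot <- vals[1]; cl <- vals[-1]
      if (tot < 0 || tot > 80)
        add(id, "total-range", "error",
            sprintf("total_%s = %d outside 0-80", tp, tot))
      for (k in seq_along(CLUSTERS)) {
        if (cl[k] < 0 || cl[k] > CLUSTER_MAX[k])
          add(id, sprintf("cluster-%s-range", CLUSTERS[k]), "error",
              sprintf("%s_%s = %d outside 0-%d", CLUSTERS[k], tp, cl[k],
                      CLUSTER_MAX[k]))
      }
      if (tot != sum(cl))
        add(id, "cluster-sum", "error",
            sprintf("total_%s = %d but clusters sum to %d", tp, tot, sum(cl)))
    }
    if (!is.na(cohort$total_pre[i]) && cohort$total_pre[i] == 0)
      add(id, "pre-zero", "warning",
          "baseline total is 0; post/pre ratios undefined")
  }
  violations <- if (length(v) == 0) {
    data.frame(record_id = character(0), rule = character(0),
               severity = character(0), message = character(0),
               stringsAsFactors = FALSE)
  } else do.call(rbind, v)
  structure(list(pass = nrow(violations) == 0, violations = violations),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("cohort validation:", if (x$pass) "PASS" else
    sprintf("FAIL (%d violation(s))", nrow(x$violations)), "\n")
  if (nrow(x$violations) > 0) print(x$violations)
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' @param report A `validation_report` from [validate_cohort()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @export
validation_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "validation_report"))
  js <- jsonlite::toJSON(list(pass = report$pass,
                              violations = report$violations),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
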