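# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed when one is supplied, restoring the caller's
# RNG state afterwards; with seed = NULL the ambient RNG stream is used.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Distribution specification
#'
#' A small declarative spec for the scalar distributions used by the cohort
#' generators. Two families are supported: a normal distribution truncated to
#' `[lower, upper]` and a uniform distribution on `[min, max]`.
#'
#' @param dist `"truncnorm"` or `"uniform"`.
#' @param mean,sd Location and scale for `"truncnorm"`.
#' @param lower,upper Truncation bounds for `"truncnorm"`.
#' @param min,max Support for `"uniform"`.
#' @return An object of class `dist_spec`.
#' @export
dist_spec <- function(dist = c("truncnorm", "uniform"),
                      mean = 0, sd = 1, lower = -Inf, upper = Inf,
                      min = 0, max = 1) {
  dist <- match.arg(dist)
  if (dist == "truncnorm") {
    stopifnot(sd > 0, lower < upper)
    out <- list(dist = dist, mean = mean, sd = sd, lower = lower, upper = upper)
  } else {
    stopifnot(min <= max)
    out <- list(dist = dist, min = min, max = max)
  }
  structure(out, class = "dist_spec")
}

# Draw n values from a dist_spec. Truncated-normal sampling is by inverse CDF,
# which is exact and vectorized.
sample_dist <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"))
  if (spec$dist == "truncnorm") {
    plo <- stats::pnorm(spec$lower, spec$mean, spec$sd)
    phi <- stats::pnorm(spec$upper, spec$mean, spec$sd)
    u <- stats::runif(n, plo, phi)
    stats::qnorm(u, spec$mean, spec$sd)
  } else {
    stats::runif(n, spec$min, spec$max)
  }
}

# All permutations of 1:n as an n! x n matrix (test hook for exact permutation
# inference; n must be small).
#' @rdname permutation_null
#' @param n Number of elements; must be at most 7.
#' @export
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 7)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), n - 1))
  }
  do.call(rbind, out)
}
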