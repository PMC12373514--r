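# Fixtures and independent oracles used across the suite. The oracles
# deliberately avoid the package's own code paths (and, where the package
# delegates to stats::, those routines too): naive loops and full
# enumeration only.

toy_cohort_path <- function() {
  system.file("extdata", "toy_cohort.csv", package = "capsthresh")
}

# The 4-subject worked example: (post_ratio, fup_ratio) pairs.
toy4_outcomes <- function() {
  as_normalized_outcomes(post_ratio = c(0.5, 0.6, 0.8, 0.9),
                         fup_ratio = c(0.4, 0.7, 0.7, 1.0))
}

# A small hand-checkable cohort builder: one record per row of `scores`,
# a list of c(pre, post, fup) totals; clusters split as 'total - 3*k' style
# fixed shares with exact sums.
make_cohort <- function(totals, arm = "active", ids = NULL) {
  n <- length(totals)
  if (is.null(ids)) ids <- sprintf("P%02d", seq_len(n))
  split4 <- function(tot) {
    b <- pmin(20L, tot %/% 4L + tot %% 4L)
    c0 <- pmin(8L, tot %/% 8L)
    d <- pmin(28L, tot %/% 3L)
    e <- tot - b - c0 - d
    stopifnot(e >= 0, e <= 24)
    c(b, c0, d, e)
  }
  rows <- lapply(seq_len(n), function(i) {
    tp <- totals[[i]]
    cl <- lapply(tp, split4)
    data.frame(participant_id = ids[i], arm = rep_len(arm, n)[i],
               total_pre = tp[1], B_pre = cl[[1]][1], C_pre = cl[[1]][2],
               D_pre = cl[[1]][3], E_pre = cl[[1]][4],
               total_post = tp[2], B_post = cl[[2]][1], C_post = cl[[2]][2],
               D_post = cl[[2]][3], E_post = cl[[2]][4],
               total_fup = tp[3], B_fup = cl[[3]][1], C_fup = cl[[3]][2],
               D_fup = cl[[3]][3], E_fup = cl[[3]][4],
               stringsAsFactors = FALSE)
  })
  caps_cohort(do.call(rbind, rows))
}

# --- independent oracles -------------------------------------------------

# Mid-ranks from first principles: r_i = #(x < x_i) + (1 + #(x == x_i)) / 2.
oracle_midranks <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (1 + sum(x == xi)) / 2, numeric(1))
}

# Spearman via explicit product-moment formula on oracle mid-ranks.
oracle_spearman <- function(x, y) {
  rx <- oracle_midranks(x); ry <- oracle_midranks(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_mw_exact <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  pooled <- c(g1, g2)
  rk <- oracle_midranks(pooled)
  U_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  U_all <- apply(idx, 2, function(j) sum(rk[j]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(U_all <= U_obs), mean(U_all >= U_obs))
  list(U = U_obs, p = min(1, p))
}

# Naive responder curve: explicit loops over grid and subjects.
oracle_curve <- function(post, fup, grid, n_min) {
  f <- rep(NA_real_, length(grid)); n <- integer(length(grid))
  for (j in seq_along(grid)) {
    sel <- which(post < grid[j])
    n[j] <- length(sel)
    if (n[j] >= n_min) f[j] <- mean(fup[sel] < post[sel])
  }
  list(f = f, n = n)
}

# Exhaustive-permutation elbow p-value: enumerate every assignment of fup
# values, compute each permutation's own maximal distance to the reference,
# and apply the add-one counting formula. `ref` is a vector on the grid.
oracle_elbow_exhaustive_p <- function(post, fup, grid, n_min, ref) {
  ord <- order(post, fup)
  post <- post[ord]; fup <- fup[ord]
  n <- length(post)
  obs <- oracle_curve(post, fup, grid, n_min)
  ok <- !is.na(obs$f) & !is.na(ref)
  D_obs <- max(obs$f[ok] - ref[ok])
  perms <- all_permutations(n)
  D_max <- apply(perms, 1, function(p) {
    cb <- oracle_curve(post, fup[p], grid, n_min)
    max(cb$f[ok] - ref[ok])
  })
  list(D_obs = D_obs,
       p = (1 + sum(D_max >= D_obs)) / (1 + nrow(perms)))
}
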