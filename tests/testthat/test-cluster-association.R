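test_that("cluster ratios: arithmetic, zero-baseline guard, identity", {
  co <- read_cohort(toy_cohort_path())
  cr <- cluster_ratios(co, "active")
  expect_equal(cr$C_post_ratio[1], 2 / 4)
  expect_equal(cr$B_fup_ratio[2], 4 / 13)
  # zero cluster baseline: only that cluster becomes undefined
  df <- as.data.frame(co)
  df$C_pre[1] <- 0L; df$B_pre[1] <- df$B_pre[1] + 4L
  cr2 <- suppressMessages(cluster_ratios(caps_cohort(df), "active"))
  expect_true(is.na(cr2$C_post_ratio[1]))
  expect_false(is.na(cr2$B_post_ratio[1]))
  # unchanged scores -> all ratios 1
  co3 <- make_cohort(list(c(40, 40, 40)))
  cr3 <- cluster_ratios(co3, "active")
  expect_true(all(unlist(cr3[, -1]) == 1))
})

test_that("Spearman/Pearson agree with the independent mid-rank oracle", {
  # perfect monotone and reversed
  x <- c(1, 3, 4, 7, 9)
  expect_equal(correlate(x, exp(x), "spearman")$r, 1)
  expect_equal(correlate(x, -x^3, "spearman")$r, -1)
  expect_equal(correlate(x, 2 * x + 1, "pearson")$r, 1)

  # property sweep, n <= 8, heavy ties included
  for (s in 1:60) {
    set.seed(s)
    n <- sample(4:8, 1)
    x <- sample(1:4, n, replace = TRUE) + ifelse(s %% 2, 0, 0.5 * runif(n))
    y <- sample(1:5, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(correlate(x, y, "spearman")$r, oracle_spearman(x, y),
                 tolerance = 1e-12)
  }

  # invariance under strictly monotone transformations (Spearman only)
  set.seed(8)
  x <- runif(20); y <- runif(20)
  r0 <- correlate(x, y, "spearman")$r
  expect_equal(correlate(exp(3 * x), y, "spearman")$r, r0)
  expect_equal(correlate(x, qlogis(y), "spearman")$r, r0)

  # degenerate input is reported, not NaN-propagated
  r <- correlate(rep(2, 5), 1:5)
  expect_true(r$undefined)
  expect_true(is.na(r$r))
  expect_error(correlate(1:2, 2:3), "at least 3")
})

test_that("bootstrap inference: determinism, degenerate CI, width shrinks with n", {
  x <- 1:12
  y <- 2 * x
  b1 <- bootstrap_inference(x, y, "spearman", B = 200, seed = 5)
  b2 <- bootstrap_inference(x, y, "spearman", B = 200, seed = 5)
  expect_identical(b1, b2)
  # perfectly correlated data: every resample has r = 1
  expect_equal(b1$ci95, c(1, 1))
  expect_equal(b1$p_bootstrap, 2 / (1 + b1$B_effective))

  width <- function(n, s) {
    set.seed(s)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    ci <- bootstrap_inference(x, y, "pearson", B = 200, seed = s)$ci95
    diff(ci)
  }
  w20 <- mean(vapply(1:8, function(s) width(20, s), numeric(1)))
  w200 <- mean(vapply(1:8, function(s) width(200, s), numeric(1)))
  expect_lt(w200, w20)
})

test_that("association matrices: degenerate single-driver cohort and determinism", {
  # totals change only through cluster B; other clusters constant
  base <- c(B = 10L, C = 4L, D = 14L, E = 12L)
  rows <- lapply(1:8, function(i) {
    b_post <- 10L - i; b_fup <- max(0L, 10L - i - 1L)
    data.frame(participant_id = sprintf("P%d", i), arm = "active",
               total_pre = 40L, B_pre = 10L, C_pre = 4L, D_pre = 14L,
               E_pre = 12L,
               total_post = 30L + (10L - i) - 10L + 10L, B_post = b_post,
               C_post = 4L, D_post = 14L, E_post = 12L,
               total_fup = 30L + b_fup, B_fup = b_fup, C_fup = 4L,
               D_fup = 14L, E_fup = 12L, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$total_post <- df$B_post + df$C_post + df$D_post + df$E_post
  df$total_fup <- df$B_fup + df$C_fup + df$D_fup + df$E_fup
  co <- caps_cohort(df)
  am <- association_matrices(co, "active", "spearman", B = 200, seed = 2)
  a <- am$POST_VS_POST_TOTAL
  expect_equal(a$r[a$cluster == "B"], 1)
  expect_true(all(is.na(a$r[a$cluster != "B"])))

  # full determinism of all 12 results under a fixed seed
  am2 <- association_matrices(co, "active", "spearman", B = 200, seed = 2)
  expect_identical(am, am2)
})

test_that("planted cluster-C follow-up dependence surfaces in comparison (c)", {
  cfg <- planted_config(n_active = 150, n_sham = 0, fup_driver_cluster = "C",
                        cluster_jitter_sd = 0.25, seed = 12)
  co <- generate_planted_cohort(cfg)
  am <- association_matrices(co, "active", "spearman", B = 200, seed = 3)
  cc <- am$POSTCLUSTER_VS_FUP_TOTAL
  expect_gt(cc$r[cc$cluster == "C"], cc$r[cc$cluster == "E"])
})

test_that("sham counts: boundaries and degenerate cohorts", {
  co <- read_cohort(toy_cohort_path())
  counts <- sham_threshold_count(co, 35)
  expect_identical(counts$n_sham, 2L)
  expect_identical(counts$deep_responders, 1L)  # S2: 25/42
  expect_identical(counts$cluster_C_improved, 2L)
  expect_identical(counts$cluster_C_attenuated, 2L)
  # all-unchanged sham arm: zero everywhere
  still <- make_cohort(list(c(40, 40, 40), c(35, 35, 35)), arm = "sham")
  c0 <- sham_threshold_count(still)
  expect_identical(c0$deep_responders, 0L)
  expect_identical(c0$cluster_C_improved, 0L)
  # improvement_pct = 0 counts every strict improver
  expect_identical(sham_threshold_count(co, 0)$deep_responders, 2L)
  expect_error(sham_threshold_count(make_cohort(list(c(40, 30, 20)))),
               "no sham")
})
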