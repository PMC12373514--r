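test_that("baseline-outcome correlation: constructed exact cases", {
  # improvement an exact linear function of baseline -> Pearson r = 1
  pre <- c(30L, 36L, 42L, 48L, 54L, 60L)
  post <- as.integer(round(pre * (1 - (pre - 20) / 100)))
  co <- make_cohort(lapply(seq_along(pre),
                           function(i) c(pre[i], post[i], post[i])))
  r <- baseline_outcome_correlation(co, "active", "post", "pearson")
  expect_gt(r$r, 0.99)  # integer rounding keeps it just below exactly 1
  expect_equal(baseline_outcome_correlation(co, "active", "post",
                                            "spearman")$r, 1)

  # improvement independent of baseline: small mean |r| across simulations
  rs <- vapply(1:60, function(s) {
    co <- generate_planted_cohort(planted_config(n_active = 56, n_sham = 0,
                                                 seed = s))
    baseline_outcome_correlation(co, "active", "fup", "spearman")$r
  }, numeric(1))
  expect_lt(mean(abs(rs)), 0.15)
  # deterministic under a fixed generator seed
  co1 <- generate_planted_cohort(planted_config(seed = 77))
  expect_identical(baseline_outcome_correlation(co1, "active", "post"),
                   baseline_outcome_correlation(co1, "active", "post"))
})

test_that("follow-up trajectory split: hand partition and tie rule", {
  co <- make_cohort(list(c(40, 30, 25), c(44, 30, 35),
                         c(36, 30, 30), c(50, 20, 10)))
  expect_message(sp <- split_by_fup_trajectory(co, "active"), "1 exact tie")
  expect_setequal(sp$improved, c(40, 50))
  expect_setequal(sp$worsened, c(44, 36))  # the tie (36) lands in WORSENED
  expect_identical(sp$tie_ids, "P03")
  expect_false(sp$degenerate)

  # all improve -> worsened empty, flagged
  all_up <- make_cohort(list(c(40, 30, 20), c(44, 30, 22)))
  sp2 <- split_by_fup_trajectory(all_up, "active")
  expect_identical(length(sp2$worsened), 0L)
  expect_true(sp2$degenerate)
})

test_that("Mann-Whitney: exact distribution, enumeration oracle, approximation", {
  # {1,2} vs {3,4}: U = 0, exact two-sided p = 2/C(4,2) = 1/3
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_identical(mw$mode, "EXACT")
  expect_equal(mw$U, 0)
  expect_equal(mw$p_two_sided, 1 / 3)

  # identical groups (all ties): U = n1 n2 / 2, p = 1
  mw2 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_identical(mw2$mode, "NORMAL_APPROX")
  expect_equal(mw2$U, 4.5)
  expect_equal(mw2$p_two_sided, 1)

  # oracle equivalence sweep: tie-free random draws, n1 = n2 = 5
  for (s in 1:25) {
    set.seed(s)
    g1 <- rnorm(5); g2 <- rnorm(5, mean = runif(1, -1, 1))
    mw <- mann_whitney(g1, g2)
    orc <- oracle_mw_exact(g1, g2)
    expect_identical(mw$mode, "EXACT")
    expect_equal(mw$U, orc$U)
    expect_equal(mw$p_two_sided, orc$p)
  }

  # U is invariant under strictly monotone transformation of pooled values
  set.seed(3)
  g1 <- runif(8); g2 <- runif(6)
  expect_equal(mann_whitney(g1, g2)$U,
               mann_whitney(exp(5 * g1), exp(5 * g2))$U)
  expect_true(mann_whitney(g1, g2)$U >= 0 &&
                mann_whitney(g1, g2)$U <= 8 * 6)

  # exact vs normal approximation agree closely by n1 = n2 = 12
  for (s in 1:10) {
    set.seed(s + 100)
    g1 <- rnorm(12); g2 <- rnorm(12, 0.3)
    p_exact <- mann_whitney(g1, g2)$p_two_sided
    # force the approximation by adding a far-away 13th point to group 2,
    # then drop it: instead compare against the formula directly
    N <- 24; U <- mann_whitney(g1, g2)$U
    z <- (U - 72 - sign(U - 72) * 0.5) / sqrt(12 * 12 / 12 * (N + 1))
    p_norm <- 2 * pnorm(-abs(z))
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("null calibration of the exact test", {
  rej <- vapply(1:400, function(s) {
    set.seed(s)
    mann_whitney(rnorm(8), rnorm(8))$p_two_sided <= 0.05
  }, logical(1))
  # exact test is valid, slightly conservative due to discreteness
  expect_lte(mean(rej), 0.05 + 2 * sqrt(0.05 * 0.95 / 400))
})

test_that("bundled baseline-severity analysis is complete and consistent", {
  co <- generate_planted_cohort(planted_config(seed = 21))
  res <- baseline_severity_analysis(co, "active")
  expect_identical(nrow(res$correlations), 4L)
  expect_setequal(res$correlations$method, c("SPEARMAN", "PEARSON"))
  expect_identical(res$split$n_improved + res$split$n_worsened, 28L)
  expect_s3_class(res$mann_whitney, "mann_whitney_result")
  expect_identical(res$mann_whitney$n1, res$split$n_improved)
})
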