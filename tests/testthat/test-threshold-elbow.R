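test_that("normalization arithmetic, strict improvement flag, exclusions", {
  co <- make_cohort(list(c(40, 26, 20), c(40, 40, 40), c(50, 30, 30)))
  out <- normalize_cohort(co, "active")
  expect_equal(out$post_ratio, c(0.65, 1.0, 0.6))
  expect_equal(out$fup_ratio, c(0.50, 1.0, 0.6))
  # strict inequality: equal ratios are not improvement
  expect_identical(out$improved_at_fup, c(TRUE, FALSE, FALSE))

  # PRE = 0 and missing FUP records are excluded, with a reported count
  df <- as.data.frame(co)
  df[1, c("total_pre", "B_pre", "C_pre", "D_pre", "E_pre")] <- 0L
  df[2, c("total_fup", "B_fup", "C_fup", "D_fup", "E_fup")] <- NA_integer_
  co2 <- caps_cohort(df)
  expect_message(out2 <- normalize_cohort(co2, "active"), "excluded 2 of 3")
  expect_identical(nrow(out2), 1L)
  expect_identical(attr(out2, "n_excluded"), 2L)
  # all records excluded -> explicit error
  df3 <- df[1:2, ]
  expect_error(suppressMessages(normalize_cohort(caps_cohort(df3))),
               "no records remain")
})

test_that("responder curve matches hand enumeration and the naive oracle", {
  out <- toy4_outcomes()
  cv <- responder_curve(out, grid = c(0.55, 0.65, 0.85, 0.95), n_min = 1)
  # t = 0.65: subgroup {0.5, 0.6}, improved flags {TRUE, FALSE}
  expect_identical(cv$n, c(1L, 2L, 3L, 4L))
  expect_equal(cv$f, c(1, 0.5, 2 / 3, 0.5))
  expect_equal(cv$overall_rate, 0.5)

  # all improved -> f = 1 wherever defined; empty subgroup -> NA
  all_imp <- as_normalized_outcomes(c(0.5, 0.6, 0.7), c(0.1, 0.2, 0.3))
  cv2 <- responder_curve(all_imp, grid = c(0.4, 0.65, 0.9), n_min = 1)
  expect_true(is.na(cv2$f[1]))
  expect_identical(cv2$n[1], 0L)
  expect_equal(cv2$f[-1], c(1, 1))

  # random cases against the naive loop oracle; n nondecreasing, f in [0,1]
  for (s in 1:20) {
    set.seed(s)
    n <- sample(4:40, 1)
    out <- as_normalized_outcomes(runif(n, 0.1, 1.2), runif(n, 0.1, 1.2))
    cv <- responder_curve(out, n_min = 2)
    orc <- oracle_curve(out$post_ratio, out$fup_ratio, cv$grid, 2)
    expect_equal(cv$f, orc$f)
    expect_identical(cv$n, orc$n)
    expect_true(all(diff(cv$n) >= 0))
    expect_true(all(cv$f[!is.na(cv$f)] >= 0 & cv$f[!is.na(cv$f)] <= 1))
  }
})

test_that("permutation null: identity hook, degenerate values, mean curve", {
  out <- toy4_outcomes()
  grid <- c(0.55, 0.65, 0.85, 0.95)
  # identity permutation reproduces the observed curve exactly
  nl <- permutation_null(out, grid, n_min = 1,
                         perms = matrix(1:4, nrow = 1))
  cv <- responder_curve(out, grid, n_min = 1)
  expect_equal(as.vector(nl$f_rep), cv$f)
  expect_equal(nl$mean_f, cv$f)

  # all fup_ratio equal: every permutation yields the same curve
  deg <- as_normalized_outcomes(c(0.4, 0.6, 0.8, 1.0), rep(0.7, 4))
  nd <- permutation_null(deg, grid, B = 25, n_min = 1, seed = 1)
  expect_true(all(apply(nd$f_rep, 1, function(r) length(unique(r)) == 1)))
  el <- elbow_threshold(responder_curve(deg, grid, n_min = 1), nd)
  expect_equal(el$D_obs, 0)
  expect_equal(el$p_value, 1)

  # seeded reproducibility
  out2 <- as_normalized_outcomes(runif(30, 0.2, 1.1), runif(30, 0.2, 1.1))
  n1 <- permutation_null(out2, B = 50, seed = 99)
  n2 <- permutation_null(out2, B = 50, seed = 99)
  expect_identical(n1$f_rep, n2$f_rep)
})

test_that("elbow on the 4-subject toy: brute-force argmax, both references", {
  out <- toy4_outcomes()
  grid <- c(0.55, 0.65, 0.85, 0.95)
  cv <- responder_curve(out, grid, n_min = 1)
  nl <- permutation_null(out, grid, n_min = 1, seed = 3, B = 100)
  # DIAGONAL with overall-rate reading: ref = 0.5 everywhere;
  # D = (0.5, 0, 1/6, 0) by hand -> argmax at t = 0.55
  el <- elbow_threshold(cv, nl, reference = "diagonal",
                        diagonal = "overall_rate")
  expect_equal(el$D, c(0.5, 0, 1 / 6, 0))
  expect_equal(el$t_star, 0.55)
  expect_equal(el$improvement_pct, 45)
  expect_identical(el$n_at_t_star, 1L)
  # identity reading: ref = 1 - t; D = f - (1 - t)
  el2 <- elbow_threshold(cv, nl, reference = "diagonal")
  expect_equal(el2$D, cv$f - (1 - grid))
  expect_equal(el2$t_star, grid[which.max(cv$f - (1 - grid))])

  # ties at the argmax break toward the smallest threshold
  cvt <- structure(list(grid = c(0.3, 0.5, 0.7), f = c(0.9, 0.9, 0.2),
                        n = c(3L, 5L, 8L), overall_rate = 0.5, n_min = 1),
                   class = "responder_curve")
  nlt <- structure(list(grid = c(0.3, 0.5, 0.7), B = 1, n = c(3L, 5L, 8L),
                        f_rep = matrix(c(0.1, 0.1, 0.1), 3, 1),
                        mean_f = c(0.1, 0.1, 0.1), n_min = 1, seed = NULL),
                   class = "permutation_null")
  expect_equal(elbow_threshold(cvt, nlt, "null_mean")$t_star, 0.3)

  # grids must match; undefined-everywhere errors
  expect_error(elbow_threshold(cv, permutation_null(out, c(0.5, 0.9),
                                                    n_min = 1, B = 10,
                                                    seed = 1)),
               "same threshold grid")
  few <- as_normalized_outcomes(c(0.9, 0.95), c(0.5, 0.99))
  expect_error(elbow_threshold(responder_curve(few, grid, n_min = 3),
                               permutation_null(few, grid, B = 5, n_min = 3,
                                                seed = 1)),
               "below n_min")
})

test_that("elbow is invariant to input order and id relabeling", {
  set.seed(42)
  out <- as_normalized_outcomes(runif(40, 0.2, 1.1), runif(40, 0.2, 1.1))
  run <- function(o) {
    el <- elbow_threshold(responder_curve(o),
                          permutation_null(o, B = 200, seed = 17))
    c(el$t_star, el$D_obs, el$p_value)
  }
  shuffled <- out[sample(nrow(out)), ]
  relabeled <- shuffled
  relabeled$participant_id <- sprintf("Z%04d", seq_len(nrow(relabeled)))
  expect_identical(run(out), run(shuffled))
  expect_identical(run(out), run(relabeled))
})
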