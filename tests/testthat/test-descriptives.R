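test_that("t-based CIs reproduce published group bounds from mean/SD/n", {
  # T-score, subsided group (n = 23) and whole cohort (n = 158)
  expect_equal(round(t_ci_mean(-1.62, 1.34, 23), 2),
               c(lower = -2.20, upper = -1.04))
  expect_equal(round(t_ci_mean(-0.95, 1.40, 158), 2),
               c(lower = -1.17, upper = -0.73))
  # per-level EBQ among non-subsided patients
  expect_equal(round(t_ci_mean(3.88, 1.04, 12), 2),
               c(lower = 3.22, upper = 4.54))
  expect_equal(round(t_ci_mean(4.08, 1.11, 84), 2),
               c(lower = 3.84, upper = 4.32))
  expect_equal(round(t_ci_mean(4.81, 0.91, 17), 2),
               c(lower = 4.34, upper = 5.28))
})

test_that("t_ci_mean handles degenerate inputs per contract", {
  expect_equal(t_ci_mean(5, 0, 10), c(lower = 5, upper = 5))
  expect_error(t_ci_mean(5, 1, 1), "at least 2")
  expect_error(t_ci_mean(5, -1, 10), "nonnegative")
})

test_that("t-intervals cover the true mean at their nominal rate", {
  set.seed(77)
  covered <- vapply(1:2000, function(i) {
    x <- stats::rnorm(15, mean = 3, sd = 2)
    ci <- t_ci_mean(mean(x), stats::sd(x), 15)
    ci[["lower"]] <= 3 && 3 <= ci[["upper"]]
  }, logical(1))
  expect_lt(abs(mean(covered) - 0.95), 0.015)
})

test_that("identical groups give p = 1 under both two-sample paths", {
  set.seed(5)
  v <- stats::rnorm(40)
  cohort <- data.frame(val = c(v, v), subsided = rep(c(FALSE, TRUE), each = 40))
  res <- compare_groups(cohort, "val")
  expect_equal(res$test_used, "student_t")
  expect_equal(res$p_value, 1)
  # heavy-tailed duplicate groups route to Mann-Whitney, still p = 1
  w <- stats::rcauchy(60)
  cohort2 <- data.frame(val = c(w, w), subsided = rep(c(FALSE, TRUE), each = 60))
  res2 <- compare_groups(cohort2, "val")
  expect_equal(res2$test_used, "mann_whitney")
  expect_equal(res2$p_value, 1)
})

test_that("clearly separated groups are detected with tiny p", {
  set.seed(8)
  cohort <- data.frame(val = c(stats::rnorm(50), stats::rnorm(50, 5)),
                       subsided = rep(c(FALSE, TRUE), each = 50))
  res <- compare_groups(cohort, "val")
  expect_lt(res$p_value, 1e-10)
  expect_match(res$test_used, "student_t|mann_whitney")
})

test_that("categorical variables use uncorrected chi-square", {
  co <- simulate_cohort(cohort_config(n_patients = 300, seed = 12))
  res <- compare_groups(co, "smoker")
  expect_equal(res$test_used, "chi_square")
  oracle <- suppressWarnings(
    stats::chisq.test(table(co$smoker, co$subsided), correct = FALSE)$p.value)
  expect_equal(res$p_value, oracle)
  co$allsame <- factor("yes", levels = c("yes", "no"))
  expect_error(compare_groups(co, "allsame"), "zero margin")
})

test_that("per-group summaries report t-CIs around each group mean", {
  co <- simulate_cohort(cohort_config(n_patients = 200, seed = 13))
  res <- compare_groups(co, "ebq")
  g <- res$groups
  expect_setequal(g$group, c("non_subsidence", "subsidence"))
  for (i in seq_len(nrow(g))) {
    expect_equal(c(g$ci_lower[i], g$ci_upper[i]),
                 unname(t_ci_mean(g$mean[i], g$sd[i], g$n[i])))
    expect_true(g$ci_lower[i] <= g$mean[i] && g$mean[i] <= g$ci_upper[i])
  }
})

test_that("Pearson correlation matches its closed forms and invariances", {
  x <- c(1, 2, 4, 5, 7, 9.5)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1.0)
  set.seed(99)
  a <- stats::rnorm(10000); b <- stats::rnorm(10000)
  expect_lt(abs(pearson_correlation(a, b)$r), 0.03)
  r1 <- pearson_correlation(a, b)
  r2 <- pearson_correlation(3 + 2 * a, 10 - 0 * b + 5 * b)
  expect_equal(r2$r, r1$r, tolerance = 1e-12)
  expect_error(pearson_correlation(a, rep(1, 10000)), "zero variance")
  expect_error(pearson_correlation(1:2, 2:3), "n >= 3")
})

test_that("per-level summaries cover non-subsided patients only, in order", {
  co <- simulate_cohort(cohort_config(n_patients = 400, seed = 17))
  tab <- per_level_summary(co)
  expect_identical(tab$level, c("C3/4", "C4/5", "C5/6", "C6/7"))
  expect_equal(sum(tab$n), sum(!co$subsided))
  one <- co[co$level == "C5/6" & !co$subsided, ]
  expect_equal(tab$mean[tab$level == "C5/6"], mean(one$ebq))

  const <- data.frame(ebq = rep(4, 5), level = "C5/6", subsided = FALSE)
  tc <- per_level_summary(const)
  expect_equal(c(tc$ci_lower, tc$ci_upper), c(4, 4))

  tiny <- data.frame(ebq = c(4, 4.5, 5), level = c("C3/4", "C5/6", "C5/6"),
                     subsided = FALSE)
  expect_warning(tab2 <- per_level_summary(tiny), "fewer than 2")
  expect_identical(tab2$level, "C5/6")
})

test_that("a configured per-level EBQ gradient is recovered in the summary", {
  shift <- c("C3/4" = -0.6, "C4/5" = -0.2, "C5/6" = 0.2, "C6/7" = 0.6)
  co <- simulate_cohort(cohort_config(n_patients = 3000, seed = 19,
                                      ebq_level_shift = shift))
  tab <- per_level_summary(co)
  expect_true(all(diff(tab$mean) > 0))  # monotone trend as configured
})
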