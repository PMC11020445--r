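test_that("cohort simulation is deterministic in config and seed", {
  a <- simulate_cohort(cohort_config(n_patients = 100, seed = 9))
  b <- simulate_cohort(cohort_config(n_patients = 100, seed = 9))
  c <- simulate_cohort(cohort_config(n_patients = 100, seed = 10))
  expect_identical(a, b)
  expect_false(identical(a$ebq, c$ebq))
})

test_that("degenerate configs are rejected", {
  expect_error(cohort_config(n_patients = 0), "positive")
  expect_error(cohort_config(smoking_prob = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(level_probs = c(A = 0.5, B = 0.4)), "sum to 1")
})

test_that("a flat outcome model at logit(0.5) yields ~50% subsidence", {
  cfg <- cohort_config(
    n_patients = 2000,
    outcome_model = list(intercept = stats::qlogis(0.5), ebq_coef = 0,
                         tscore_coef = 0),
    seed = 11)
  co <- simulate_cohort(cfg)
  expect_equal(unique(co$true_subsidence_prob), 0.5)
  se <- sqrt(0.25 / 2000)
  expect_lt(abs(mean(co$subsided) - 0.5), 3 * se)
})

test_that("zero residual height-loss noise forces a perfect EBQ correlation", {
  cfg <- cohort_config(
    n_patients = 200,
    heightloss_model = list(intercept = -0.5, slope = 0.45, sd = 0),
    seed = 3)
  co <- simulate_cohort(cfg)
  loss <- co$preop_height_mm - co$final_height_mm
  expect_equal(stats::cor(co$ebq, loss), 1.0, tolerance = 1e-12)
})

test_that("simulated moments converge to the configured ones", {
  cfg <- cohort_config(n_patients = 5000, seed = 21)
  co <- simulate_cohort(cfg)
  checks <- list(
    c(mean(co$age), cfg$age$mean, cfg$age$sd),
    c(mean(co$bmi), cfg$bmi$mean, cfg$bmi$sd),
    c(mean(co$ebq), cfg$ebq$mean, cfg$ebq$sd),
    c(mean(co$preop_height_mm), cfg$preop_height$mean, cfg$preop_height$sd))
  for (chk in checks) {
    expect_lt(abs(chk[1] - chk[2]), 3 * chk[3] / sqrt(5000))
  }
  expect_lt(abs(mean(co$sex == "M") - cfg$sex_prob_male),
            3 * sqrt(cfg$sex_prob_male * (1 - cfg$sex_prob_male) / 5000))
})

test_that("subsidence prevalence is weakly increasing in the EBQ slope", {
  prev <- vapply(c(0, 0.5, 1, 1.5, 2.5), function(b) {
    cfg <- cohort_config(
      n_patients = 500,
      outcome_model = list(intercept = -5, ebq_coef = b, tscore_coef = 0),
      seed = 7)
    mean(simulate_cohort(cfg)$subsided)
  }, numeric(1))
  expect_true(all(diff(prev) >= 0))
})

test_that("the calibrated logistic model hits its target prevalence and case mean", {
  cal <- calibrate_outcome_model(23 / 158, 5.38, 4.31, 1.15)
  f <- function(x) stats::dnorm(x, 4.31, 1.15) *
    stats::plogis(cal$intercept + cal$ebq_coef * x)
  p <- stats::integrate(f, -10, 20, rel.tol = 1e-10)$value
  m <- stats::integrate(function(x) x * f(x), -10, 20, rel.tol = 1e-10)$value / p
  expect_equal(p, 23 / 158, tolerance = 1e-6)
  expect_equal(m, 5.38, tolerance = 1e-6)
})

test_that("default cohorts reproduce the reference group EBQ means", {
  # repeated-simulation oracle: 200 replicate cohorts of n = 158
  reps <- vapply(1:200, function(s) {
    co <- simulate_cohort(cohort_config(seed = s))
    c(sub = mean(co$ebq[co$subsided]), non = mean(co$ebq[!co$subsided]),
      prev = mean(co$subsided))
  }, numeric(3))
  for (row in list(c("sub", 5.38), c("non", 4.1277))) {
    est <- reps[row[1], ]
    se <- stats::sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - as.numeric(row[2])), 2 * se)
  }
  prev_se <- stats::sd(reps["prev", ]) / sqrt(200)
  expect_lt(abs(mean(reps["prev", ]) - 23 / 158), 2 * prev_se)
})

test_that("cohort tables round-trip through CSV with latent truths alongside", {
  co <- simulate_cohort(cohort_config(n_patients = 40, seed = 5))
  d <- withr::local_tempdir()
  path <- file.path(d, "cohort.csv")
  write_cohort(co, path)
  expect_true(file.exists(file.path(d, "cohort_latent.csv")))
  back <- read_cohort(path)
  expect_equal(back$ebq, co$ebq, tolerance = 1e-12)
  expect_identical(back$subsided, co$subsided)
  expect_identical(as.character(back$level), as.character(co$level))
  latent <- utils::read.csv(file.path(d, "cohort_latent.csv"))
  expect_equal(latent$true_subsidence_prob, co$true_subsidence_prob,
               tolerance = 1e-12)
})

test_that("cohort files with missing columns are rejected by name", {
  co <- simulate_cohort(cohort_config(n_patients = 20, seed = 5))
  d <- withr::local_tempdir()
  path <- file.path(d, "bad.csv")
  co$tscore <- NULL
  utils::write.csv(co, path, row.names = FALSE)
  expect_error(read_cohort(path), "tscore")
})
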