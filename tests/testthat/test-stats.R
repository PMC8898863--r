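test_that("OLS matches the closed-form normal-equations oracle", {
  coh <- fixture_cohort(n = 16L, seed = 99L)
  eff <- fit_adjusted_uplift(coh)
  X <- cbind(1, coh$sex == "female", coh$age, coh$preop_ohs, coh$preop_fjs,
             coh$preop_eq5d, coh$preop_eqvas, coh$group == "rTHA")
  beta <- oracle_ols(X, coh$eq5d_change)
  expect_equal(unname(eff$covariate_coefficients$estimate), unname(beta),
               tolerance = 1e-10)
  expect_equal(eff$estimate, unname(beta[8]), tolerance = 1e-10)
  expect_lte(eff$ci_low, eff$estimate)
  expect_gte(eff$ci_high, eff$estimate)
  expect_identical(eff$n_used, 16L)

  # residuals orthogonal to every design column (machine precision)
  expect_lt(max(abs(t(X) %*% residuals(eff$fit))), 1e-9)
})

test_that("randomly permuted group labels centre the estimate on zero", {
  coh <- generate_cohort(cohort_spec(seed = 31))
  set.seed(31)
  est <- replicate(200, {
    perm <- coh
    perm$group <- sample(perm$group)
    fit_adjusted_uplift(perm)$estimate
  })
  expect_lt(abs(mean(est)), 0.01)
})

test_that("the estimator recovers the true effect when the ceiling cannot bind", {
  # low preop utility + small change keeps postop far from 1.0, so censoring
  # never triggers and OLS is unbiased for the generating effect
  est <- vapply(1:50, function(s) {
    s_ <- cohort_spec(eq5d_mean = c(0.1, 0.15), eq5d_sd = c(0.15, 0.15),
                      mtha_mean_change = 0.15, residual_sd = 0.1,
                      group_effect = 0.091, seed = s)
    fit_adjusted_uplift(generate_cohort(s_))$estimate
  }, 0)
  expect_lt(abs(mean(est) - 0.091), 0.01)
})

test_that("rank deficiency and missing fields are reported by name", {
  coh <- fixture_cohort()
  coh$sex <- "male"  # constant dummy column
  expect_error(fit_adjusted_uplift(coh), regexp = "sexfemale",
               class = "hipcea_validation_error")

  coh <- fixture_cohort()
  coh$age[c(2, 5)] <- NA
  expect_error(fit_adjusted_uplift(coh), regexp = "F002.*F005",
               class = "hipcea_validation_error")

  expect_error(fit_adjusted_uplift(fixture_cohort()[0, ]),
               class = "hipcea_validation_error")
})

test_that("female odds ratio matches the cross-product oracle on the study counts", {
  # group x sex counts of the published demographics table
  coh <- make_cohort(
    group = rep(c("mTHA", "rTHA"), times = c(512, 48)),
    sex = c(rep("male", 235), rep("female", 277),
            rep("male", 32), rep("female", 16)),
    age = rnorm(560, 65, 5), ohs = runif(560, 10, 30), fjs = runif(560, 5, 30),
    preop_eq5d = runif(560, 0.2, 0.6), eqvas = runif(560, 50, 90),
    postop_eq5d = runif(560, 0.6, 0.9)
  )
  gc <- group_comparisons(coh)
  expect_equal(gc$summary$sex$odds_ratio, (16 * 235) / (32 * 277))
  expect_equal(round(gc$summary$sex$odds_ratio, 3), 0.424)
  expect_false(gc$summary$sex$undefined)
  expect_lte(gc$summary$sex$ci_low, gc$summary$sex$odds_ratio)
})

test_that("identical groups give zero differences and OR 1", {
  block <- function(g) make_cohort(
    group = rep(g, 4), sex = c("male", "male", "female", "female"),
    age = c(60, 70, 65, 75), ohs = c(15, 25, 20, 30), fjs = c(5, 15, 10, 20),
    preop_eq5d = c(0.2, 0.4, 0.3, 0.5), eqvas = c(60, 70, 65, 75),
    postop_eq5d = c(0.6, 0.8, 0.7, 0.9)
  )
  coh <- rbind(block("mTHA"), block("rTHA"))
  coh$patient_id <- sprintf("F%03d", seq_len(nrow(coh)))
  gc <- group_comparisons(coh)
  expect_equal(gc$summary$demographics$difference, rep(0, 5))
  expect_equal(gc$summary$sex$odds_ratio, 1)
})

test_that("a perfectly linear covariate-change relation gives Pearson r = -1", {
  pre <- seq(0.1, 0.8, length.out = 10)
  coh <- make_cohort(
    group = rep(c("mTHA", "rTHA"), each = 5),
    sex = rep(c("male", "female"), 5), age = seq(55, 80, length.out = 10),
    ohs = seq(10, 30, length.out = 10), fjs = seq(5, 25, length.out = 10),
    preop_eq5d = pre, eqvas = seq(50, 90, length.out = 10),
    postop_eq5d = pre + (0.9 - pre)  # change = 0.9 - pre, exactly linear
  )
  gc <- group_comparisons(coh)
  r <- gc$correlations$r[gc$correlations$covariate == "eq5d"]
  expect_equal(r, -1)
})

test_that("Welch flag switches the unpaired comparison", {
  coh <- generate_cohort(cohort_spec(seed = 13))
  pooled <- group_comparisons(coh, welch = FALSE)$summary$demographics
  welch <- group_comparisons(coh, welch = TRUE)$summary$demographics
  expect_false(isTRUE(all.equal(pooled$p_value, welch$p_value)))
  expect_equal(pooled$difference, welch$difference)  # point estimate unchanged
})

test_that("sample size matches the z-quantile formula", {
  ss <- sample_size_two_group(0.08, 0.3, 0.05, 0.80)
  z <- qnorm(0.975) + qnorm(0.80)
  expect_equal(ss$n_exact, 2 * z^2 * (0.3 / 0.08)^2)
  expect_identical(ss$per_group, 221L)  # the study's discussion prints 222
  expect_identical(ss$total, 442L)

  expect_identical(sample_size_two_group(0.3, 0.3)$per_group,
                   as.integer(ceiling(2 * z^2)))  # 16 when delta = sd

  # power 0.5 limit: z_(1-beta) = 0
  ss5 <- sample_size_two_group(0.08, 0.3, 0.05, 0.5)
  expect_equal(ss5$n_exact, 2 * qnorm(0.975)^2 * (0.3 / 0.08)^2)

  expect_error(sample_size_two_group(0, 0.3), class = "hipcea_validation_error")
})

test_that("sample size is monotone in delta, sd and power", {
  n_of <- function(...) sample_size_two_group(...)$n_exact
  expect_true(all(diff(vapply(c(0.05, 0.08, 0.2), function(d) n_of(delta = d), 0)) < 0))
  expect_true(all(diff(vapply(c(0.2, 0.3, 0.5), function(s) n_of(sd = s), 0)) > 0))
  expect_true(all(diff(vapply(c(0.5, 0.8, 0.9), function(p) n_of(power = p), 0)) > 0))
})
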