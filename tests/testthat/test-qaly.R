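params <- default_parameters()

test_that("policy construction validates its inputs", {
  expect_error(accrual_policy(0), class = "hipcea_validation_error")
  expect_error(accrual_policy(2.5), class = "hipcea_validation_error")
  expect_error(accrual_policy(10, annual_mortality = 1),
               class = "hipcea_validation_error")
  expect_error(accrual_policy(10, discount_rate = -0.1),
               class = "hipcea_validation_error")
})

test_that("weight sums match closed-form oracles", {
  # geometric series over 17 years at 5% multiplicative discount from year 2
  p <- accrual_policy(17, "none", discount_mode = "multiplicative_from_year2",
                      discount_rate = 0.05)
  expect_equal(sum(accrual_weights(p)), (1 - 0.95^17) / 0.05)
  expect_equal(round(sum(accrual_weights(p)), 4), 11.6376)

  # brute-force partial sum of 0.975^t, t = 1..10
  p <- accrual_policy(10, "multiplicative_annual", annual_mortality = 0.025)
  expect_equal(sum(accrual_weights(p)), sum(0.975^(1:10)))
  expect_equal(round(sum(accrual_weights(p)), 4), 8.7231)

  # all rates zero: every weight is exactly 1
  for (sm in c("none", "multiplicative_annual", "linear_annual")) {
    p <- accrual_policy(12, sm)
    expect_identical(accrual_weights(p), rep(1, 12))
  }
})

test_that("discount off => multiplicative survival equals the geometric closed form", {
  for (m in c(0.01, 0.025, 0.1)) {
    for (h in c(1L, 7L, 30L)) {
      p <- accrual_policy(h, "multiplicative_annual", annual_mortality = m)
      q <- 1 - m
      expect_equal(sum(accrual_weights(p)), q * (1 - q^h) / (1 - q),
                   tolerance = 1e-14)
    }
  }
})

test_that("linear survival errors when a weight would reach zero", {
  expect_error(
    accrual_weights(accrual_policy(25, "linear_annual", annual_mortality = 0.05)),
    regexp = "year 20", class = "hipcea_validation_error"
  )
})

test_that("qalys_gained reproduces the printed QALY-gain block", {
  life_u <- default_accrual_policy("lifetime_undiscounted", params)
  life_d <- default_accrual_policy("lifetime_discounted", params)
  ten_u <- default_accrual_policy("ten_year_undiscounted", params)

  expect_equal(qalys_gained(0.091, life_u)$qalys_gained, 1.5470)
  expect_equal(round(qalys_gained(0.091, life_d)$qalys_gained, 4), 1.0590)

  q10 <- qalys_gained(0.091, ten_u)$qalys_gained
  expect_equal(round(q10, 4), 0.7938)
  expect_lt(abs(q10 - 0.7935) / 0.7935, 5e-4)  # vs the printed value

  z <- qalys_gained(0, life_u)
  expect_identical(z$qalys_gained, 0)
  expect_s3_class(z$policy_used, "accrual_policy")
})

test_that("accrual matches the brute-force year-loop oracle on a mode grid", {
  set.seed(21)
  for (sm in c("none", "multiplicative_annual", "linear_annual")) {
    for (dm in c("none", "multiplicative_from_year2",
                 "multiplicative_from_year1", "compound_interest_from_year2")) {
      for (rep in 1:3) {
        h <- sample(1:30, 1)
        m <- if (sm == "linear_annual") runif(1, 0, 0.9 / (h + 1)) else runif(1, 0, 0.3)
        r <- runif(1, 0, min(0.02, 0.05 / h))
        d <- runif(1, 0, 0.2)
        p <- accrual_policy(h, sm, include_revision_in_qalys = TRUE,
                            discount_mode = dm, annual_mortality = m,
                            annual_revision = r, discount_rate = d)
        expect_equal(accrual_weights(p),
                     oracle_weights(h, sm, m, r, TRUE, dm, d),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("weights are in (0,1], non-increasing; QALYs monotone in every rate", {
  base <- function(m = 0.025, r = 0.004, d = 0.05, h = 10L, u = 0.091) {
    qalys_gained(u, accrual_policy(
      h, "multiplicative_annual", include_revision_in_qalys = TRUE,
      discount_mode = "multiplicative_from_year2", annual_mortality = m,
      annual_revision = r, discount_rate = d
    ))$qalys_gained
  }
  w <- accrual_weights(accrual_policy(
    15, "multiplicative_annual", include_revision_in_qalys = TRUE,
    discount_mode = "multiplicative_from_year2", annual_mortality = 0.025,
    annual_revision = 0.004, discount_rate = 0.05
  ))
  expect_true(all(w > 0 & w <= 1))
  expect_true(all(diff(w) <= 0))

  expect_true(all(diff(vapply(c(0, 0.01, 0.05, 0.2), function(m) base(m = m), 0)) < 0))
  expect_true(all(diff(vapply(c(0, 0.01, 0.05), function(r) base(r = r), 0)) < 0))
  expect_true(all(diff(vapply(c(0, 0.03, 0.1), function(d) base(d = d), 0)) < 0))
  expect_true(all(diff(vapply(c(0.017, 0.08, 0.091, 0.2), function(u) base(u = u), 0)) > 0))
  expect_true(all(diff(vapply(c(1L, 5L, 10L, 17L), function(h) base(h = h), 0)) > 0))
})
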