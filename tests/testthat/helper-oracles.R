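# Independent oracles, deliberately written as plain per-year loops and
# textbook formulas, never calling the implementation they check.

# Brute-force accrual weights: one explicit loop over postoperative years.
oracle_weights <- function(horizon, survival_mode, mortality, revision,
                           include_revision, discount_mode, rate) {
  w <- numeric(horizon)
  for (t in seq_len(horizon)) {
    s <- 1
    if (survival_mode == "multiplicative_annual") {
      s <- (1 - mortality)^t
      if (include_revision) s <- s * (1 - revision)^t
    } else if (survival_mode == "linear_annual") {
      s <- 1 - (mortality + if (include_revision) revision else 0) * t
    }
    d <- 1
    if (discount_mode == "multiplicative_from_year2") d <- (1 - rate)^(t - 1)
    if (discount_mode == "multiplicative_from_year1") d <- (1 - rate)^t
    if (discount_mode == "compound_interest_from_year2") d <- (1 + rate)^(-(t - 1))
    w[t] <- s * d
  }
  w
}

# Closed-form OLS via the normal equations.
oracle_ols <- function(X, y) drop(solve(t(X) %*% X, t(X) %*% y))

# Build a syntactically complete cohort data frame from raw columns.
make_cohort <- function(group, sex, age, ohs, fjs, preop_eq5d, eqvas,
                        postop_eq5d) {
  data.frame(
    patient_id = sprintf("F%03d", seq_along(group)),
    group = group, sex = sex, age = age,
    preop_ohs = ohs, preop_fjs = fjs,
    preop_eq5d = preop_eq5d, preop_eqvas = eqvas,
    postop_eq5d = postop_eq5d,
    eq5d_change = postop_eq5d - preop_eq5d,
    stringsAsFactors = FALSE
  )
}

# A small well-conditioned two-group cohort for estimator fixtures
# (covariates drawn independently so the design has full rank).
fixture_cohort <- function(n = 16L, seed = 99L, effect = 0.05) {
  set.seed(seed)
  group <- rep(c("mTHA", "rTHA"), each = n / 2)
  sex <- rep(c("male", "female"), length.out = n)
  age <- runif(n, 55, 80)
  ohs <- runif(n, 10, 35)
  fjs <- runif(n, 5, 40)
  pre <- runif(n, 0.1, 0.6)
  vas <- runif(n, 50, 90)
  post <- pre + 0.25 + 0.002 * ohs - 0.3 * pre +
    effect * (group == "rTHA") + rnorm(n, 0, 0.02)
  make_cohort(group, sex, age, ohs, fjs, pre, vas, post)
}
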